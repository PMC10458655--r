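test_that("energy errors are offset-invariant and match hand arithmetic", {
  cm <- make_chain(6, seed = 41)
  set.seed(41)
  confs <- lapply(1:3, function(i)
    cm$conf + matrix(rnorm(length(cm$conf), sd = 0.05), ncol = 3))
  oracle <- mm_oracle(cm$top, cm$ps)
  lab <- oracle(confs)
  self <- reference_dataset(confs, lab$energies, lab$forces)
  expect_equal(energy_errors(cm$top, cm$ps, self),
               c(rmse = 0, mae = 0), tolerance = 1e-10)
  shifted <- reference_dataset(confs, lab$energies + 55.5, lab$forces)
  expect_equal(energy_errors(cm$top, cm$ps, shifted),
               c(rmse = 0, mae = 0), tolerance = 1e-10)
  # residuals {+1, -1, +2}: centered {1/3, -5/3, 4/3}
  resid <- c(1, -1, 2)
  made <- reference_dataset(confs, lab$energies - resid, lab$forces)
  e <- energy_errors(cm$top, cm$ps, made)
  expect_equal(unname(e["rmse"]), sqrt(mean((resid - mean(resid))^2)))
  expect_equal(unname(e["mae"]), mean(abs(resid - mean(resid))))
  expect_gte(e[["rmse"]], e[["mae"]])
})

test_that("rmse >= mae on random residual sets", {
  cm <- make_chain(5, seed = 42)
  set.seed(42)
  confs <- lapply(1:12, function(i)
    cm$conf + matrix(rnorm(length(cm$conf), sd = 0.05), ncol = 3))
  lab <- mm_oracle(cm$top, cm$ps)(confs)
  for (rep in 1:10) {
    d <- reference_dataset(confs, lab$energies + rnorm(12, 0, 2), lab$forces)
    e <- energy_errors(cm$top, cm$ps, d)
    expect_gte(e[["rmse"]], e[["mae"]])
  }
})

test_that("per-unit decomposition reproduces the printed arithmetic", {
  expect_equal(per_unit_error(3.7, 7), 0.5286)
  expect_equal(per_unit_error(4.3, 8), 0.5375)
  expect_equal(per_unit_error(0, 5), 0)
})

test_that("force-error matrix: magnitudes, permutations, aggregates", {
  cm <- make_chain(6, seed = 43)
  set.seed(43)
  confs <- lapply(1:4, function(i)
    cm$conf + matrix(rnorm(length(cm$conf), sd = 0.05), ncol = 3))
  lab <- mm_oracle(cm$top, cm$ps)(confs)
  self <- reference_dataset(confs, lab$energies, lab$forces)
  rep0 <- force_error_matrix(cm$top, cm$ps, self, grouping = "none")
  expect_equal(max(rep0$per_atom_force_error), 0)
  expect_equal(rep0$force_rmse, 0)

  # a single (3,4,0) deviation on atom 2 of frame 3 has magnitude 5
  forces2 <- lab$forces
  forces2[[3]][2, ] <- forces2[[3]][2, ] - c(3, 4, 0)
  dev <- reference_dataset(confs, lab$energies, forces2)
  repd <- force_error_matrix(cm$top, cm$ps, dev, grouping = "none")
  expect_equal(repd$per_atom_force_error[3, 2], 5)
  expect_equal(sum(repd$per_atom_force_error > 1e-12), 1)
  n <- nrow(cm$conf)
  expect_equal(repd$force_rmse, sqrt(25 / (3 * n * 4)))
  expect_equal(repd$force_rmse_atom, sqrt(25 / (n * 4)))
  expect_equal(repd$force_mean_abs, 5 / (n * 4))

  # element grouping: N block first, O block last
  ord <- force_error_matrix(cm$top, cm$ps, self, grouping = "element")$atom_order
  el <- cm$top$atoms$element[ord]
  if (any(el == "N")) expect_true(all(which(el == "N") <=  sum(el == "N")))
  if (any(el == "O")) expect_true(all(which(el == "O") > length(el) - sum(el == "O")))
  expect_error(force_error_matrix(cm$top, cm$ps, self, grouping = c(1, 1, 2, 3, 4, 5)),
               "permutation")
})

test_that("force aggregate ties out with the fm loss force block", {
  cm <- make_chain(6, seed = 44)
  set.seed(44)
  confs <- lapply(1:5, function(i)
    cm$conf + matrix(rnorm(length(cm$conf), sd = 0.05), ncol = 3))
  truth_lab <- mm_oracle(cm$top, cm$ps)(confs)
  data <- reference_dataset(confs, truth_lab$energies, truth_lab$forces)
  trial <- perturb_params(cm$ps, perturb_spec(rel_k = 0.2, seed = 45,
                                              prob_drop = 0, prob_add = 0))
  l <- fm_loss(pack_parameters(trial), cm$top, trial, data,
               fit_config(w_energy = 0, lambda_reg = 0))
  rep1 <- force_error_matrix(cm$top, trial, data)
  n <- nrow(cm$conf)
  # w_F = 1/(3 n n_confs) turns the force block into the squared force RMSE
  expect_equal(l$value, rep1$force_rmse^2, tolerance = 1e-10)
})

test_that("radius of gyration closed forms and invariances", {
  two <- trajectory(list(rbind(c(0, 0, 0), c(2, 0, 0))), c("H", "H"))
  expect_equal(radius_of_gyration(two, masses = c(1, 1))$values, 1)
  same <- trajectory(list(rbind(c(1, 2, 3), c(1, 2, 3) + 1e-12)), c("C", "C"))
  expect_lt(radius_of_gyration(same)$values, 1e-9)
  set.seed(46)
  m <- matrix(rnorm(30, sd = 3), 10, 3)
  tr <- trajectory(list(m, sweep(m, 2, c(10, -4, 2), "+")),
                   rep("C", 10))
  rg <- radius_of_gyration(tr)
  expect_equal(rg$values[1], rg$values[2], tolerance = 1e-12)
  expect_error(radius_of_gyration(tr, masses = rep(-1, 10)), "positive")
})

test_that("Kabsch superposition recovers planted rigid transforms", {
  set.seed(47)
  ref <- matrix(rnorm(36, sd = 2), 12, 3)
  out0 <- kabsch_superpose(ref, ref)
  expect_lt(out0$rmsd, 1e-12)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  mob <- sweep(ref %*% q, 2, c(3, -1, 7), "+")
  out <- kabsch_superpose(ref, mob)
  expect_lt(out$rmsd, 1e-9)
  expect_equal(out$aligned, ref, tolerance = 1e-9)
  # optimality: no random rotation does better
  noisy <- ref + matrix(rnorm(36, sd = 0.3), 12, 3)
  best <- kabsch_superpose(ref, noisy)$rmsd
  ctr <- sweep(noisy, 2, colMeans(noisy))
  refc <- sweep(ref, 2, colMeans(ref))
  for (rep in 1:100) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    r <- sqrt(mean(rowSums((ctr %*% q - refc)^2)))
    expect_gte(r, best - 1e-12)
  }
})

test_that("state classification recovers a planted two-state mixture", {
  rg <- simulate_rg_series(4000, occupancies = c(0.65, 0.35),
                           means = c(7.5, 6.2), sds = c(0.12, 0.12),
                           dwell = 60, seed = 48)
  st <- classify_states(rg, k_states = 2, min_dwell = 5)
  expect_equal(sum(st$occupancy), 1)
  truth_occ <- mean(rg$labels == 1)
  expect_lt(abs(st$occupancy[1] - truth_occ), 0.02)
  expect_gt(st$mean_rg[1], st$mean_rg[2])  # opened state first
})

test_that("state classification handles degenerate and periodic inputs", {
  expect_error(classify_states(rep(5, 100), k_states = 2), "distinct")
  st1 <- classify_states(rep(5, 100), k_states = 1)
  expect_equal(st1$occupancy, 1)
  # periodic interconversion between opened and squashed states
  set.seed(49)
  vals <- rep(c(7.4, 6.1), each = 100, times = 5) + rnorm(1000, 0, 0.1)
  st <- classify_states(rg_series(seq_along(vals), pmax(vals, 0)),
                        k_states = 2, min_dwell = 10)
  expect_equal(sort(unique(st$labels)), c(1L, 2L))
  expect_equal(st$occupancy, c(0.5, 0.5), tolerance = 0.02)
})

test_that("dwell smoothing removes sub-threshold blips", {
  vals <- c(rep(7.5, 80), 6.2, 6.25, rep(7.5, 80),
            rep(6.2, 90), 7.5, rep(6.2, 60))
  st <- classify_states(rg_series(seq_along(vals), vals), k_states = 2,
                        min_dwell = 10)
  r <- rle(st$labels)
  expect_true(all(r$lengths >= 10))
  expect_identical(length(r$lengths), 2L)  # one clean transition remains
})
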