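# force-matching loss and refit on small chains: the oracle is the MM
# engine under the generating ("true") parameters, so restraint-free
# refits must recover the generating bonded terms

chain_dataset <- function(cm, params, n = 8, seed = 1, jitter = 0.08,
                          energy_offset = 0) {
  set.seed(seed)
  confs <- lapply(seq_len(n), function(i)
    cm$conf + matrix(rnorm(length(cm$conf), sd = jitter), ncol = 3))
  oracle <- mm_oracle(cm$top, params)
  lab <- oracle(confs)
  reference_dataset(confs, lab$energies + energy_offset, lab$forces,
                    provenance = "mm-truth")
}

test_that("loss vanishes at the generating parameters (offset-consistent)", {
  cm <- make_chain(6, seed = 21)
  # a constant shift between reference and model energy zeros is profiled out
  data <- chain_dataset(cm, cm$ps, energy_offset = 137.2)
  theta_star <- pack_parameters(cm$ps)
  cfg <- fit_config(lambda_reg = 0)
  l <- fm_loss(theta_star, cm$top, cm$ps, data, cfg)
  expect_lt(l$value, 1e-16)
})

test_that("dominant restraint pins the optimum at the starting parameters", {
  cm <- make_chain(5, seed = 22)
  truth <- cm$ps
  start <- perturb_params(truth, perturb_spec(rel_k = 0.15, seed = 5,
                                              prob_drop = 0, prob_add = 0))
  data <- chain_dataset(cm, truth)
  fit <- optimize_bonded(start, cm$top, data,
                         fit_config(lambda_reg = 1e10, maxit = 500))
  scales <- hostfit:::theta_scales(start)
  dev <- hostfit:::wrap_gamma_diff(fit$theta - pack_parameters(start), start)
  expect_lt(max(abs(dev) / scales), 1e-6)
})

test_that("loss equals a hand-assembled brute-force sum", {
  cm <- make_chain(5, seed = 23)
  data <- chain_dataset(cm, cm$ps, n = 3, seed = 2)
  set.seed(3)
  theta <- pack_parameters(cm$ps) * (1 + runif(22, -0.1, 0.1))[
    seq_along(pack_parameters(cm$ps))]
  trial <- unpack_parameters(theta, cm$ps)
  cfg <- fit_config(lambda_reg = 0)
  l <- fm_loss(theta, cm$top, cm$ps, data, cfg)
  # oracle: per-configuration brute-force energies + finite-difference forces
  h <- 1e-5
  n <- nrow(cm$conf)
  Eb <- vapply(data$confs, function(cf) brute_energy(cm$top, trial, cf), 0)
  eres <- Eb - data$energies
  eres <- eres - mean(eres)
  floss <- 0
  for (c in seq_along(data$confs)) {
    cf <- data$confs[[c]]
    for (i in seq_len(n)) for (d in 1:3) {
      cp <- cf; cp[i, d] <- cp[i, d] + h
      cmn <- cf; cmn[i, d] <- cmn[i, d] - h
      fmodel <- -(brute_energy(cm$top, trial, cp) -
                    brute_energy(cm$top, trial, cmn)) / (2 * h)
      floss <- floss + (fmodel - data$forces[[c]][i, d])^2
    }
  }
  expected <- sum(eres^2) / 3 + floss / (3 * n * 3)
  expect_equal(l$value, expected, tolerance = 1e-5)
})

test_that("loss gradient matches central finite differences", {
  cm <- make_chain(6, seed = 24)
  data <- chain_dataset(cm, cm$ps, n = 4)
  theta0 <- pack_parameters(cm$ps)
  set.seed(4)
  theta <- theta0 * (1 + runif(length(theta0), -0.1, 0.1))
  cfg <- fit_config(lambda_reg = 1e-3)
  g <- fm_loss(theta, cm$top, cm$ps, data, cfg, theta0 = theta0)$gradient
  h <- 1e-6
  for (i in seq_along(theta)) {
    tp <- theta; tp[i] <- tp[i] + h
    tm <- theta; tm[i] <- tm[i] - h
    fd <- (fm_loss(tp, cm$top, cm$ps, data, cfg, theta0 = theta0)$value -
             fm_loss(tm, cm$top, cm$ps, data, cfg, theta0 = theta0)$value) /
      (2 * h)
    expect_lt(abs(g[i] - fd) / max(abs(fd), 1), 1e-4)
  }
})

test_that("theta packing mismatches are rejected", {
  cm <- make_chain(5, seed = 25)
  data <- chain_dataset(cm, cm$ps, n = 2)
  expect_error(fm_loss(c(1, 2, 3), cm$top, cm$ps, data), "packing map")
})

test_that("restraint-free refit recovers the generating bonded terms", {
  # hot sampling decorrelates the dihedrals enough to identify every
  # torsion profile; room-temperature data leaves them underdetermined
  for (seed in c(26, 29)) {
    cm <- make_chain(7, seed = seed)
    truth <- cm$ps
    scfg <- sampler_config(1500, 150, stride = 20, seed = seed)
    traj <- metropolis_sample(cm$top, truth, cm$conf, scfg)
    lab <- mm_oracle(cm$top, truth)(traj$frames)
    data <- reference_dataset(traj$frames, lab$energies, lab$forces)
    start <- perturb_params(truth, perturb_spec(rel_k = 0.1, abs_r0 = 0.02,
                                                abs_theta0 = 3,
                                                prob_drop = 0.2,
                                                prob_add = 0.2,
                                                seed = seed + 1))
    fit <- optimize_bonded(start, cm$top, data,
                           fit_config(lambda_reg = 0, maxit = 2000))
    expect_lte(fit$loss, fit$initial_loss)
    # phase-degeneracy-aware comparison: per-type energy profiles within 1%
    errs <- profile_rms(truth, fit$params)
    expect_lt(max(errs), 0.01)
  }
})

test_that("refit from the truth itself returns the truth unchanged", {
  cm <- make_chain(5, seed = 27)
  data <- chain_dataset(cm, cm$ps, n = 10)
  fit <- optimize_bonded(cm$ps, cm$top, data, fit_config(lambda_reg = 0))
  scales <- hostfit:::theta_scales(cm$ps)
  expect_lt(max(abs(fit$theta - pack_parameters(cm$ps)) / scales), 1e-5)
})

test_that("strong regularization cannot beat the unrestrained refit", {
  cm <- make_chain(6, seed = 28)
  truth <- cm$ps
  train <- chain_dataset(cm, truth, n = 40, seed = 8)
  test <- chain_dataset(cm, truth, n = 25, seed = 9)
  start <- perturb_params(truth, perturb_spec(rel_k = 0.2, seed = 10,
                                              prob_drop = 0, prob_add = 0))
  fit0 <- optimize_bonded(start, cm$top, train,
                          fit_config(lambda_reg = 0, maxit = 2000))
  fitL <- optimize_bonded(start, cm$top, train,
                          fit_config(lambda_reg = 10, maxit = 2000))
  e0 <- energy_errors(cm$top, fit0$params, test)["rmse"]
  eL <- energy_errors(cm$top, fitL$params, test)["rmse"]
  expect_lte(e0, eL + 1e-9)
})

test_that("adaptive loop bookkeeping: sizes grow by batch, test is fresh", {
  bench <- make_bench_ring()
  truth <- bench$truth
  start <- perturb_params(truth, perturb_spec(seed = 31))
  oracle <- mm_oracle(bench$top, truth)
  cfg <- fit_config(n_iterations = 3, batch_size = 40, seed = 32,
                    maxit = 150)
  fit <- adaptive_refit(bench$top, start, oracle, bench$conf, cfg,
                        test_size = 30)
  expect_identical(fit$dataset_size_history, c(40L, 80L, 120L))
  expect_length(fit$train_data$confs, 120)
  expect_length(fit$test_data$confs, 30)
  # test configurations were never part of training
  train_sig <- vapply(fit$train_data$confs, function(m) sum(m), 0)
  test_sig <- vapply(fit$test_data$confs, function(m) sum(m), 0)
  expect_length(intersect(train_sig, test_sig), 0)
  expect_true(all(diff(c(0, fit$dataset_size_history)) == 40))
})

test_that("a single-iteration loop reduces the pre-refit error", {
  bench <- make_bench_ring()
  start <- perturb_params(bench$truth, perturb_spec(seed = 33))
  oracle <- mm_oracle(bench$top, bench$truth)
  cfg <- fit_config(n_iterations = 1, batch_size = 80, seed = 34,
                    maxit = 300)
  fit <- adaptive_refit(bench$top, start, oracle, bench$conf, cfg,
                        test_size = 60)
  expect_lt(fit$test_errors$after["rmse"], fit$test_errors$before["rmse"])
  expect_lt(fit$test_errors$after["force_rmse"],
            fit$test_errors$before["force_rmse"])
})

test_that("oracle failures are skipped and replaced, count preserved", {
  bench <- make_bench_ring(n_units = 5)
  truth <- bench$truth
  base <- mm_oracle(bench$top, truth)
  calls <- new.env(); calls$k <- 0
  flaky <- function(confs) {
    out <- base(confs)
    calls$k <- calls$k + 1
    if (calls$k == 1) out$energies[3] <- NaN  # poison one configuration once
    out
  }
  start <- perturb_params(truth, perturb_spec(seed = 35))
  cfg <- fit_config(n_iterations = 1, batch_size = 25, seed = 36,
                    maxit = 50)
  expect_warning(
    fit <- adaptive_refit(bench$top, start, flaky, bench$conf, cfg,
                          test_size = 10),
    "resampling")
  expect_length(fit$train_data$confs, 25)
})
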