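test_that("bond term vanishes at the equilibrium geometry", {
  atoms <- data.frame(element = c("C", "C"), type_label = c("c1", "c1"),
                      charge = 0, unit_id = 1)
  top <- topology(atoms, rbind(c(1, 2)))
  ps <- parameter_set(
    bonds = data.frame(t1 = "c1", t2 = "c1", k = 100, r0 = 1.5),
    angles = data.frame(t1 = character(), t2 = character(),
                        t3 = character(), k = numeric(), theta0 = numeric()),
    torsions = data.frame(t1 = character(), t2 = character(),
                          t3 = character(), t4 = character(), v = numeric(),
                          n = numeric(), gamma = numeric()),
    vdw = data.frame(type = "c1", rmin_half = 1.9, epsilon = 0.1))
  conf <- rbind(c(0, 0, 0), c(1.5, 0, 0))
  e <- energy_components(top, ps, conf)
  expect_equal(unname(e["bond"]), 0)
  expect_equal(unname(e["total"]), 0)
  expect_equal(forces(top, ps, conf), matrix(0, 2, 3), tolerance = 1e-12)
})

# a single-component torsion scanned over the dihedral must span exactly
# its barrier height; 2.08 kcal/mol with periodicity 2 is the canonical case
test_that("torsion scan spans the defined barrier height", {
  atoms <- data.frame(element = rep("C", 4), type_label = rep("ct", 4),
                      charge = 0, unit_id = 1)
  top <- topology(atoms, rbind(c(1, 2), c(2, 3), c(3, 4)))
  ps <- parameter_set(
    bonds = data.frame(t1 = "ct", t2 = "ct", k = 0, r0 = 1.5),
    angles = data.frame(t1 = "ct", t2 = "ct", t3 = "ct", k = 0, theta0 = 110),
    torsions = data.frame(t1 = "ct", t2 = "ct", t3 = "ct", t4 = "ct",
                          v = 2.08, n = 2, gamma = 180),
    vdw = data.frame(type = "ct", rmin_half = 1.9, epsilon = 0))
  phis <- seq(0, 2 * pi, length.out = 181)
  e <- vapply(phis, function(phi) {
    conf <- rbind(c(1.2, 0, -1.4),
                  c(0, 0, 0), c(0, 0, 1.5),
                  c(1.2 * cos(phi), 1.2 * sin(phi), 2.9))
    unname(energy_components(top, ps, conf)["torsion"])
  }, 0)
  expect_equal(max(e) - min(e), 2.08, tolerance = 1e-6)
  # periodicity: E(phi) = E(phi + 2 pi / n)
  expect_equal(e[phis <= pi + 1e-9], e[phis >= pi - 1e-9], tolerance = 1e-9)
})

test_that("total energy matches the independent brute-force oracle", {
  for (seed in 1:5) {
    cm <- make_chain(8, seed = seed)
    expect_equal(unname(energy_components(cm$top, cm$ps, cm$conf)["total"]),
                 brute_energy(cm$top, cm$ps, cm$conf), tolerance = 1e-10)
  }
})

test_that("energy is invariant under rigid motion", {
  cm <- make_chain(7, seed = 3)
  e0 <- total_energy(cm$top, cm$ps, cm$conf)
  set.seed(4)
  for (rep in 1:5) {
    q <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    shifted <- sweep(cm$conf %*% q, 2, rnorm(3, sd = 5), "+")
    expect_lt(abs(total_energy(cm$top, cm$ps, shifted) - e0), 1e-8)
  }
})

test_that("forces are the analytic negative gradient of the energy", {
  h <- 1e-5
  worst <- 0
  for (seed in 1:50) {
    cm <- make_chain(sample(4:6, 1), seed = seed)
    f <- forces(cm$top, cm$ps, cm$conf)
    expect_equal(colSums(f), c(0, 0, 0), tolerance = 1e-9)  # no net force
    trq <- colSums(cbind(
      cm$conf[, 2] * f[, 3] - cm$conf[, 3] * f[, 2],
      cm$conf[, 3] * f[, 1] - cm$conf[, 1] * f[, 3],
      cm$conf[, 1] * f[, 2] - cm$conf[, 2] * f[, 1]))
    expect_equal(trq, c(0, 0, 0), tolerance = 1e-9)  # no net torque
    for (i in seq_len(nrow(cm$conf))) for (d in 1:3) {
      cp <- cm$conf; cp[i, d] <- cp[i, d] + h
      cmn <- cm$conf; cmn[i, d] <- cmn[i, d] - h
      fd <- -(total_energy(cm$top, cm$ps, cp) -
                total_energy(cm$top, cm$ps, cmn)) / (2 * h)
      worst <- max(worst, abs(f[i, d] - fd))
    }
  }
  expect_lt(worst, 1e-5)
})

test_that("forces rotate with the molecule", {
  cm <- make_chain(6, seed = 9)
  f <- forces(cm$top, cm$ps, cm$conf)
  set.seed(10)
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  f_rot <- forces(cm$top, cm$ps, cm$conf %*% q)
  expect_equal(f_rot, f %*% q, tolerance = 1e-9)
})

test_that("degenerate and invalid inputs are rejected", {
  cm <- make_chain(4, seed = 1)
  bad <- cm$conf
  bad[2, ] <- bad[1, ]
  expect_error(energy_components(cm$top, cm$ps, bad), "degenerate")
  ps2 <- cm$ps
  ps2$torsions <- ps2$torsions[-1, ]
  expect_error(energy_components(cm$top, ps2, cm$conf), "unresolved")
})

test_that("validate_system reports issues as data", {
  cm <- make_chain(5, seed = 2)
  expect_identical(validate_system(cm$top, cm$ps), character(0))
  ps2 <- cm$ps
  ps2$torsions <- ps2$torsions[-1, ]
  issues <- validate_system(cm$top, ps2)
  expect_length(issues, 1)
  expect_match(issues, "unresolved torsion")
  # duplicated bond built by hand, bypassing the constructor's checks
  top2 <- cm$top
  top2$bonds <- rbind(top2$bonds, top2$bonds[1, ])
  expect_match(validate_system(top2, cm$ps), "duplicated bond",
               all = FALSE)
})

test_that("parameter diff classifies identical/changed/eliminated/new", {
  cm <- make_chain(6, seed = 5)
  d0 <- diff_parameter_sets(cm$ps, cm$ps)
  for (cls in names(d0)) expect_true(all(d0[[cls]]$status == "identical"))

  ps2 <- cm$ps
  ps2$bonds$k[1] <- ps2$bonds$k[1] * 1.4   # +40% force constant
  newtor <- ps2$torsions[1, ]
  newtor[, c("t1", "t2", "t3", "t4")] <- c("zz", "zz", "zz", "zz")
  newtor$type_key <- "zz zz zz zz"
  ps2$torsions <- rbind(ps2$torsions, newtor)
  dropped_key <- cm$ps$torsions$type_key[nrow(cm$ps$torsions)]
  ps2$torsions$v[ps2$torsions$type_key == dropped_key] <- 0

  d <- diff_parameter_sets(cm$ps, ps2)
  b1 <- d$bond[d$bond$type_key == cm$ps$bonds$type_key[1], ]
  expect_identical(b1$status, "changed")
  expect_equal(b1$pct_k, 40, tolerance = 1e-9)
  expect_identical(d$torsion$status[d$torsion$type_key == "zz zz zz zz"],
                   "only_in_b")
  expect_identical(d$torsion$status[d$torsion$type_key == dropped_key],
                   "only_in_a")
  # mirror image under argument swap
  drev <- diff_parameter_sets(ps2, cm$ps)
  for (cls in names(d)) {
    a_only <- sort(d[[cls]]$type_key[d[[cls]]$status == "only_in_a"])
    b_only <- sort(drev[[cls]]$type_key[drev[[cls]]$status == "only_in_b"])
    expect_identical(a_only, b_only)
  }
})
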