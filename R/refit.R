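#' Reference dataset of configurations, energies and forces
#'
#' The training/testing material of the force-matching refit: sampled
#' configurations labelled with energies and per-atom forces by a reference
#' Hamiltonian (an ab initio-like oracle).
#'
#' @param confs list of n_atoms x 3 matrices (or an [trajectory()]).
#' @param energies per-configuration energies (kcal/mol).
#' @param forces list of n_atoms x 3 force matrices (kcal/mol/A).
#' @param provenance label of the oracle that produced the data.
#' @return object of class `hf_reference_dataset`.
#' @export
reference_dataset <- function(confs, energies, forces, provenance = "oracle") {
  if (inherits(confs, "hf_trajectory")) confs <- confs$frames
  stopifnot(length(confs) == length(energies),
            length(forces) == length(confs))
  na <- nrow(confs[[1]])
  stopifnot(all(vapply(forces, nrow, 0L) == na))
  structure(list(confs = confs, energies = as.numeric(energies),
                 forces = forces, provenance = provenance),
            class = "hf_reference_dataset")
}

#' @export
print.hf_reference_dataset <- function(x, ...) {
  cat(sprintf("hf_reference_dataset: %d configurations x %d atoms [%s]\n",
              length(x$confs), nrow(x$confs[[1]]), x$provenance))
  invisible(x)
}

dataset_matrices <- function(data) {
  list(confs = confs_to_matrix(data$confs),
       Fref = vapply(data$forces, function(f) as.numeric(t(f)),
                     numeric(3 * nrow(data$forces[[1]]))))
}

#' Force-matching refit configuration
#'
#' Defaults mirror the adaptive-accumulation protocol: 500 configurations
#' per iteration, 18 iterations (9000 training configurations in total),
#' training sampled at 600 K for unconstrained exploration and testing at
#' 300 K to probe the room-temperature-accessible region.
#'
#' @param w_energy energy-block weight per (kcal/mol)^2; `NULL` means
#'   1/n_confs (per-datum mean square).
#' @param w_force force-block weight; `NULL` means 1/(3 n_atoms n_confs).
#' @param lambda_reg L2 restraint strength in scaled (dimensionless)
#'   parameter units (default 1e-3).
#' @param n_iterations adaptive accumulation iterations (default 18).
#' @param batch_size configurations sampled per iteration (default 500).
#' @param train_T,test_T sampling temperatures in K (defaults 600 / 300).
#' @param stride sampler sweeps between retained frames (default 10).
#' @param max_step initial trial-move size (A).
#' @param maxit optimizer iteration cap per refit (default 500).
#' @param seed integer seed controlling all sampling.
#' @return list of class `hf_fit_config`.
#' @export
fit_config <- function(w_energy = NULL, w_force = NULL, lambda_reg = 1e-3,
                       n_iterations = 18, batch_size = 500,
                       train_T = 600, test_T = 300, stride = 10,
                       max_step = 0.05, maxit = 500, seed = 1) {
  stopifnot(is.null(w_energy) || w_energy >= 0,
            is.null(w_force) || w_force >= 0,
            lambda_reg >= 0, n_iterations >= 1, batch_size >= 1)
  structure(list(w_energy = w_energy, w_force = w_force,
                 lambda_reg = lambda_reg,
                 n_iterations = as.integer(n_iterations),
                 batch_size = as.integer(batch_size),
                 train_T = train_T, test_T = test_T,
                 stride = as.integer(stride), max_step = max_step,
                 maxit = as.integer(maxit), seed = as.integer(seed)),
            class = "hf_fit_config")
}

resolve_weights <- function(cfg, n_confs, n_atoms) {
  list(wE = if (is.null(cfg$w_energy)) 1 / n_confs else cfg$w_energy,
       wF = if (is.null(cfg$w_force)) 1 / (3 * n_atoms * n_confs) else cfg$w_force)
}

# gamma entries live on a circle: wrap differences to (-pi, pi]
wrap_gamma_diff <- function(d, params) {
  nb <- nrow(params$bonds); na <- nrow(params$angles); nt <- nrow(params$torsions)
  idx <- 2 * nb + 2 * na + nt + seq_len(nt)
  d[idx] <- ((d[idx] + pi) %% (2 * pi)) - pi
  d
}

fm_loss_core <- function(theta, cs, params, mats, Eref, wE, wF, lambda,
                         theta0, scales) {
  parts <- .hf_fm_parts(cs$sys, theta, mats$confs,
                        if (wF > 0) mats$Fref else NULL)
  eres <- parts$energies - Eref
  eres <- eres - mean(eres)  # energy offset Delta profiled out analytically
  d <- wrap_gamma_diff(theta - theta0, params) / scales
  loss <- wE * sum(eres^2) + wF * parts$floss + lambda * sum(d^2)
  grad <- 2 * wE * as.numeric(parts$dE %*% eres) + 2 * lambda * d / scales
  if (wF > 0) grad <- grad + wF * parts$gF
  list(value = loss, gradient = grad,
       energy_ss = sum(eres^2), force_ss = parts$floss)
}

#' Force-matching loss and its analytic gradient
#'
#' `L = w_E sum_c (E_theta(c) - E_ref(c) - Delta)^2
#'    + w_F sum_c |F_theta(c) - F_ref(c)|_F^2
#'    + lambda |(theta - theta0)/s|^2`,
#' where `Delta` (the incommensurate QM/MM energy zero) is profiled out
#' analytically as the mean energy residual, and `s` are per-parameter
#' natural scales (100 kcal/mol/A^2 for bond k, 0.1 A for r0, 50
#' kcal/mol/rad^2 for angle k, 5 deg for theta0, 1 kcal/mol for barriers,
#' 1 rad for phases) making `lambda` dimensionless. `theta` packs only the
#' bonded parameters (bond k, r0; angle k, theta0; torsion V, gamma);
#' periodicities, vdW, charges and 1-4 scalings stay frozen.
#'
#' @param theta packed parameter vector (see [pack_parameters()]).
#' @param topology an [topology()] object.
#' @param params the [parameter_set()] defining the packing map and the
#'   frozen non-bonded terms.
#' @param data an [reference_dataset()].
#' @param cfg an [fit_config()] (weights, lambda).
#' @param theta0 restraint center (defaults to `pack_parameters(params)`).
#' @param charges optional per-atom charges.
#' @return list with `value`, `gradient`, `energy_ss`, `force_ss`.
#' @export
fm_loss <- function(theta, topology, params, data, cfg = fit_config(),
                    theta0 = NULL, charges = NULL) {
  cs <- compile_system(topology, params, charges)
  if (is.null(theta0)) theta0 <- cs$theta
  if (length(theta) != length(cs$theta))
    stop(sprintf("theta length %d does not match the packing map (%d)",
                 length(theta), length(cs$theta)))
  mats <- dataset_matrices(data)
  w <- resolve_weights(cfg, length(data$confs), nrow(topology$atoms))
  fm_loss_core(theta, cs, params, mats, data$energies, w$wE, w$wF,
               cfg$lambda_reg, theta0, theta_scales(params))
}

#' Pack / unpack the bonded parameters of a parameter set
#'
#' The refit's optimization vector: `[bond k | bond r0 | angle k |
#' angle theta0 (rad) | torsion V | torsion gamma (rad)]`, rows in the
#' order they appear in the parameter tables.
#'
#' @param params an [parameter_set()].
#' @param theta packed vector to write back.
#' @return numeric vector ([pack_parameters()]) or updated parameter set
#'   ([unpack_parameters()]).
#' @export
pack_parameters <- function(params) pack_theta(params)

#' @rdname pack_parameters
#' @export
unpack_parameters <- function(theta, params) unpack_theta(theta, params)

# The optimizer works in Fourier torsion coordinates a = (V/2) cos gamma,
# b = (V/2) sin gamma, in which the torsion energy is linear (so the
# torsion block of the loss is convex and phase flips cannot trap the
# optimizer at the V = 0 boundary); V >= 0 holds by construction on the
# way back. Bond/angle entries stay as scaled (k, r0, theta0).
theta_split <- function(params) {
  nb <- nrow(params$bonds); na <- nrow(params$angles); nt <- nrow(params$torsions)
  list(nb = nb, na = na, nt = nt, harm = seq_len(2 * nb + 2 * na),
       vidx = 2 * nb + 2 * na + seq_len(nt),
       gidx = 2 * nb + 2 * na + nt + seq_len(nt))
}

ab_from_theta <- function(theta, sp) {
  v <- theta[sp$vidx]; g <- theta[sp$gidx]
  # the origin (V = 0) is a coordinate singularity with a vanishing
  # chain-rule gradient; nudge exactly-zero barriers off it so explicit
  # null terms can re-acquire amplitude during optimization
  v <- pmax(v, 1e-6)
  c(theta[sp$harm], v / 2 * cos(g), v / 2 * sin(g))
}

theta_from_ab <- function(z, sp) {
  a <- z[sp$vidx]; b <- z[sp$gidx]
  r <- sqrt(a^2 + b^2)
  c(z[sp$harm], 2 * r, atan2(b, a))
}

# chain rule: gradient w.r.t. (V, gamma) -> gradient w.r.t. (a, b)
grad_ab <- function(gtheta, z, sp) {
  a <- z[sp$vidx]; b <- z[sp$gidx]
  r <- pmax(sqrt(a^2 + b^2), 1e-12)
  gV <- gtheta[sp$vidx]; gG <- gtheta[sp$gidx]
  c(gtheta[sp$harm],
    gV * 2 * a / r - gG * b / r^2,
    gV * 2 * b / r + gG * a / r^2)
}

theta_bounds <- function(params) {
  nb <- nrow(params$bonds); na <- nrow(params$angles); nt <- nrow(params$torsions)
  list(lower = c(rep(0, nb), rep(0.5, nb),
                 rep(0, na), rep(5 * pi / 180, na),
                 rep(0, nt), rep(-Inf, nt)),
       upper = c(rep(Inf, nb), rep(3, nb),
                 rep(Inf, na), rep(175 * pi / 180, na),
                 rep(Inf, nt), rep(Inf, nt)))
}

#' Refit bonded parameters against a labelled dataset
#'
#' Bounded quasi-Newton (L-BFGS-B) minimization of [fm_loss()] with
#' physical bounds (k >= 0, V >= 0, r0 and theta0 boxed), warm-started at
#' `params`, restrained to `restraint_center`. Converges on projected
#' gradient or after `cfg$maxit` iterations; the returned loss never
#' exceeds the starting loss.
#'
#' @param params starting [parameter_set()] (also the packing map).
#' @param topology an [topology()] object.
#' @param data an [reference_dataset()] (non-empty).
#' @param cfg an [fit_config()].
#' @param restraint_center parameter set the L2 restraint pulls toward
#'   (default: `params`).
#' @param charges optional per-atom charges.
#' @return list of class `hf_fit`: `params` (optimized), `theta`, `loss`,
#'   `initial_loss`, `convergence`, `counts`.
#' @export
optimize_bonded <- function(params, topology, data, cfg = fit_config(),
                            restraint_center = params, charges = NULL) {
  if (!length(data$confs)) stop("reference dataset is empty")
  cs <- compile_system(topology, params, charges)
  mats <- dataset_matrices(data)
  w <- resolve_weights(cfg, length(data$confs), nrow(topology$atoms))
  scales <- theta_scales(params)
  theta0 <- pack_theta(restraint_center)
  if (length(theta0) != length(cs$theta))
    stop("restraint center has a different packing map than params")
  f0 <- fm_loss_core(cs$theta, cs, params, mats, data$energies,
                     w$wE, w$wF, cfg$lambda_reg, theta0, scales)
  if (!is.finite(f0$value)) {
    bad <- which(!is.finite(.hf_fm_parts(cs$sys, cs$theta, mats$confs, NULL)$energies))
    stop("non-finite loss at the starting parameters (configuration ",
         if (length(bad)) bad[1] else "?", ")")
  }
  bounds <- theta_bounds(params)
  sp <- theta_split(params)
  # scaled Fourier coordinates: harmonic entries theta/s, torsions (a, b)
  to_z <- function(theta) {
    ab <- ab_from_theta(theta, sp)
    c(ab[sp$harm] / scales[sp$harm], ab[c(sp$vidx, sp$gidx)])
  }
  from_z <- function(z) {
    ab <- c(z[sp$harm] * scales[sp$harm], z[c(sp$vidx, sp$gidx)])
    theta_from_ab(ab, sp)
  }
  z0 <- to_z(theta0)
  # optim calls fn and gr at the same point back to back: cache one eval
  cache <- new.env(parent = emptyenv())
  eval_at <- function(z) {
    if (!is.null(cache$z) && identical(cache$z, z)) return(cache$res)
    theta <- from_z(z)
    core <- fm_loss_core(theta, cs, params, mats, data$energies,
                         w$wE, w$wF, 0, theta0, scales)
    # restraint applied in the smooth scaled coordinates
    value <- core$value + cfg$lambda_reg * sum((z - z0)^2)
    gth <- grad_ab(core$gradient, c(z[sp$harm] * scales[sp$harm],
                                    z[c(sp$vidx, sp$gidx)]), sp)
    grad <- c(gth[sp$harm] * scales[sp$harm], gth[c(sp$vidx, sp$gidx)]) +
      2 * cfg$lambda_reg * (z - z0)
    cache$z <- z
    cache$res <- list(value = value, gradient = grad)
    cache$res
  }
  lower <- c(bounds$lower[sp$harm] / scales[sp$harm],
             rep(-Inf, 2 * sp$nt))
  upper <- c(bounds$upper[sp$harm] / scales[sp$harm],
             rep(Inf, 2 * sp$nt))
  zstart <- to_z(cs$theta)
  f0z <- eval_at(zstart)$value
  opt <- stats::optim(zstart, function(z) eval_at(z)$value,
                      function(z) eval_at(z)$gradient,
                      method = "L-BFGS-B", lower = lower, upper = upper,
                      control = list(maxit = cfg$maxit, pgtol = 1e-6,
                                     factr = 1e7))
  theta_opt <- from_z(opt$par)
  loss <- opt$value
  if (loss > f0z) {  # never accept an uphill "optimum"
    theta_opt <- cs$theta
    loss <- f0z
  }
  structure(list(params = unpack_theta(theta_opt, params),
                 theta = theta_opt, loss = loss, initial_loss = f0$value,
                 convergence = opt$convergence, counts = opt$counts),
            class = "hf_fit")
}

#' Wrap a parameter set as a reference oracle
#'
#' Returns a function mapping a list of configurations to reference
#' energies and forces computed with the MM engine under `params` — the
#' stand-in for an ab initio reference Hamiltonian in synthetic
#' parameter-recovery studies.
#'
#' @param topology an [topology()] object.
#' @param params the ground-truth [parameter_set()].
#' @param charges optional per-atom charges.
#' @return function(list of confs) -> list(energies, forces).
#' @export
mm_oracle <- function(topology, params, charges = NULL) {
  cs <- compile_system(topology, params, charges)
  label <- paste0("mm:", params$label)
  function(confs) {
    if (inherits(confs, "hf_trajectory")) confs <- confs$frames
    if (is.matrix(confs)) confs <- list(confs)
    out <- .hf_batch_eval(cs$sys, cs$theta, confs_to_matrix(confs), TRUE)
    list(energies = out$energies,
         forces = lapply(seq_along(confs),
                         function(i) forces_from_flat(out$forces[, i])),
         provenance = label)
  }
}

label_with_oracle <- function(confs, oracle) {
  lab <- oracle(confs)
  ok <- is.finite(lab$energies) &
    vapply(lab$forces, function(f) all(is.finite(f)), TRUE)
  list(confs = confs[ok], energies = lab$energies[ok],
       forces = lab$forces[ok], n_bad = sum(!ok),
       provenance = if (!is.null(lab$provenance)) lab$provenance else "oracle")
}

#' Adaptive force-matching refit
#'
#' The full data-accumulation loop: each iteration samples `batch_size`
#' configurations at `train_T` under the *current* parameters (continuing
#' from the last frame of the previous iteration), labels them with the
#' reference oracle, appends them to the training set, and re-optimizes
#' the bonded parameters warm-started from the current values while the L2
#' restraint stays centered on the original starting set. After the last
#' iteration a fresh test set is sampled at `test_T` under the final
#' parameters and labelled with the oracle; train/test energy and force
#' error reports are computed for the starting and final parameter sets.
#'
#' @param topology an [topology()] object.
#' @param start_params starting (transferable-like) [parameter_set()];
#'   also the restraint center.
#' @param oracle function(list of confs) -> list(energies, forces), e.g.
#'   [mm_oracle()]. Configurations the oracle fails on (non-finite output)
#'   are dropped with a warning and replacements are sampled.
#' @param start_conf starting configuration.
#' @param cfg an [fit_config()].
#' @param charges optional per-atom charges.
#' @param test_size test-set size (default `cfg$batch_size`).
#' @return list of class `hf_fit_result`: `params_opt`, `params_start`,
#'   `loss_history`, `dataset_size_history`, `train_errors` /
#'   `test_errors` (each a list `before` / `after` of [energy_errors()] +
#'   aggregate force RMSE), `train_data`, `test_data`.
#' @export
adaptive_refit <- function(topology, start_params, oracle, start_conf,
                           cfg = fit_config(), charges = NULL,
                           test_size = NULL) {
  if (is.null(test_size)) test_size <- cfg$batch_size
  params <- start_params
  conf <- check_configuration(start_conf, topology)
  confs <- list(); energies <- numeric(0); forces <- list()
  loss_history <- numeric(cfg$n_iterations)
  size_history <- integer(cfg$n_iterations)
  provenance <- "oracle"
  for (k in seq_len(cfg$n_iterations)) {
    batch <- sample_labelled_batch(topology, params, conf, oracle,
                                   cfg$batch_size, cfg$train_T, cfg,
                                   seed = cfg$seed + k, charges = charges)
    conf <- batch$confs[[length(batch$confs)]]
    confs <- c(confs, batch$confs)
    energies <- c(energies, batch$energies)
    forces <- c(forces, batch$forces)
    provenance <- batch$provenance
    data_k <- reference_dataset(confs, energies, forces, provenance)
    fit <- optimize_bonded(params, topology, data_k, cfg,
                           restraint_center = start_params, charges = charges)
    params <- fit$params
    loss_history[k] <- fit$loss
    size_history[k] <- length(confs)
  }
  train_data <- reference_dataset(confs, energies, forces, provenance)
  test_batch <- sample_labelled_batch(topology, params, conf, oracle,
                                      test_size, cfg$test_T, cfg,
                                      seed = cfg$seed + cfg$n_iterations + 1,
                                      charges = charges)
  test_data <- reference_dataset(test_batch$confs, test_batch$energies,
                                 test_batch$forces, provenance)
  report <- function(p, d) {
    ee <- energy_errors(topology, p, d, charges = charges)
    fe <- force_error_matrix(topology, p, d, charges = charges)
    c(ee, force_rmse = unname(fe$force_rmse))
  }
  structure(list(
    params_opt = params, params_start = start_params,
    loss_history = loss_history, dataset_size_history = size_history,
    train_errors = list(before = report(start_params, train_data),
                        after = report(params, train_data)),
    test_errors = list(before = report(start_params, test_data),
                       after = report(params, test_data)),
    train_data = train_data, test_data = test_data),
    class = "hf_fit_result")
}

#' @export
print.hf_fit_result <- function(x, ...) {
  cat(sprintf("hf_fit_result: %d iterations, final training set %d configs\n",
              length(x$loss_history), tail(x$dataset_size_history, 1)))
  cat(sprintf("  test energy RMSE %.4f -> %.4f kcal/mol | force RMSE %.4f -> %.4f kcal/mol/A\n",
              x$test_errors$before["rmse"], x$test_errors$after["rmse"],
              x$test_errors$before["force_rmse"],
              x$test_errors$after["force_rmse"]))
  invisible(x)
}

sample_labelled_batch <- function(topology, params, conf, oracle, n_needed,
                                  temperature, cfg, seed, charges = NULL,
                                  max_tries = 5) {
  confs <- list(); energies <- numeric(0); forces <- list()
  provenance <- "oracle"
  tries <- 0
  while (length(confs) < n_needed && tries < max_tries) {
    tries <- tries + 1
    scfg <- sampler_config(temperature, n_needed - length(confs),
                           stride = cfg$stride, max_step = cfg$max_step,
                           seed = seed + 1000L * (tries - 1L))
    traj <- metropolis_sample(topology, params, conf, scfg, charges = charges)
    conf <- traj$frames[[length(traj$frames)]]
    lab <- label_with_oracle(traj$frames, oracle)
    if (lab$n_bad > 0)
      warning(sprintf("oracle failed on %d configuration(s); resampling replacements",
                      lab$n_bad))
    confs <- c(confs, lab$confs)
    energies <- c(energies, lab$energies)
    forces <- c(forces, lab$forces)
    provenance <- lab$provenance
  }
  if (length(confs) < n_needed)
    stop("could not assemble a labelled batch: oracle keeps failing")
  list(confs = confs, energies = energies, forces = forces,
       provenance = provenance)
}
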