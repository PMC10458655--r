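#' Thermal energy k_B T
#'
#' @param T temperature in K (> 0).
#' @return k_B T in kcal/mol (k_B = 1.987204e-3 kcal/mol/K). At 298 K this
#'   is ~0.59 kcal/mol, the usual yardstick for "soft" torsional barriers.
#' @export
thermal_energy <- function(T) {
  if (any(T <= 0)) stop("temperature must be > 0 K")
  KB_KCAL * T
}

#' Sampler configuration
#'
#' @param temperature K.
#' @param n_samples frames to retain.
#' @param stride Monte Carlo sweeps between retained frames (the desk-scale
#'   stand-in for a sampling interval in ps).
#' @param max_step initial Gaussian trial-move size (A); auto-tuned during
#'   burn-in toward ~40% acceptance unless `tune = FALSE`.
#' @param seed integer RNG seed.
#' @param burnin_sweeps discarded equilibration sweeps; default
#'   `10 * n_atoms` (resolved at run time when `NULL`).
#' @param tune logical, adapt `max_step` during burn-in.
#' @return list of class `hf_sampler_config`.
#' @export
sampler_config <- function(temperature, n_samples, stride = 10,
                           max_step = 0.05, seed = 1,
                           burnin_sweeps = NULL, tune = TRUE) {
  stopifnot(temperature > 0, n_samples >= 1, stride >= 1, max_step > 0)
  structure(list(temperature = temperature, n_samples = n_samples,
                 stride = as.integer(stride), max_step = max_step,
                 seed = as.integer(seed), burnin_sweeps = burnin_sweeps,
                 tune = isTRUE(tune)),
            class = "hf_sampler_config")
}

#' Metropolis Monte Carlo configurational sampling
#'
#' Gas-phase canonical sampling with single-atom Gaussian displacement
#' trials and Metropolis acceptance min(1, exp(-dE/kT)). One sweep is
#' n_atoms trials; `cfg$stride` sweeps separate retained frames. Burn-in
#' (default 10 x n_atoms sweeps) is discarded, and the trial step is tuned
#' toward ~40% acceptance during burn-in. Trials that blow the energy up
#' (atom collisions) are simply rejected. Deterministic for a fixed seed.
#'
#' @param topology an [topology()] object.
#' @param params an [parameter_set()] object.
#' @param start n_atoms x 3 starting configuration (Angstrom) with finite
#'   energy.
#' @param cfg an [sampler_config()].
#' @param charges optional per-atom charges (defaults to the topology's).
#' @return an [trajectory()] with `cfg$n_samples` frames; attributes
#'   `acceptance` (production acceptance ratio), `energies` (per-frame
#'   potential energies, kcal/mol) and `max_step` (tuned step size).
#' @export
metropolis_sample <- function(topology, params, start, cfg, charges = NULL) {
  start <- check_configuration(start, topology)
  stopifnot(inherits(cfg, "hf_sampler_config"))
  cs <- compile_system(topology, params, charges)
  n <- nrow(topology$atoms)
  burn <- if (is.null(cfg$burnin_sweeps)) 10L * n else as.integer(cfg$burnin_sweeps)
  kT <- thermal_energy(cfg$temperature)
  set.seed(cfg$seed)
  out <- .hf_mc_sample(cs$sys, cs$theta, as.numeric(t(start)),
                       cfg$n_samples, cfg$stride, kT, burn,
                       cfg$max_step, cfg$tune)
  frames <- lapply(seq_len(ncol(out$frames)),
                   function(i) forces_from_flat(out$frames[, i]))
  traj <- trajectory(frames, topology$atoms$element,
                     times = seq_len(cfg$n_samples) * cfg$stride,
                     stride = cfg$stride)
  attr(traj, "acceptance") <- out$acceptance
  attr(traj, "energies") <- out$energies
  attr(traj, "max_step") <- out$max_step
  traj
}

#' Number of frames a sampling length yields
#'
#' @param duration sampling length (ps).
#' @param interval sampling interval (ps).
#' @return `floor(duration / interval)`; e.g. 5 ns at 10 ps intervals gives
#'   500 configurations, and 18 such blocks give 9000.
#' @export
frame_count <- function(duration, interval) {
  stopifnot(duration > 0, interval > 0)
  as.integer(floor(duration / interval))
}
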