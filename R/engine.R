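# Engine front end: resolves type keys to flat term arrays once, then calls
# the compiled kernels. All energies kcal/mol, forces kcal/mol/A.

compile_system <- function(topology, params, charges = NULL) {
  issues <- validate_system(topology, params)
  if (length(issues))
    stop("parameter set does not resolve against topology:\n  ",
         paste(issues, collapse = "\n  "))
  if (is.null(charges)) charges <- topology$atoms$charge
  n <- nrow(topology$atoms)
  stopifnot(length(charges) == n)
  keys <- topology_type_keys(topology)

  bond_t <- match(keys$bond, params$bonds$type_key) - 1L
  angle_t <- match(keys$angle, params$angles$type_key) - 1L

  # expand each topology torsion into one instance per Fourier component
  tor <- topology$torsions
  ti <- tj <- tk <- tl <- tc <- integer(0)
  if (nrow(tor)) {
    rows_by_key <- split(seq_len(nrow(params$torsions)), params$torsions$type_key)
    comp_rows <- rows_by_key[keys$torsion]
    len <- lengths(comp_rows)
    rep_idx <- rep(seq_len(nrow(tor)), len)
    ti <- tor[rep_idx, 1] - 1L; tj <- tor[rep_idx, 2] - 1L
    tk <- tor[rep_idx, 3] - 1L; tl <- tor[rep_idx, 4] - 1L
    tc <- unlist(comp_rows, use.names = FALSE) - 1L
  }

  # nonbonded pair list: all pairs minus exclusions; 1-4 scaled
  all_pairs <- t(utils::combn(n, 2))
  pkey <- paste(all_pairs[, 1], all_pairs[, 2])
  excl <- paste(topology$exclusions[, 1], topology$exclusions[, 2])
  keep <- !(pkey %in% excl)
  nb <- all_pairs[keep, , drop = FALSE]
  is14 <- paste(nb[, 1], nb[, 2]) %in%
    paste(topology$pairs14[, 1], topology$pairs14[, 2])
  vrow <- match(topology$atoms$type_label, params$vdw$type)
  rh <- params$vdw$rmin_half[vrow]
  ep <- params$vdw$epsilon[vrow]
  i <- nb[, 1]; j <- nb[, 2]
  qq <- COULOMB_KCAL * charges[i] * charges[j] / ifelse(is14, params$scee, 1)
  eps <- sqrt(ep[i] * ep[j]) / ifelse(is14, params$scnb, 1)
  rmin <- rh[i] + rh[j]

  list(sys = list(
         natoms = n,
         bond_i = topology$bonds[, 1] - 1L, bond_j = topology$bonds[, 2] - 1L,
         bond_t = bond_t,
         angle_i = topology$angles[, 1] - 1L, angle_j = topology$angles[, 2] - 1L,
         angle_k = topology$angles[, 3] - 1L, angle_t = angle_t,
         tor_i = ti, tor_j = tj, tor_k = tk, tor_l = tl, tor_c = tc,
         comp_n = as.integer(params$torsions$n),
         nb_i = i - 1L, nb_j = j - 1L,
         nb_qq = qq, nb_eps = eps, nb_rmin = rmin,
         n_bond_types = nrow(params$bonds),
         n_angle_types = nrow(params$angles),
         n_tor_comps = nrow(params$torsions)),
       theta = pack_theta(params))
}

# theta layout: [bond k | bond r0 | angle k | angle theta0(rad) |
#               torsion V | torsion gamma(rad)]
pack_theta <- function(params) {
  c(params$bonds$k, params$bonds$r0,
    params$angles$k, params$angles$theta0 * pi / 180,
    params$torsions$v, params$torsions$gamma * pi / 180)
}

unpack_theta <- function(theta, params) {
  nb <- nrow(params$bonds); na <- nrow(params$angles); nt <- nrow(params$torsions)
  stopifnot(length(theta) == 2 * nb + 2 * na + 2 * nt)
  off <- 0
  params$bonds$k <- theta[off + seq_len(nb)]; off <- off + nb
  params$bonds$r0 <- theta[off + seq_len(nb)]; off <- off + nb
  params$angles$k <- theta[off + seq_len(na)]; off <- off + na
  params$angles$theta0 <- theta[off + seq_len(na)] * 180 / pi; off <- off + na
  params$torsions$v <- theta[off + seq_len(nt)]; off <- off + nt
  params$torsions$gamma <- (theta[off + seq_len(nt)] * 180 / pi) %% 360
  params
}

# per-parameter natural scales making the refit restraint dimensionless
theta_scales <- function(params) {
  nb <- nrow(params$bonds); na <- nrow(params$angles); nt <- nrow(params$torsions)
  c(rep(100, nb), rep(0.1, nb),
    rep(50, na), rep(5 * pi / 180, na),
    rep(1, nt), rep(1, nt))
}

#' Intramolecular energy, decomposed by term class
#'
#' Evaluates the AMBER-style potential on one configuration and returns the
#' bond, angle, torsion, Lennard-Jones and Coulomb contributions plus their
#' sum. Gas phase: every non-excluded pair is summed exactly, no cutoff.
#'
#' @param topology an [topology()] object.
#' @param params an [parameter_set()] resolving every term in `topology`.
#' @param conf n_atoms x 3 coordinate matrix (Angstrom).
#' @param charges per-atom charges (e); defaults to `topology$atoms$charge`.
#' @return named numeric vector `bond, angle, torsion, lj, coulomb, total`
#'   (kcal/mol).
#' @seealso [forces()] for the analytic negative gradient.
#' @export
energy_components <- function(topology, params, conf, charges = NULL) {
  conf <- check_configuration(conf, topology)
  cs <- compile_system(topology, params, charges)
  out <- .hf_energy_forces(cs$sys, cs$theta, as.numeric(t(conf)), FALSE)
  comps <- out$components
  c(comps, total = sum(comps))
}

#' Total intramolecular energy
#'
#' @inheritParams energy_components
#' @return scalar energy in kcal/mol.
#' @export
total_energy <- function(topology, params, conf, charges = NULL) {
  unname(energy_components(topology, params, conf, charges)["total"])
}

#' Analytic atomic forces
#'
#' Forces are the exact negative gradient of [total_energy()]; they sum to
#' zero and carry zero net torque for any isolated configuration.
#'
#' @inheritParams energy_components
#' @return n_atoms x 3 matrix, kcal/mol/A.
#' @export
forces <- function(topology, params, conf, charges = NULL) {
  conf <- check_configuration(conf, topology)
  cs <- compile_system(topology, params, charges)
  out <- .hf_energy_forces(cs$sys, cs$theta, as.numeric(t(conf)), TRUE)
  matrix(out$forces, ncol = 3, byrow = TRUE)
}

# batch energies/forces on a trajectory or list of configurations
batch_eval <- function(cs, confs, want_forces = FALSE) {
  mat <- confs_to_matrix(confs)
  .hf_batch_eval(cs$sys, cs$theta, mat, want_forces)
}

# stack configurations into the column-per-frame layout the kernels use
confs_to_matrix <- function(confs) {
  if (is.matrix(confs) && ncol(confs) != 3) return(confs)  # already stacked
  if (is.matrix(confs)) confs <- list(confs)
  if (inherits(confs, "hf_trajectory")) confs <- confs$frames
  vapply(confs, function(f) as.numeric(t(f)), numeric(3 * nrow(confs[[1]])))
}

forces_from_flat <- function(v) matrix(v, ncol = 3, byrow = TRUE)

#' Minimize the intramolecular energy of a configuration
#'
#' L-BFGS-B on the Cartesian coordinates with analytic forces. Intended
#' for relaxing embedded starting geometries before sampling.
#'
#' @inheritParams energy_components
#' @param maxit iteration cap (default 2000).
#' @return list: `conf` (minimized coordinates), `energy`, `convergence`.
#' @export
minimize_energy <- function(topology, params, conf, charges = NULL,
                            maxit = 2000) {
  conf <- check_configuration(conf, topology)
  cs <- compile_system(topology, params, charges)
  fn <- function(x) .hf_energy_forces(cs$sys, cs$theta, x, FALSE)$energy
  gr <- function(x) -.hf_energy_forces(cs$sys, cs$theta, x, TRUE)$forces
  opt <- stats::optim(as.numeric(t(conf)), fn, gr, method = "L-BFGS-B",
                      control = list(maxit = maxit, factr = 1e5))
  list(conf = forces_from_flat(opt$par), energy = opt$value,
       convergence = opt$convergence)
}
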