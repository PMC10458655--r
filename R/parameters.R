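#' Construct a force-field parameter set
#'
#' Holds the typed bonded and van der Waals parameters of an AMBER-style
#' force field together with the 1-4 scaling divisors. Angles and torsion
#' phases are stored in degrees (the file convention); the engine converts
#' to radians internally.
#'
#' Functional form: bonds \eqn{k(r-r_0)^2}, angles \eqn{k(\theta-\theta_0)^2},
#' torsions \eqn{\sum_n (V_n/2)(1+\cos(n\phi-\gamma_n))}, 12-6 Lennard-Jones
#' with Lorentz-Berthelot combining, Coulomb with constant 332.0637
#' kcal A / (mol e^2). 1-2 and 1-3 pairs are excluded; 1-4 electrostatics
#' and vdW are divided by `scee` and `scnb`.
#'
#' @param bonds data.frame `t1,t2,k,r0` (kcal/mol/A^2, A).
#' @param angles data.frame `t1,t2,t3,k,theta0` (kcal/mol/rad^2, degrees).
#' @param torsions data.frame `t1,t2,t3,t4,v,n,gamma` (kcal/mol, periodicity,
#'   degrees); several rows with distinct `n` form one multi-component term.
#' @param vdw data.frame `type,rmin_half,epsilon` (A, kcal/mol).
#' @param scee,scnb 1-4 electrostatic / vdW divisors (AMBER defaults 1.2, 2.0).
#' @param label provenance string.
#' @return object of class `hf_params`.
#' @export
parameter_set <- function(bonds, angles, torsions, vdw,
                          scee = 1.2, scnb = 2.0, label = "") {
  bonds <- as.data.frame(bonds); angles <- as.data.frame(angles)
  torsions <- as.data.frame(torsions); vdw <- as.data.frame(vdw)
  stopifnot(scee > 0, scnb > 0)
  if (nrow(bonds)) {
    bonds$type_key <- bond_key(bonds$t1, bonds$t2)
    if (anyDuplicated(bonds$type_key)) stop("duplicated bond type")
    if (any(bonds$k < 0)) stop("bond k must be >= 0")
    if (any(bonds$r0 <= 0)) stop("bond r0 must be > 0")
  } else bonds$type_key <- character(0)
  if (nrow(angles)) {
    angles$type_key <- angle_key(angles$t1, angles$t2, angles$t3)
    if (anyDuplicated(angles$type_key)) stop("duplicated angle type")
    if (any(angles$k < 0)) stop("angle k must be >= 0")
    if (any(angles$theta0 <= 0 | angles$theta0 >= 180))
      stop("angle theta0 must lie in (0, 180) degrees")
  } else angles$type_key <- character(0)
  if (nrow(torsions)) {
    torsions$type_key <- torsion_key(torsions$t1, torsions$t2,
                                     torsions$t3, torsions$t4)
    if (any(torsions$v < 0))
      stop("torsion barriers must be >= 0 (flip the phase by 180 deg instead)")
    if (any(torsions$n < 1 | torsions$n != round(torsions$n)))
      stop("torsion periodicity must be a positive integer")
    torsions$n <- as.integer(torsions$n)
    dup <- duplicated(paste(torsions$type_key, torsions$n))
    if (any(dup)) stop("duplicate periodicity within one torsion term")
  } else torsions$type_key <- character(0)
  if (nrow(vdw)) {
    if (anyDuplicated(vdw$type)) stop("duplicated vdW type")
    if (any(vdw$rmin_half <= 0)) stop("vdW rmin_half must be > 0")
    if (any(vdw$epsilon < 0)) stop("vdW epsilon must be >= 0")
  }
  structure(list(bonds = bonds, angles = angles, torsions = torsions,
                 vdw = vdw, scee = scee, scnb = scnb, label = label),
            class = "hf_params")
}

#' @export
print.hf_params <- function(x, ...) {
  cat(sprintf(
    "hf_params '%s': %d bond, %d angle types; %d torsion components; %d vdW types (scee=%g, scnb=%g)\n",
    x$label, nrow(x$bonds), nrow(x$angles), nrow(x$torsions), nrow(x$vdw),
    x$scee, x$scnb))
  invisible(x)
}

# canonical type keys: order-independent within the AMBER wildcardless scheme
bond_key <- function(t1, t2) {
  ifelse(t1 <= t2, paste(t1, t2), paste(t2, t1))
}

angle_key <- function(t1, t2, t3) {
  ifelse(t1 <= t3, paste(t1, t2, t3), paste(t3, t2, t1))
}

torsion_key <- function(t1, t2, t3, t4) {
  fwd <- paste(t1, t2, t3, t4)
  rev <- paste(t4, t3, t2, t1)
  flip <- t2 > t3 | (t2 == t3 & t1 > t4)
  ifelse(flip, rev, fwd)
}

topology_type_keys <- function(topology) {
  lab <- topology$atoms$type_label
  list(
    bond = if (nrow(topology$bonds))
      bond_key(lab[topology$bonds[, 1]], lab[topology$bonds[, 2]]) else character(0),
    angle = if (nrow(topology$angles))
      angle_key(lab[topology$angles[, 1]], lab[topology$angles[, 2]],
                lab[topology$angles[, 3]]) else character(0),
    torsion = if (nrow(topology$torsions))
      torsion_key(lab[topology$torsions[, 1]], lab[topology$torsions[, 2]],
                  lab[topology$torsions[, 3]], lab[topology$torsions[, 4]])
      else character(0))
}

#' Validate a parameter set against a topology
#'
#' Returns issues as data (an empty character vector means the pair is
#' consistent): unresolved bond/angle/torsion type keys, missing vdW types,
#' and basic invariant violations.
#'
#' @param topology an [topology()] object.
#' @param params an [parameter_set()] object.
#' @return character vector of human-readable issues.
#' @export
validate_system <- function(topology, params) {
  issues <- character(0)
  keys <- topology_type_keys(topology)
  miss <- setdiff(unique(keys$bond), params$bonds$type_key)
  for (k in miss) issues <- c(issues, paste("unresolved bond type:", k))
  miss <- setdiff(unique(keys$angle), params$angles$type_key)
  for (k in miss) issues <- c(issues, paste("unresolved angle type:", k))
  miss <- setdiff(unique(keys$torsion), unique(params$torsions$type_key))
  for (k in miss) issues <- c(issues, paste("unresolved torsion type:", k))
  miss <- setdiff(unique(topology$atoms$type_label), params$vdw$type)
  for (k in miss) issues <- c(issues, paste("missing vdW type:", k))
  if (nrow(topology$bonds) &&
      anyDuplicated(paste(topology$bonds[, 1], topology$bonds[, 2])))
    issues <- c(issues, "duplicated bond in topology")
  both <- intersect(paste(topology$exclusions[, 1], topology$exclusions[, 2]),
                    paste(topology$pairs14[, 1], topology$pairs14[, 2]))
  if (length(both))
    issues <- c(issues, "exclusion list overlaps 1-4 pair list")
  issues
}
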