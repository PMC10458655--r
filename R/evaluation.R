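# Evaluation metrics and host-dynamics analyses: offset-profiled energy
# RMSE/MAE, atom-resolved force errors, per-repeating-unit decomposition,
# Kabsch superposition, radius-of-gyration series and state classification.

#' Energy RMSE and MAE of a parameter set against a reference dataset
#'
#' Model and reference energies have incommensurate zeros (MM vs
#' QM-like), so residuals are centered on their mean before the error
#' metrics are taken — the same offset convention the force-matching loss
#' uses.
#'
#' @param topology an [topology()] object.
#' @param params an [parameter_set()].
#' @param data an [reference_dataset()].
#' @param charges optional per-atom charges.
#' @return named numeric `c(rmse=, mae=)` in kcal/mol.
#' @export
energy_errors <- function(topology, params, data, charges = NULL) {
  if (!length(data$confs)) stop("reference dataset is empty")
  cs <- compile_system(topology, params, charges)
  E <- batch_eval(cs, data$confs, want_forces = FALSE)$energies
  r <- E - data$energies
  r <- r - mean(r)
  c(rmse = sqrt(mean(r^2)), mae = mean(abs(r)))
}

#' Per-repeating-unit energy error
#'
#' Decomposes a whole-molecule energy RMSE uniformly over the ring's
#' repeating units; e.g. a 3.7 kcal/mol RMSE over 7 units is 0.5286
#' kcal/mol per unit. Reported to 4 decimals.
#'
#' @param whole_rmse whole-molecule energy RMSE (kcal/mol).
#' @param n_units number of repeating units (>= 1).
#' @return per-unit error in kcal/mol, rounded to 4 decimals.
#' @export
per_unit_error <- function(whole_rmse, n_units) {
  stopifnot(n_units >= 1)
  round(whole_rmse / n_units, 4)
}

#' Atom-resolved force errors
#'
#' Per-configuration, per-atom magnitudes of the force deviation vector
#' `|F_model(c,i) - F_ref(c,i)|`, arranged as an n_confs x n_atoms matrix
#' whose columns follow a display permutation: `"element"` puts nitrogen
#' atoms first and oxygen atoms last (the backbone-vs-portal layout),
#' `"unit"` orders atoms by repeating unit, `"none"` keeps input order; a
#' custom integer permutation is also accepted. Aggregate errors are
#' reported under three conventions, since "kcal/(mol A atom)" is
#' ambiguous: `force_rmse` (RMS over Cartesian components, the default
#' headline number), `force_rmse_atom` (RMS of per-atom deviation
#' magnitudes) and `force_mean_abs` (mean deviation magnitude).
#'
#' @inheritParams energy_errors
#' @param grouping `"element"`, `"unit"`, `"none"` or an integer
#'   permutation of the atom indices.
#' @return list of class `hf_error_report`: `per_atom_force_error`,
#'   `atom_order`, `force_rmse`, `force_rmse_atom`, `force_mean_abs`.
#' @export
force_error_matrix <- function(topology, params, data, grouping = "element",
                               charges = NULL) {
  if (!length(data$confs)) stop("reference dataset is empty")
  cs <- compile_system(topology, params, charges)
  n <- nrow(topology$atoms)
  out <- batch_eval(cs, data$confs, want_forces = TRUE)
  Fref <- vapply(data$forces, function(f) as.numeric(t(f)), numeric(3 * n))
  D <- out$forces - Fref  # 3n x n_confs
  comp_ss <- sum(D^2)
  # per-atom vector deviation magnitudes: rows atoms, cols confs
  mag <- sqrt(D[seq(1, 3 * n, 3), , drop = FALSE]^2 +
              D[seq(2, 3 * n, 3), , drop = FALSE]^2 +
              D[seq(3, 3 * n, 3), , drop = FALSE]^2)
  ord <- resolve_grouping(grouping, topology)
  structure(list(
    per_atom_force_error = t(mag)[, ord, drop = FALSE],
    atom_order = ord,
    force_rmse = sqrt(comp_ss / (3 * n * length(data$confs))),
    force_rmse_atom = sqrt(mean(mag^2)),
    force_mean_abs = mean(mag)),
    class = "hf_error_report")
}

resolve_grouping <- function(grouping, topology) {
  n <- nrow(topology$atoms)
  if (is.numeric(grouping)) {
    ord <- as.integer(grouping)
    if (!identical(sort(ord), seq_len(n)))
      stop("grouping must be a permutation of the atom indices")
    return(ord)
  }
  el <- topology$atoms$element
  switch(match.arg(grouping, c("element", "unit", "none")),
    element = c(which(el == "N"),
                which(el != "N" & el != "O"),
                which(el == "O")),
    unit = order(topology$atoms$unit_id, seq_len(n)),
    none = seq_len(n))
}

#' Radius-of-gyration time series
#'
#' Per frame, `Rg = sqrt( sum_i m_i |r_i - r_cm|^2 / sum_i m_i )` — the
#' order parameter separating opened from squashed host cavities.
#'
#' @param traj an [trajectory()] object.
#' @param masses per-atom masses (amu); defaults to element masses.
#' @return object of class `hf_rg_series`: list with `times` (ps),
#'   `values` (A) and optional per-frame `labels`.
#' @export
radius_of_gyration <- function(traj, masses = NULL) {
  stopifnot(inherits(traj, "hf_trajectory"))
  if (is.null(masses)) masses <- element_property(traj$elements, "mass")
  if (any(masses <= 0)) stop("masses must be positive")
  w <- masses / sum(masses)
  vals <- vapply(traj$frames, function(m) {
    cm <- colSums(m * w)
    sqrt(sum(w * rowSums(sweep(m, 2, cm)^2)))
  }, 0)
  rg_series(traj$times, vals)
}

#' @rdname radius_of_gyration
#' @param times frame times (ps).
#' @param values Rg values (A, >= 0).
#' @param labels optional per-frame state ids.
#' @export
rg_series <- function(times, values, labels = NULL) {
  stopifnot(length(times) == length(values), all(values >= 0))
  if (!is.null(labels)) stopifnot(length(labels) == length(values))
  structure(list(times = times, values = values, labels = labels),
            class = "hf_rg_series")
}

#' @export
print.hf_rg_series <- function(x, ...) {
  cat(sprintf("hf_rg_series: %d frames, Rg %.3f +/- %.3f A\n",
              length(x$values), mean(x$values), sd(x$values)))
  invisible(x)
}

#' Kabsch superposition of two configurations
#'
#' Optimal weighted rigid-body superposition (proper rotation + translation,
#' no reflection) of `mobile` onto `reference`, minimizing the weighted
#' RMSD, via SVD of the covariance with determinant sign correction.
#'
#' @param reference,mobile n x 3 coordinate matrices.
#' @param weights per-atom weights (default uniform); e.g. masses, or an
#'   indicator restricted to heavy atoms.
#' @return list: `aligned` (mobile after superposition), `rmsd` (A),
#'   `rotation` (3 x 3), `translation`.
#' @export
kabsch_superpose <- function(reference, mobile, weights = NULL) {
  reference <- as.matrix(reference); mobile <- as.matrix(mobile)
  stopifnot(nrow(reference) == nrow(mobile), ncol(reference) == 3)
  n <- nrow(reference)
  if (is.null(weights)) weights <- rep(1, n)
  w <- weights / sum(weights)
  cr <- colSums(reference * w); cm <- colSums(mobile * w)
  A <- sweep(reference, 2, cr); B <- sweep(mobile, 2, cm)
  H <- t(B * w) %*% A
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- B %*% t(R)
  rmsd <- sqrt(sum(w * rowSums((aligned - A)^2)))
  aligned <- sweep(aligned, 2, cr, "+")
  list(aligned = aligned, rmsd = rmsd, rotation = R,
       translation = cr - as.numeric(R %*% cm))
}

#' Classify conformational states from an Rg series
#'
#' 1-D k-means on the Rg values (deterministic quantile initialization)
#' followed by dwell-time smoothing: runs shorter than `min_dwell` frames
#' are merged into the neighboring state whose mean Rg is closer. States
#' are reported sorted by mean Rg descending, so state 1 is the most
#' opened cavity and the last state the most squashed.
#'
#' @param rg an [rg_series()] or numeric vector of Rg values.
#' @param k_states number of states (1, 2 or 3).
#' @param min_dwell minimum dwell length in frames (default 10).
#' @return list of class `hf_states`: `labels` (per frame, 1 = largest
#'   mean Rg), `occupancy`, `mean_rg` (both length `k_states`).
#' @export
classify_states <- function(rg, k_states = 2, min_dwell = 10) {
  vals <- if (inherits(rg, "hf_rg_series")) rg$values else as.numeric(rg)
  stopifnot(k_states %in% 1:3)
  if (length(unique(vals)) < k_states)
    stop("fewer distinct Rg values than requested states")
  if (k_states == 1) {
    lab <- rep(1L, length(vals))
  } else {
    centers <- matrix(quantile(vals, probs = (seq_len(k_states) - 0.5) / k_states))
    km <- kmeans(vals, centers = centers)
    # relabel clusters by mean Rg descending
    ord <- order(km$centers, decreasing = TRUE)
    lab <- match(km$cluster, ord)
    lab <- smooth_dwell(lab, vals, min_dwell)
  }
  occ <- tabulate(lab, nbins = k_states) / length(lab)
  means <- vapply(seq_len(k_states),
                  function(s) if (any(lab == s)) mean(vals[lab == s]) else NA_real_,
                  0)
  structure(list(labels = lab, occupancy = occ, mean_rg = means),
            class = "hf_states")
}

smooth_dwell <- function(lab, vals, min_dwell) {
  if (min_dwell <= 1) return(lab)
  repeat {
    r <- rle(lab)
    if (length(r$lengths) <= 1) break
    short <- which(r$lengths < min_dwell)
    if (!length(short)) break
    s <- short[which.min(r$lengths[short])]
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    seg_mean <- mean(vals[starts[s]:ends[s]])
    nb <- c(if (s > 1) r$values[s - 1], if (s < length(r$values)) r$values[s + 1])
    nb_means <- vapply(nb, function(st) mean(vals[lab == st]), 0)
    lab[starts[s]:ends[s]] <- nb[which.min(abs(nb_means - seg_mean))]
  }
  lab
}

#' @export
print.hf_states <- function(x, ...) {
  for (s in seq_along(x$occupancy))
    cat(sprintf("state %d: occupancy %.3f, mean Rg %.3f A\n",
                s, x$occupancy[s], x$mean_rg[s]))
  invisible(x)
}
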