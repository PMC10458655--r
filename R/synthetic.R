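# Synthetic fixtures emulating the statistical structure of macrocyclic
# hosts: ring topologies built from a repeating-unit template, ground-truth
# parameter sets standing in for an ab initio reference, calibrated
# perturbations of them ("transferable-like" starting points), ESP test
# cases and stochastic two-state Rg series. Templates are abstract C/N/O/H
# motifs; the point is ring closure, unit repetition and term-class mix,
# not any specific host chemistry.

#' Repeating-unit template
#'
#' A small connected graph of 4-8 atoms with element labels, parameter
#' type labels, per-atom partial charges and two linker attachment points
#' through which consecutive units are bonded into a ring.
#'
#' @param size template size in atoms (4-8); picks one of the built-in
#'   motifs.
#' @return list with `elements`, `type_labels`, `charges`, `bonds`,
#'   `linkers` (length 2), `local_coords` (size x 3, linker axis along x).
#' @export
unit_template <- function(size = 6) {
  templates <- list(
    `4` = list(
      elements = c("C", "N", "C", "O"),
      type_labels = c("cA", "nA", "cB", "oA"),
      charges = c(0.20, -0.35, 0.25, -0.10),
      bonds = rbind(c(1, 2), c(2, 3), c(3, 4)),
      linkers = c(1, 3),
      local_coords = rbind(c(0, 0, 0), c(1.25, 1.00, 0.25),
                           c(2.50, 0, 0), c(3.10, -1.05, 0.55))),
    `5` = list(
      elements = c("C", "C", "N", "C", "O"),
      type_labels = c("cA", "cB", "nA", "cA", "oA"),
      charges = c(0.15, -0.10, -0.30, 0.15, 0.10),
      bonds = rbind(c(1, 2), c(2, 3), c(3, 4), c(2, 5)),
      linkers = c(1, 4),
      local_coords = rbind(c(0, 0, 0), c(1.25, 0.85, 0.10),
                           c(2.30, 0.05, -0.40), c(3.45, 0.60, 0.35),
                           c(1.20, 2.05, -0.55))),
    `6` = list(
      elements = c("C", "C", "C", "O", "N", "H"),
      type_labels = c("cA", "cB", "cC", "oA", "nA", "hA"),
      charges = c(0.18, -0.05, 0.22, -0.38, -0.32, 0.35),
      bonds = rbind(c(1, 2), c(2, 3), c(1, 4), c(2, 5), c(3, 6)),
      linkers = c(1, 3),
      local_coords = rbind(c(0, 0, 0), c(1.25, 0.80, 0.15),
                           c(2.50, 0, 0), c(-0.55, -1.25, 0.30),
                           c(1.25, 2.20, -0.15), c(3.15, -1.10, 0.45))),
    `7` = list(
      elements = c("C", "C", "N", "C", "O", "C", "H"),
      type_labels = c("cA", "cB", "nA", "cC", "oA", "cD", "hA"),
      charges = c(0.12, -0.08, -0.35, 0.30, -0.40, 0.05, 0.36),
      bonds = rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 6), c(4, 5), c(2, 7)),
      linkers = c(1, 6),
      local_coords = rbind(c(0, 0, 0), c(1.20, 0.85, 0.20),
                           c(2.35, 0.10, -0.30), c(3.55, 0.75, 0.20),
                           c(3.60, 2.00, 0.55), c(4.80, 0.05, 0.10),
                           c(1.15, 2.25, 0.40))),
    `8` = list(
      elements = c("C", "C", "C", "N", "O", "C", "H", "H"),
      type_labels = c("cA", "cB", "cC", "nA", "oA", "cD", "hA", "hB"),
      charges = c(0.10, -0.06, 0.24, -0.36, -0.42, 0.02, 0.34, 0.14),
      bonds = rbind(c(1, 2), c(2, 3), c(3, 6), c(2, 4), c(3, 5),
                    c(4, 7), c(6, 8)),
      linkers = c(1, 6),
      local_coords = rbind(c(0, 0, 0), c(1.25, 0.80, 0.10),
                           c(2.50, 0.05, -0.20), c(1.30, 2.20, 0.30),
                           c(2.60, -1.30, -0.60), c(3.75, 0.75, 0.25),
                           c(0.55, 2.95, -0.25), c(4.60, 0.10, 0.85))))
  tpl <- templates[[as.character(size)]]
  if (is.null(tpl)) stop("no built-in template of size ", size)
  tpl
}

#' Ring specification
#'
#' @param n_units repeating-unit count (>= 3); the tunable ring size.
#' @param template an [unit_template()] (default the 6-atom motif).
#' @param charge_per_unit net charge per unit (e); template charges are
#'   shifted uniformly to match.
#' @param seed integer; fixes the small symmetry-breaking jitter of the
#'   embedded geometry.
#' @return list of class `hf_ring_spec`.
#' @export
ring_spec <- function(n_units, template = unit_template(6),
                      charge_per_unit = 0, seed = 1) {
  stopifnot(n_units >= 3)
  if (length(template$linkers) != 2 ||
      template$linkers[1] == template$linkers[2])
    stop("template needs two distinct linker attachment points")
  structure(list(n_units = as.integer(n_units), template = template,
                 charge_per_unit = charge_per_unit, seed = as.integer(seed)),
            class = "hf_ring_spec")
}

#' Build a toy macrocycle
#'
#' Replicates the unit template `n_units` times, closes the ring through
#' linker bonds, derives all bonded term lists from connectivity, and
#' embeds an initial geometry on a circle whose radius grows linearly with
#' the unit count (each unit's local frame is bent around the ring, with a
#' small seeded jitter to break planar symmetry). Type labels repeat
#' across units, so the parameter set is shared by all units — the
#' transferable-force-field structure.
#'
#' @param spec an [ring_spec()].
#' @return list with `topology` ([topology()]) and `conf` (initial
#'   coordinates, Angstrom).
#' @export
build_ring <- function(spec) {
  stopifnot(inherits(spec, "hf_ring_spec"))
  tpl <- spec$template
  s <- length(tpl$elements)
  n <- spec$n_units
  q <- tpl$charges + (spec$charge_per_unit - sum(tpl$charges)) / s
  atoms <- data.frame(
    element = rep(tpl$elements, n),
    type_label = rep(tpl$type_labels, n),
    charge = rep(q, n),
    unit_id = rep(seq_len(n), each = s))
  bonds <- do.call(rbind, lapply(seq_len(n) - 1L, function(u)
    tpl$bonds + u * s))
  linker_bonds <- cbind(
    (seq_len(n) - 1L) * s + tpl$linkers[2],
    (seq_len(n) %% n) * s + tpl$linkers[1])
  top <- topology(atoms, rbind(bonds, linker_bonds), n_units = n)

  # embed: local x runs along the ring arc, local y radially, z axially
  span <- max(tpl$local_coords[, 1]) + 1.5  # unit span + linker bond
  R <- n * span / (2 * pi)
  set.seed(spec$seed)
  conf <- matrix(0, n * s, 3)
  for (u in seq_len(n)) {
    phi0 <- 2 * pi * (u - 1) / n
    for (a in seq_len(s)) {
      lc <- tpl$local_coords[a, ]
      phi <- phi0 + lc[1] / R
      r <- R + lc[2]
      conf[(u - 1) * s + a, ] <- c(r * cos(phi), r * sin(phi), lc[3])
    }
  }
  conf <- conf + matrix(rnorm(length(conf), sd = 0.02), ncol = 3)
  list(topology = top, conf = conf)
}

#' Ground-truth parameter set for a topology
#'
#' Assigns plausible magnitudes to every term class the topology needs —
#' bond k in [250, 400] kcal/mol/A^2 and r0 in [1.0, 1.6] A, angle k in
#' [40, 80] kcal/mol/rad^2 and theta0 in [105, 125] deg, one torsion
#' component per term with periodicity in {1,2,3}, barrier in [0, 3]
#' kcal/mol and phase 0 or 180 deg, vdW from a small per-element table —
#' deterministically per seed. This set plays the role of the reference
#' Hamiltonian in parameter-recovery studies.
#'
#' @param topology an [topology()] object.
#' @param seed integer seed.
#' @return an [parameter_set()] resolving every term of `topology`.
#' @export
ground_truth_params <- function(topology, seed = 1) {
  set.seed(seed)
  keys <- topology_type_keys(topology)
  bk <- unique(keys$bond)
  bd <- do.call(rbind, strsplit(bk, " "))
  bonds <- data.frame(t1 = bd[, 1], t2 = bd[, 2],
                      k = runif(length(bk), 250, 400),
                      r0 = runif(length(bk), 1.0, 1.6))
  ak <- unique(keys$angle)
  ad <- do.call(rbind, strsplit(ak, " "))
  angles <- data.frame(t1 = ad[, 1], t2 = ad[, 2], t3 = ad[, 3],
                       k = runif(length(ak), 40, 80),
                       theta0 = runif(length(ak), 105, 125))
  tk <- unique(keys$torsion)
  td <- do.call(rbind, strsplit(tk, " "))
  torsions <- data.frame(t1 = td[, 1], t2 = td[, 2], t3 = td[, 3],
                         t4 = td[, 4],
                         v = runif(length(tk), 0, 3),
                         n = sample(1:3, length(tk), replace = TRUE),
                         gamma = sample(c(0, 180), length(tk), replace = TRUE))
  vdw_tab <- data.frame(
    element = c("C", "N", "O", "S", "H"),
    rmin_half = c(1.908, 1.824, 1.661, 2.000, 1.387),
    epsilon = c(0.086, 0.170, 0.210, 0.250, 0.0157))
  types <- unique(topology$atoms$type_label)
  el <- topology$atoms$element[match(types, topology$atoms$type_label)]
  row <- match(el, vdw_tab$element)
  vdw <- data.frame(type = types, rmin_half = vdw_tab$rmin_half[row],
                    epsilon = vdw_tab$epsilon[row])
  parameter_set(bonds, angles, torsions, vdw, label = "ground-truth")
}

#' Perturbation specification
#'
#' Emulates the gap between a transferable parameter database and the
#' molecule-specific truth: fractional force-constant jitter, absolute
#' equilibrium-value jitter, and a per-torsion action drawn from
#' {jitter, drop, add} — dropped terms become explicit zero-barrier
#' components (so the functional form is preserved), added terms gain a
#' component with an unused periodicity.
#'
#' @param rel_k fractional force-constant / barrier jitter (default 0.3).
#' @param abs_r0 bond-length jitter (A, default 0.02).
#' @param abs_theta0 equilibrium-angle jitter (deg, default 3).
#' @param prob_drop,prob_add torsion action probabilities (defaults 0.15
#'   each; remainder jitters).
#' @param gamma_flip_prob probability a jittered torsion also flips its
#'   phase by 180 deg (default 0.2).
#' @param seed integer seed.
#' @return list of class `hf_perturb_spec`.
#' @export
perturb_spec <- function(rel_k = 0.3, abs_r0 = 0.02, abs_theta0 = 3,
                         prob_drop = 0.15, prob_add = 0.15,
                         gamma_flip_prob = 0.2, seed = 1) {
  stopifnot(rel_k >= 0, abs_r0 >= 0, abs_theta0 >= 0,
            prob_drop >= 0, prob_add >= 0, prob_drop + prob_add <= 1)
  structure(list(rel_k = rel_k, abs_r0 = abs_r0, abs_theta0 = abs_theta0,
                 prob_drop = prob_drop, prob_add = prob_add,
                 gamma_flip_prob = gamma_flip_prob, seed = as.integer(seed)),
            class = "hf_perturb_spec")
}

#' Perturb a ground-truth parameter set
#'
#' Applies the jitters and torsion actions of `spec`; the result still
#' validates against any topology the truth validates against. A manifest
#' of applied changes is attached as attribute `"manifest"` (data.frame
#' `class`, `type_key`, `action`).
#'
#' @param truth an [parameter_set()].
#' @param spec an [perturb_spec()].
#' @return perturbed [parameter_set()] with a `"manifest"` attribute.
#' @export
perturb_params <- function(truth, spec = perturb_spec()) {
  stopifnot(inherits(spec, "hf_perturb_spec"))
  set.seed(spec$seed)
  ps <- truth
  ps$label <- paste0(truth$label, "-perturbed")
  manifest <- list()
  nb <- nrow(ps$bonds)
  if (nb) {
    ps$bonds$k <- pmax(ps$bonds$k * (1 + spec$rel_k * runif(nb, -1, 1)), 1)
    ps$bonds$r0 <- pmax(ps$bonds$r0 + spec$abs_r0 * runif(nb, -1, 1), 0.6)
    manifest[[length(manifest) + 1]] <- data.frame(
      class = "bond", type_key = ps$bonds$type_key,
      action = if (spec$rel_k > 0 || spec$abs_r0 > 0) "jitter" else "none")
  }
  na <- nrow(ps$angles)
  if (na) {
    ps$angles$k <- pmax(ps$angles$k * (1 + spec$rel_k * runif(na, -1, 1)), 1)
    ps$angles$theta0 <- pmin(pmax(
      ps$angles$theta0 + spec$abs_theta0 * runif(na, -1, 1), 95), 135)
    manifest[[length(manifest) + 1]] <- data.frame(
      class = "angle", type_key = ps$angles$type_key,
      action = if (spec$rel_k > 0 || spec$abs_theta0 > 0) "jitter" else "none")
  }
  tkeys <- unique(ps$torsions$type_key)
  add_rows <- NULL
  for (key in tkeys) {
    rows <- which(ps$torsions$type_key == key)
    u <- runif(1)
    action <- if (u < spec$prob_drop) "drop"
      else if (u < spec$prob_drop + spec$prob_add) "add" else "jitter"
    if (action == "add") {
      free_n <- setdiff(1:3, ps$torsions$n[rows])
      if (!length(free_n)) action <- "jitter"
    }
    if (action == "drop") {
      ps$torsions$v[rows] <- 0
    } else if (action == "add") {
      r1 <- ps$torsions[rows[1], , drop = FALSE]
      r1$v <- runif(1, 0.5, 1.5)
      r1$n <- free_n[1]
      r1$gamma <- sample(c(0, 180), 1)
      add_rows <- rbind(add_rows, r1)
    } else {
      had <- any(ps$torsions$v[rows] > 1e-12)
      ps$torsions$v[rows] <-
        pmax(ps$torsions$v[rows] *
               (1 + spec$rel_k * runif(length(rows), -1, 1)), 0)
      flip <- runif(length(rows)) < spec$gamma_flip_prob
      ps$torsions$gamma[rows] <-
        (ps$torsions$gamma[rows] + 180 * flip) %% 360
      if (!had && spec$rel_k > 0) action <- "none"  # 0 * jitter stays 0
      if (spec$rel_k == 0 && all(!flip)) action <- "none"
    }
    manifest[[length(manifest) + 1]] <- data.frame(
      class = "torsion", type_key = key, action = action)
  }
  if (!is.null(add_rows)) ps$torsions <- rbind(ps$torsions, add_rows)
  attr(ps, "manifest") <- do.call(rbind, manifest)
  ps
}

#' Synthetic ESP fitting case
#'
#' Builds a random non-degenerate geometry, a Merz-Kollman grid and
#' reference potentials computed exactly from known charges, enabling
#' generate-then-fit round trips. `anisotropy > 0` adds the potential of a
#' small off-center point dipole on the first atom — the lone-pair-like
#' anisotropic ESP component that atom-centered charges cannot absorb, so
#' the fitted RRMSE grows with it.
#'
#' @param n_atoms atom count.
#' @param geometry_scale radius of the random-placement sphere (A).
#' @param true_charges known generating charges (default: seeded normal
#'   draws, sd 0.3 e).
#' @param seed integer seed (geometry, grid and default charges).
#' @param anisotropy dipole moment of the off-center contribution (e A).
#' @param density grid density (points/A^2).
#' @return an [esp_case()] with attributes `true_charges` and
#'   `anisotropy`.
#' @export
make_esp_case <- function(n_atoms, geometry_scale = 2.5, true_charges = NULL,
                          seed = 1, anisotropy = 0, density = 1.0) {
  set.seed(seed)
  elements <- c("C", sample(c("C", "N", "O", "H"), n_atoms - 1,
                            replace = TRUE))
  conf <- matrix(NA_real_, n_atoms, 3)
  conf[1, ] <- 0
  for (i in seq_len(n_atoms)[-1]) {
    repeat {
      p <- runif(3, -geometry_scale, geometry_scale)
      if (all(sqrt(rowSums(sweep(conf[seq_len(i - 1), , drop = FALSE],
                                 2, p)^2)) > 1.2)) break
    }
    conf[i, ] <- p
  }
  if (is.null(true_charges)) {
    true_charges <- rnorm(n_atoms, 0, 0.3)
    true_charges <- true_charges - mean(true_charges)  # neutral by default
  }
  stopifnot(length(true_charges) == n_atoms)
  grid <- build_esp_grid(conf, elements, density = density, seed = seed)
  ref <- esp_from_charges(true_charges, conf, grid)
  if (anisotropy > 0) {
    u <- c(1, 0, 0)
    off <- 0.3
    ref <- ref +
      esp_from_charges(c(anisotropy / (2 * off), -anisotropy / (2 * off)),
                       rbind(conf[1, ] + off * u, conf[1, ] - off * u), grid)
  }
  case <- esp_case(conf, elements, grid, ref,
                   total_charge = sum(true_charges))
  attr(case, "true_charges") <- true_charges
  attr(case, "anisotropy") <- anisotropy
  case
}

#' Simulate a multi-state Rg time series
#'
#' Stochastic stand-in for the opened/squashed cavity dynamics: a hidden
#' Markov chain with the requested stationary occupancies and a mean dwell
#' time, emitting Gaussian Rg values per state. Used to exercise
#' [classify_states()] without running long molecular sampling.
#'
#' @param n_frames series length.
#' @param occupancies stationary state weights (sum to 1); first state is
#'   the opened (largest-Rg) one.
#' @param means per-state mean Rg (A), decreasing.
#' @param sds per-state Gaussian widths (A).
#' @param dwell mean dwell time in frames (default 50).
#' @param stride frame interval in ps (default 50, the display convention
#'   for host Rg series).
#' @param seed integer seed.
#' @return an [rg_series()] with true state `labels`.
#' @export
simulate_rg_series <- function(n_frames, occupancies = c(0.6, 0.4),
                               means = c(7.5, 6.2), sds = c(0.15, 0.15),
                               dwell = 50, stride = 50, seed = 1) {
  stopifnot(abs(sum(occupancies) - 1) < 1e-8,
            length(means) == length(occupancies),
            length(sds) == length(occupancies),
            all(diff(means) < 0))
  set.seed(seed)
  k <- length(occupancies)
  rho <- 1 - 1 / dwell
  state <- integer(n_frames)
  state[1] <- sample.int(k, 1, prob = occupancies)
  for (t in seq_len(n_frames)[-1]) {
    state[t] <- if (runif(1) < rho) state[t - 1]
      else sample.int(k, 1, prob = occupancies)
  }
  vals <- rnorm(n_frames, means[state], sds[state])
  vals <- pmax(vals, 0)
  rg_series((seq_len(n_frames) - 1) * stride, vals, labels = state)
}
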