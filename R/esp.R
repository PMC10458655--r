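# Electrostatic-potential machinery: Merz-Kollman-style shell grids,
# point-charge ESP evaluation, restrained (hyperbolic) charge fitting and
# the relative RMSE quality metric. Potentials are kept in e/A throughout;
# multiply by 332.0637 for kcal/mol/e. RRMSE is scale invariant.

#' Build a Merz-Kollman-style ESP grid
#'
#' Places points on nested shells at `shell_scales` times the Bondi vdW
#' radius of each atom using a golden-spiral layout (deterministically
#' rotated per atom/shell from `seed`), then removes any point that falls
#' inside the same-scale surface of another atom.
#'
#' @param conf n_atoms x 3 coordinates (Angstrom).
#' @param elements per-atom element symbols (must have tabulated radii).
#' @param shell_scales shell multipliers (default 1.4, 1.6, 1.8, 2.0).
#' @param density surface point density (points/A^2, default 1.0).
#' @param seed integer; fixes the spiral orientations.
#' @return m x 3 matrix of grid points.
#' @export
build_esp_grid <- function(conf, elements, shell_scales = c(1.4, 1.6, 1.8, 2.0),
                           density = 1.0, seed = 1) {
  conf <- as.matrix(conf)
  radii <- element_property(elements, "vdw_radius")
  set.seed(seed)
  pts <- list()
  for (s in shell_scales) {
    for (i in seq_len(nrow(conf))) {
      r <- s * radii[i]
      npt <- max(8L, ceiling(density * 4 * pi * r^2))
      sphere <- golden_spiral(npt) %*% random_rotation()
      cand <- sweep(sphere * r, 2, conf[i, ], "+")
      # keep points outside the s-scaled surface of every other atom
      keep <- rep(TRUE, nrow(cand))
      for (j in seq_len(nrow(conf))) {
        if (j == i) next
        dj <- sqrt(rowSums(sweep(cand, 2, conf[j, ])^2))
        keep <- keep & dj >= s * radii[j] - 1e-9
      }
      pts[[length(pts) + 1]] <- cand[keep, , drop = FALSE]
    }
  }
  do.call(rbind, pts)
}

golden_spiral <- function(n) {
  i <- seq_len(n) - 0.5
  z <- 1 - 2 * i / n
  rho <- sqrt(pmax(1 - z^2, 0))
  phi <- 2 * pi * i * (1 + sqrt(5)) / 2
  cbind(rho * cos(phi), rho * sin(phi), z)
}

random_rotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed to a proper rotation
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Point-charge electrostatic potential on a grid
#'
#' V(g) = sum_i q_i / |g - r_i|, in e/A.
#'
#' @param charges per-atom charges (e).
#' @param positions n x 3 atom coordinates (Angstrom).
#' @param grid_points m x 3 evaluation points.
#' @return length-m potential vector (e/A).
#' @export
esp_from_charges <- function(charges, positions, grid_points) {
  positions <- as.matrix(positions); grid_points <- as.matrix(grid_points)
  stopifnot(length(charges) == nrow(positions))
  inv_dist_matrix(grid_points, positions) %*% charges |> as.numeric()
}

inv_dist_matrix <- function(grid, pos) {
  m <- nrow(grid); n <- nrow(pos)
  d2 <- outer(rowSums(grid^2), rep(1, n)) + outer(rep(1, m), rowSums(pos^2)) -
    2 * grid %*% t(pos)
  d2 <- pmax(d2, 0)
  if (any(d2 < 1e-12))
    stop("grid point coincident with a nucleus")
  1 / sqrt(d2)
}

#' ESP relative root-mean-squared error
#'
#' 100 * sqrt( sum (V_model - V_ref)^2 / sum V_ref^2 ), in percent. The
#' standard scale-free measure of how well a point-charge model reproduces
#' a reference potential on a shared grid.
#'
#' @param model_esp,reference_esp equal-length potential vectors.
#' @return RRMSE in percent.
#' @export
esp_rrmse <- function(model_esp, reference_esp) {
  stopifnot(length(model_esp) == length(reference_esp))
  denom <- sum(reference_esp^2)
  if (denom <= 0) stop("reference ESP has zero norm: RRMSE undefined")
  100 * sqrt(sum((model_esp - reference_esp)^2) / denom)
}

#' ESP fitting case
#'
#' Bundles a conformation, a grid, the reference potentials and the fit
#' constraints (total charge, atom equivalence classes).
#'
#' @param conf n x 3 coordinates (Angstrom).
#' @param elements per-atom element symbols.
#' @param grid_points m x 3 grid (m >= n).
#' @param reference_esp length-m reference potentials (e/A).
#' @param total_charge net molecular charge (e).
#' @param equivalence_classes list of integer vectors partitioning
#'   1..n_atoms; charges within one class are constrained equal. Default:
#'   every atom its own class.
#' @return object of class `hf_esp_case`.
#' @export
esp_case <- function(conf, elements, grid_points, reference_esp,
                     total_charge = 0, equivalence_classes = NULL) {
  conf <- as.matrix(conf); grid_points <- as.matrix(grid_points)
  n <- nrow(conf)
  stopifnot(length(elements) == n, nrow(grid_points) == length(reference_esp))
  if (nrow(grid_points) < n)
    stop("need at least as many grid points as atoms")
  if (is.null(equivalence_classes))
    equivalence_classes <- as.list(seq_len(n))
  idx <- sort(as.integer(unlist(equivalence_classes)))
  if (!identical(idx, seq_len(n)))
    stop("equivalence classes must partition the atoms")
  structure(list(conf = conf, elements = elements, grid_points = grid_points,
                 reference_esp = as.numeric(reference_esp),
                 total_charge = total_charge,
                 equivalence_classes = equivalence_classes),
            class = "hf_esp_case")
}

#' Restrained ESP charge fit
#'
#' Minimizes `sum_g (V_ref - V_q)^2 + sum_i a_i (sqrt(q_i^2 + b^2) - b)`
#' subject to the total-charge constraint and within-class charge equality,
#' by iterated reweighted linear solves with a Lagrange multiplier for the
#' constraint. The hyperbolic restraint (strength `a`, width `b`) shrinks
#' charge magnitudes toward zero and is applied to non-hydrogen atoms only.
#' With `stage2 = TRUE` a two-stage protocol is used: stage 1 fits all
#' atoms independently (no equivalences, strength `a`), stage 2 refits only
#' the multi-atom equivalence classes (methyl-like groups) under the
#' equality constraints with strength `a2`, freezing the remaining atoms.
#'
#' @param case an [esp_case()].
#' @param a restraint strength (default 0.0005).
#' @param b restraint width in e (default 0.1).
#' @param stage2 logical; run the two-stage protocol (default FALSE).
#' @param a2 stage-2 restraint strength (default 0.001).
#' @param tol convergence threshold on max |dq| (default 1e-6 e).
#' @param maxit maximum reweighting iterations.
#' @return list of class `hf_charge_fit`: `charges`, `rrmse_vs_target` (%),
#'   `loss`, `constraint_residual`.
#' @export
resp_fit <- function(case, a = 0.0005, b = 0.1, stage2 = FALSE, a2 = 0.001,
                     tol = 1e-6, maxit = 200) {
  stopifnot(inherits(case, "hf_esp_case"))
  n <- nrow(case$conf)
  A <- inv_dist_matrix(case$grid_points, case$conf)
  restrained <- case$elements != "H"
  if (!stage2) {
    q <- resp_solve(A, case$reference_esp, case$total_charge,
                    case$equivalence_classes, a * restrained, b, tol, maxit)
  } else {
    q1 <- resp_solve(A, case$reference_esp, case$total_charge,
                     as.list(seq_len(n)), a * restrained, b, tol, maxit)
    free <- sort(unlist(Filter(function(cl) length(cl) > 1,
                               case$equivalence_classes)))
    if (!length(free)) {
      q <- q1
    } else {
      frozen <- setdiff(seq_len(n), free)
      Vres <- case$reference_esp -
        as.numeric(A[, frozen, drop = FALSE] %*% q1[frozen])
      classes2 <- lapply(Filter(function(cl) length(cl) > 1,
                                case$equivalence_classes),
                         function(cl) match(cl, free))
      # singleton free atoms cannot occur: free is the union of multi-classes
      q2 <- resp_solve(A[, free, drop = FALSE], Vres,
                       case$total_charge - sum(q1[frozen]), classes2,
                       (a2 * restrained)[free], b, tol, maxit)
      q <- q1; q[free] <- q2
    }
  }
  vq <- as.numeric(A %*% q)
  loss <- sum((case$reference_esp - vq)^2) +
    sum(a * restrained * (sqrt(q^2 + b^2) - b))
  structure(list(charges = q,
                 rrmse_vs_target = esp_rrmse(vq, case$reference_esp),
                 loss = loss,
                 constraint_residual = abs(sum(q) - case$total_charge)),
            class = "hf_charge_fit")
}

# IRLS core: A is m x n, restraint a_i per column, classes partition columns
resp_solve <- function(A, V, Q, classes, a_atom, b, tol, maxit) {
  n <- ncol(A)
  nc <- length(classes)
  C <- matrix(0, n, nc)
  for (k in seq_len(nc)) C[classes[[k]], k] <- 1
  Ac <- A %*% C
  M0 <- 2 * crossprod(Ac)
  rhs0 <- 2 * crossprod(Ac, V)
  csize <- colSums(C)
  q <- rep(Q / n, n)
  for (it in seq_len(maxit)) {
    w <- a_atom / sqrt(q^2 + b^2)
    B <- crossprod(C, w * C)  # class-collapsed restraint
    K <- rbind(cbind(M0 + B, csize), c(csize, 0))
    sol <- tryCatch(solve(K, c(rhs0, Q)),
                    error = function(e)
                      stop("singular ESP design matrix; use a denser grid"))
    qn <- as.numeric(C %*% sol[seq_len(nc)])
    if (max(abs(qn - q)) < tol) { q <- qn; break }
    q <- qn
  }
  q
}

#' Write / read an ESP case
#'
#' Serialized as a paired XYZ file (comment line carries `q= <net charge>`
#' and `classes= <comma-separated class id per atom>`) plus a whitespace-
#' delimited grid file with `x y z V_ref` per line.
#'
#' @param case an [esp_case()].
#' @param xyz_path,grid_path file paths.
#' @return `xyz_path`, invisibly.
#' @export
write_esp_case <- function(case, xyz_path, grid_path) {
  cls <- integer(nrow(case$conf))
  for (k in seq_along(case$equivalence_classes))
    cls[case$equivalence_classes[[k]]] <- k
  con <- file(xyz_path, "w"); on.exit(close(con))
  writeLines(c(as.character(nrow(case$conf)),
               sprintf("q= %.10g classes= %s", case$total_charge,
                       paste(cls, collapse = ","))), con)
  writeLines(sprintf("%-2s %18.10f %18.10f %18.10f", case$elements,
                     case$conf[, 1], case$conf[, 2], case$conf[, 3]), con)
  g <- cbind(case$grid_points, case$reference_esp)
  writeLines(sprintf("%18.10f %18.10f %18.10f %18.17g",
                     g[, 1], g[, 2], g[, 3], g[, 4]), grid_path)
  invisible(xyz_path)
}

#' @rdname write_esp_case
#' @export
read_esp_case <- function(xyz_path, grid_path) {
  ln <- readLines(xyz_path)
  na <- as.integer(trimws(ln[1]))
  cm <- ln[2]
  Q <- as.numeric(regmatches(cm, regexec("q=\\s*([-0-9.eE+]+)", cm))[[1]][2])
  cls_str <- regmatches(cm, regexec("classes=\\s*([0-9,]+)", cm))[[1]][2]
  cls <- as.integer(strsplit(cls_str, ",")[[1]])
  rows <- strsplit(trimws(ln[2 + seq_len(na)]), "\\s+")
  elements <- vapply(rows, `[`, "", 1)
  conf <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), ncol = 3,
                 byrow = TRUE)
  g <- as.matrix(read.table(grid_path))
  classes <- split(seq_len(na), cls)
  names(classes) <- NULL
  esp_case(conf, elements, g[, 1:3, drop = FALSE], g[, 4], Q, classes)
}
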