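#' Build a molecular topology from atoms and bonds
#'
#' A topology holds the atom table and every bonded term list the energy
#' engine needs. Angles, proper torsions, 1-2/1-3 exclusions and 1-4 pairs
#' are derived from the bond graph, so the bonded lists are guaranteed
#' consistent with connectivity.
#'
#' Atom indices are 1-based throughout the R interface.
#'
#' @param atoms data.frame with columns `element`, `type_label`, `charge`,
#'   `unit_id` (1-based repeating-unit index) and optionally `mass` (amu;
#'   looked up from the element when absent).
#' @param bonds two-column integer matrix of bonded atom pairs.
#' @param n_units number of repeating units; defaults to `max(unit_id)`.
#' @return object of class `hf_topology`: list with `atoms`, `bonds`,
#'   `angles`, `torsions`, `exclusions`, `pairs14`, `n_units`.
#' @examples
#' atoms <- data.frame(element = c("C", "C", "O"),
#'                     type_label = c("c1", "c1", "os"),
#'                     charge = c(0.1, 0.1, -0.2), unit_id = 1)
#' top <- topology(atoms, rbind(c(1, 2), c(2, 3)))
#' nrow(top$angles)  # one angle: 1-2-3
#' @export
topology <- function(atoms, bonds, n_units = NULL) {
  stopifnot(is.data.frame(atoms))
  need <- c("element", "type_label", "charge", "unit_id")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms lacks column(s): ", paste(miss, collapse = ", "))
  n <- nrow(atoms)
  if (is.null(atoms$mass)) atoms$mass <- element_property(atoms$element, "mass")
  if (any(atoms$mass <= 0)) stop("atom masses must be positive")
  bonds <- canonical_pairs(as.matrix(bonds))
  if (any(bonds < 1L) || any(bonds > n)) stop("bond indices out of range")
  if (any(bonds[, 1] == bonds[, 2])) stop("self-bond found")
  if (anyDuplicated(paste(bonds[, 1], bonds[, 2]))) stop("duplicated bond")
  if (is.null(n_units)) n_units <- max(atoms$unit_id)
  if (any(atoms$unit_id < 1L) || any(atoms$unit_id > n_units))
    stop("unit_id out of [1, n_units]")

  adj <- vector("list", n)
  for (b in seq_len(nrow(bonds))) {
    i <- bonds[b, 1]; j <- bonds[b, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  angles <- derive_angles(adj, n)
  torsions <- derive_torsions(adj, bonds)
  ex12 <- bonds
  ex13 <- if (nrow(angles)) canonical_pairs(angles[, c(1, 3), drop = FALSE]) else
    matrix(integer(), 0, 2)
  exclusions <- unique_pairs(rbind(ex12, ex13))
  p14 <- if (nrow(torsions)) canonical_pairs(torsions[, c(1, 4), drop = FALSE]) else
    matrix(integer(), 0, 2)
  p14 <- unique_pairs(p14)
  # in small rings a 1-4 path can also be a 1-2 or 1-3 path: exclusion wins
  p14 <- setdiff_pairs(p14, exclusions)

  structure(
    list(atoms = atoms, bonds = bonds, angles = angles, torsions = torsions,
         exclusions = exclusions, pairs14 = p14, n_units = as.integer(n_units)),
    class = "hf_topology")
}

#' @export
print.hf_topology <- function(x, ...) {
  cat(sprintf(
    "hf_topology: %d atoms, %d units | %d bonds, %d angles, %d torsions, %d 1-4 pairs\n",
    nrow(x$atoms), x$n_units, nrow(x$bonds), nrow(x$angles),
    nrow(x$torsions), nrow(x$pairs14)))
  invisible(x)
}

canonical_pairs <- function(m) {
  m <- matrix(as.integer(m), ncol = 2)
  sw <- m[, 1] > m[, 2]
  m[sw, ] <- m[sw, c(2, 1), drop = FALSE]
  m
}

unique_pairs <- function(m) {
  if (!nrow(m)) return(m)
  m[!duplicated(paste(m[, 1], m[, 2])), , drop = FALSE]
}

setdiff_pairs <- function(a, b) {
  if (!nrow(a)) return(a)
  a[!(paste(a[, 1], a[, 2]) %in% paste(b[, 1], b[, 2])), , drop = FALSE]
}

derive_angles <- function(adj, n) {
  out <- list()
  for (j in seq_len(n)) {
    nb <- sort(adj[[j]])
    if (length(nb) < 2) next
    cmb <- utils::combn(nb, 2)
    out[[length(out) + 1]] <- cbind(cmb[1, ], j, cmb[2, ])
  }
  if (!length(out)) return(matrix(integer(), 0, 3))
  do.call(rbind, out)
}

derive_torsions <- function(adj, bonds) {
  out <- list()
  for (b in seq_len(nrow(bonds))) {
    j <- bonds[b, 1]; k <- bonds[b, 2]
    for (i in adj[[j]]) {
      if (i == k) next
      for (l in adj[[k]]) {
        if (l == j || l == i) next
        quad <- c(i, j, k, l)
        # canonical orientation: smaller central atom first, tie-break on ends
        if (quad[2] > quad[3] || (quad[2] == quad[3] && quad[1] > quad[4]))
          quad <- rev(quad)
        out[[length(out) + 1]] <- quad
      }
    }
  }
  if (!length(out)) return(matrix(integer(), 0, 4))
  m <- do.call(rbind, out)
  m[!duplicated(paste(m[, 1], m[, 2], m[, 3], m[, 4])), , drop = FALSE]
}

#' Validate a configuration against a topology
#'
#' Checks shape, finiteness, and that no two atoms sit closer than 1e-6 A.
#' @param conf n_atoms x 3 coordinate matrix (Angstrom).
#' @param topology an [topology()] object.
#' @return the configuration, invisibly; errors on violation.
#' @export
check_configuration <- function(conf, topology) {
  conf <- as.matrix(conf)
  if (!is.numeric(conf) || ncol(conf) != 3 || nrow(conf) != nrow(topology$atoms))
    stop("configuration must be an n_atoms x 3 numeric matrix")
  if (!all(is.finite(conf))) stop("non-finite coordinates")
  dmin <- min(stats::dist(conf))
  if (dmin <= 1e-6)
    stop(sprintf("degenerate geometry: coincident atoms (min distance %.2e A)", dmin))
  invisible(conf)
}
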