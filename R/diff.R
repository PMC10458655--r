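#' Term-by-term comparison of two parameter sets
#'
#' Classifies every term key of each class (bond, angle, torsion, vdW) into
#' `identical`, `changed` (with field deltas and percent change of force
#' constants / barriers), `only_in_a` (eliminated going A to B) and
#' `only_in_b` (newly defined in B). Torsion terms are compared as whole
#' multi-component definitions: a term counts as changed when any barrier,
#' periodicity or phase differs.
#'
#' @param psA,psB [parameter_set()] objects.
#' @param tol numeric tolerance for "identical" (default 1e-9).
#' @return object of class `hf_diff`: list of per-class data.frames with
#'   columns `type_key`, `status`, and for changed force-constant-bearing
#'   fields `delta_*` and `pct_k`.
#' @examples
#' \dontrun{
#' d <- diff_parameter_sets(gaff_like, gaff2_like)
#' subset(d$torsion, status == "only_in_b")  # newly defined terms
#' }
#' @export
diff_parameter_sets <- function(psA, psB, tol = 1e-9) {
  out <- list(
    bond = diff_table(psA$bonds, psB$bonds, "type_key",
                      val = c("k", "r0"), kfield = "k", tol = tol),
    angle = diff_table(psA$angles, psB$angles, "type_key",
                       val = c("k", "theta0"), kfield = "k", tol = tol),
    torsion = diff_torsions(psA$torsions, psB$torsions, tol),
    vdw = diff_table(psA$vdw, psB$vdw, "type",
                     val = c("rmin_half", "epsilon"), kfield = "epsilon",
                     tol = tol))
  structure(out, class = "hf_diff")
}

diff_table <- function(a, b, keycol, val, kfield, tol) {
  keys <- union(a[[keycol]], b[[keycol]])
  status <- character(length(keys))
  deltas <- matrix(NA_real_, length(keys), length(val),
                   dimnames = list(NULL, paste0("delta_", val)))
  pct_k <- rep(NA_real_, length(keys))
  for (i in seq_along(keys)) {
    ia <- match(keys[i], a[[keycol]]); ib <- match(keys[i], b[[keycol]])
    if (is.na(ia)) { status[i] <- "only_in_b"; next }
    if (is.na(ib)) { status[i] <- "only_in_a"; next }
    dv <- vapply(val, function(v) b[[v]][ib] - a[[v]][ia], 0)
    deltas[i, ] <- dv
    if (all(abs(dv) <= tol)) status[i] <- "identical" else {
      status[i] <- "changed"
      ka <- a[[kfield]][ia]
      if (abs(ka) > tol) pct_k[i] <- 100 * (b[[kfield]][ib] - ka) / ka
    }
  }
  cbind(data.frame(type_key = keys, status = status), deltas,
        data.frame(pct_k = pct_k))
}

diff_torsions <- function(a, b, tol) {
  keys <- union(unique(a$type_key), unique(b$type_key))
  status <- character(length(keys))
  detail <- character(length(keys))
  for (i in seq_along(keys)) {
    ra <- a[a$type_key == keys[i], c("v", "n", "gamma"), drop = FALSE]
    rb <- b[b$type_key == keys[i], c("v", "n", "gamma"), drop = FALSE]
    # a term whose every component has zero barrier is an explicit null:
    # it defines nothing, so treat it as absent for classification
    null_a <- nrow(ra) == 0 || all(ra$v <= tol)
    null_b <- nrow(rb) == 0 || all(rb$v <= tol)
    if (null_a && null_b) { status[i] <- "identical"; next }
    if (null_a) { status[i] <- "only_in_b"; next }
    if (null_b) { status[i] <- "only_in_a"; next }
    ra <- ra[order(ra$n), ]; rb <- rb[order(rb$n), ]
    same <- nrow(ra) == nrow(rb) && all(ra$n == rb$n) &&
      all(abs(ra$v - rb$v) <= tol) &&
      all(abs((ra$gamma - rb$gamma + 180) %% 360 - 180) <= tol |
            ra$v <= tol)
    if (same) status[i] <- "identical" else {
      status[i] <- "changed"
      detail[i] <- paste0("V: ", paste(sprintf("%.4g", ra$v), collapse = "/"),
                          " -> ", paste(sprintf("%.4g", rb$v), collapse = "/"))
    }
  }
  data.frame(type_key = keys, status = status, detail = detail)
}

#' @export
print.hf_diff <- function(x, ...) {
  for (cls in names(x)) {
    tab <- table(factor(x[[cls]]$status,
                        levels = c("identical", "changed", "only_in_a",
                                   "only_in_b")))
    cat(sprintf("%-8s identical %3d | changed %3d | only in A %3d | only in B %3d\n",
                cls, tab[1], tab[2], tab[3], tab[4]))
  }
  invisible(x)
}
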