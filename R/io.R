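# File formats: a plain-text parameter dialect (sections [scaling], [vdw],
# [bonds], [angles], [torsions]) and multi-frame XYZ. Values are printed
# with %.17g so that write(read(x)) is field-identical.

#' Write a parameter set to the plain-text dialect
#'
#' @param params an [parameter_set()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_parameter_set <- function(params, path) {
  g <- function(x) sprintf("%.17g", x)
  ln <- c("# hostfit parameter set v1",
          paste("label", params$label),
          "[scaling]",
          paste("scee", g(params$scee)),
          paste("scnb", g(params$scnb)),
          "[vdw]")
  for (i in seq_len(nrow(params$vdw)))
    ln <- c(ln, paste(params$vdw$type[i], g(params$vdw$rmin_half[i]),
                      g(params$vdw$epsilon[i])))
  ln <- c(ln, "[bonds]")
  for (i in seq_len(nrow(params$bonds)))
    ln <- c(ln, paste(params$bonds$t1[i], params$bonds$t2[i],
                      g(params$bonds$k[i]), g(params$bonds$r0[i])))
  ln <- c(ln, "[angles]")
  for (i in seq_len(nrow(params$angles)))
    ln <- c(ln, paste(params$angles$t1[i], params$angles$t2[i],
                      params$angles$t3[i], g(params$angles$k[i]),
                      g(params$angles$theta0[i])))
  ln <- c(ln, "[torsions]")
  for (i in seq_len(nrow(params$torsions)))
    ln <- c(ln, paste(params$torsions$t1[i], params$torsions$t2[i],
                      params$torsions$t3[i], params$torsions$t4[i],
                      g(params$torsions$v[i]), g(params$torsions$n[i]),
                      g(params$torsions$gamma[i])))
  writeLines(ln, path)
  invisible(path)
}

#' Read a parameter set from the plain-text dialect
#'
#' @param path file written by [write_parameter_set()].
#' @return an [parameter_set()] object.
#' @export
read_parameter_set <- function(path) {
  ln <- readLines(path)
  ln <- trimws(ln)
  ln <- ln[!grepl("^#", ln) & nzchar(ln)]
  label <- ""
  lab <- grep("^label\\b", ln)
  if (length(lab)) {
    label <- trimws(sub("^label", "", ln[lab[1]]))
    ln <- ln[-lab]
  }
  sec <- cumsum(grepl("^\\[", ln))
  names_sec <- gsub("\\[|\\]", "", ln[grepl("^\\[", ln)])
  body <- split(ln[!grepl("^\\[", ln)], factor(sec[!grepl("^\\[", ln)],
                labels = names_sec, levels = seq_along(names_sec)))
  tok <- function(section) {
    rows <- body[[section]]
    if (is.null(rows) || !length(rows)) return(list())
    lapply(strsplit(rows, "\\s+"), identity)
  }
  sc <- tok("scaling")
  scee <- 1.2; scnb <- 2.0
  for (r in sc) {
    if (r[1] == "scee") scee <- as.numeric(r[2])
    if (r[1] == "scnb") scnb <- as.numeric(r[2])
  }
  vd <- tok("vdw")
  vdw <- data.frame(type = vapply(vd, `[`, "", 1),
                    rmin_half = as.numeric(vapply(vd, `[`, "", 2)),
                    epsilon = as.numeric(vapply(vd, `[`, "", 3)))
  bd <- tok("bonds")
  bonds <- data.frame(t1 = vapply(bd, `[`, "", 1), t2 = vapply(bd, `[`, "", 2),
                      k = as.numeric(vapply(bd, `[`, "", 3)),
                      r0 = as.numeric(vapply(bd, `[`, "", 4)))
  an <- tok("angles")
  angles <- data.frame(t1 = vapply(an, `[`, "", 1), t2 = vapply(an, `[`, "", 2),
                       t3 = vapply(an, `[`, "", 3),
                       k = as.numeric(vapply(an, `[`, "", 4)),
                       theta0 = as.numeric(vapply(an, `[`, "", 5)))
  to <- tok("torsions")
  torsions <- data.frame(t1 = vapply(to, `[`, "", 1), t2 = vapply(to, `[`, "", 2),
                         t3 = vapply(to, `[`, "", 3), t4 = vapply(to, `[`, "", 4),
                         v = as.numeric(vapply(to, `[`, "", 5)),
                         n = as.numeric(vapply(to, `[`, "", 6)),
                         gamma = as.numeric(vapply(to, `[`, "", 7)))
  parameter_set(bonds, angles, torsions, vdw, scee = scee, scnb = scnb,
                label = label)
}

#' Trajectory container
#'
#' Ordered list of same-sized configurations with per-frame times.
#'
#' @param frames list of n_atoms x 3 matrices (Angstrom).
#' @param elements per-atom element symbols.
#' @param times per-frame times (ps); defaults to a unit grid.
#' @param stride time between frames (ps), used when `times` is absent.
#' @return object of class `hf_trajectory`.
#' @export
trajectory <- function(frames, elements, times = NULL, stride = 1) {
  if (is.matrix(frames)) frames <- list(frames)
  stopifnot(length(frames) >= 1, stride > 0)
  na <- nrow(frames[[1]])
  if (!all(vapply(frames, nrow, 0L) == na))
    stop("all frames must have the same atom count")
  stopifnot(length(elements) == na)
  if (is.null(times)) times <- (seq_along(frames) - 1) * stride
  stopifnot(length(times) == length(frames))
  structure(list(frames = frames, elements = elements, times = times,
                 stride = stride), class = "hf_trajectory")
}

#' @export
print.hf_trajectory <- function(x, ...) {
  cat(sprintf("hf_trajectory: %d frames x %d atoms, t = %g..%g ps\n",
              length(x$frames), nrow(x$frames[[1]]),
              min(x$times), max(x$times)))
  invisible(x)
}

#' Write a trajectory as multi-frame XYZ
#'
#' Comment line carries `t= <ps>`.
#' @param traj an [trajectory()] object.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  na <- nrow(traj$frames[[1]])
  for (f in seq_along(traj$frames)) {
    writeLines(c(as.character(na), sprintf("t= %.6f", traj$times[f])), con)
    m <- traj$frames[[f]]
    writeLines(sprintf("%-2s %18.10f %18.10f %18.10f",
                       traj$elements, m[, 1], m[, 2], m[, 3]), con)
  }
  invisible(path)
}

#' Read a multi-frame XYZ file
#'
#' @param path XYZ file; the comment line may carry `t= <ps>`.
#' @return an [trajectory()] object.
#' @export
read_xyz <- function(path) {
  ln <- readLines(path)
  frames <- list(); times <- numeric(0); elements <- NULL
  i <- 1
  while (i <= length(ln)) {
    if (!nzchar(trimws(ln[i]))) { i <- i + 1; next }
    na <- as.integer(trimws(ln[i]))
    cm <- ln[i + 1]
    tm <- regmatches(cm, regexec("t=\\s*([-0-9.eE+]+)", cm))[[1]]
    times <- c(times, if (length(tm) == 2) as.numeric(tm[2]) else length(frames))
    rows <- strsplit(trimws(ln[i + 1 + seq_len(na)]), "\\s+")
    el <- vapply(rows, `[`, "", 1)
    if (is.null(elements)) elements <- el
    xyz <- matrix(as.numeric(unlist(lapply(rows, `[`, 2:4))), ncol = 3,
                  byrow = TRUE)
    frames[[length(frames) + 1]] <- xyz
    i <- i + 2 + na
  }
  stride <- if (length(times) > 1) times[2] - times[1] else 1
  trajectory(frames, elements, times = times,
             stride = if (stride > 0) stride else 1)
}

#' Read coordinates from a PDB file (convenience, read-only)
#'
#' Thin wrapper over `bio3d::read.pdb`; returns the coordinates of the
#' first model plus element symbols.
#'
#' @param path PDB file.
#' @return list with `conf` (n x 3 matrix, Angstrom) and `elements`.
#' @export
read_pdb_coords <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("read_pdb_coords requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(path)
  conf <- matrix(pdb$xyz[1, ], ncol = 3, byrow = TRUE)
  el <- pdb$atom$elesy
  if (is.null(el) || all(is.na(el)) || !any(nzchar(el)))
    el <- substr(trimws(pdb$atom$elety), 1, 1)
  list(conf = conf, elements = trimws(el))
}
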