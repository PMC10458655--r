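# Shared fixtures: small random chain systems and an independent
# brute-force energy oracle (plain per-term loops, no vectorization, its
# own type-key lookup and dihedral convention) used to cross-check the
# engine.

make_chain <- function(n_atoms = 6, seed = 1, charged = TRUE) {
  set.seed(seed)
  elements <- sample(c("C", "N", "O"), n_atoms, replace = TRUE)
  types <- paste0(tolower(elements), sample(1:2, n_atoms, replace = TRUE))
  q <- if (charged) round(rnorm(n_atoms, 0, 0.2), 3) else rep(0, n_atoms)
  atoms <- data.frame(element = elements, type_label = types,
                      charge = q, unit_id = 1)
  bonds <- cbind(seq_len(n_atoms - 1), 2:n_atoms)
  top <- topology(atoms, bonds)
  keys <- hostfit:::topology_type_keys(top)
  bd <- do.call(rbind, strsplit(unique(keys$bond), " "))
  ad <- do.call(rbind, strsplit(unique(keys$angle), " "))
  td <- do.call(rbind, strsplit(unique(keys$torsion), " "))
  ps <- parameter_set(
    bonds = data.frame(t1 = bd[, 1], t2 = bd[, 2],
                       k = runif(nrow(bd), 250, 400),
                       r0 = runif(nrow(bd), 1.3, 1.6)),
    angles = data.frame(t1 = ad[, 1], t2 = ad[, 2], t3 = ad[, 3],
                        k = runif(nrow(ad), 40, 80),
                        theta0 = runif(nrow(ad), 105, 125)),
    torsions = data.frame(t1 = td[, 1], t2 = td[, 2], t3 = td[, 3],
                          t4 = td[, 4],
                          v = runif(nrow(td), 0.2, 3),
                          n = sample(1:3, nrow(td), replace = TRUE),
                          gamma = sample(c(0, 90, 180), nrow(td),
                                         replace = TRUE)),
    vdw = data.frame(type = unique(types),
                     rmin_half = runif(length(unique(types)), 1.6, 2.0),
                     epsilon = runif(length(unique(types)), 0.05, 0.25)))
  conf <- cbind(seq(0, by = 1.45, length.out = n_atoms), 0, 0) +
    matrix(rnorm(3 * n_atoms, sd = 0.25), ncol = 3)
  list(top = top, ps = ps, conf = conf)
}

# independent brute-force oracle: naive loops, multiset key matching
brute_energy <- function(top, ps, conf, charges = NULL) {
  if (is.null(charges)) charges <- top$atoms$charge
  lab <- top$atoms$type_label
  find_bond <- function(a, b) {
    for (r in seq_len(nrow(ps$bonds)))
      if ((ps$bonds$t1[r] == a && ps$bonds$t2[r] == b) ||
          (ps$bonds$t1[r] == b && ps$bonds$t2[r] == a)) return(r)
    stop("no bond type")
  }
  find_angle <- function(a, b, c) {
    for (r in seq_len(nrow(ps$angles)))
      if (ps$angles$t2[r] == b &&
          ((ps$angles$t1[r] == a && ps$angles$t3[r] == c) ||
           (ps$angles$t1[r] == c && ps$angles$t3[r] == a))) return(r)
    stop("no angle type")
  }
  find_torsion <- function(a, b, c, d) {
    rows <- c()
    for (r in seq_len(nrow(ps$torsions)))
      if ((ps$torsions$t1[r] == a && ps$torsions$t2[r] == b &&
           ps$torsions$t3[r] == c && ps$torsions$t4[r] == d) ||
          (ps$torsions$t1[r] == d && ps$torsions$t2[r] == c &&
           ps$torsions$t3[r] == b && ps$torsions$t4[r] == a))
        rows <- c(rows, r)
    rows
  }
  E <- 0
  for (b in seq_len(nrow(top$bonds))) {
    i <- top$bonds[b, 1]; j <- top$bonds[b, 2]
    r <- sqrt(sum((conf[i, ] - conf[j, ])^2))
    row <- find_bond(lab[i], lab[j])
    E <- E + ps$bonds$k[row] * (r - ps$bonds$r0[row])^2
  }
  for (a in seq_len(nrow(top$angles))) {
    i <- top$angles[a, 1]; j <- top$angles[a, 2]; k <- top$angles[a, 3]
    u <- conf[i, ] - conf[j, ]; v <- conf[k, ] - conf[j, ]
    th <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2)))
    row <- find_angle(lab[i], lab[j], lab[k])
    E <- E + ps$angles$k[row] * (th - ps$angles$theta0[row] * pi / 180)^2
  }
  for (t in seq_len(nrow(top$torsions))) {
    i <- top$torsions[t, 1]; j <- top$torsions[t, 2]
    k <- top$torsions[t, 3]; l <- top$torsions[t, 4]
    phi <- brute_dihedral(conf[i, ], conf[j, ], conf[k, ], conf[l, ])
    for (row in find_torsion(lab[i], lab[j], lab[k], lab[l])) {
      E <- E + ps$torsions$v[row] / 2 *
        (1 + cos(ps$torsions$n[row] * phi -
                   ps$torsions$gamma[row] * pi / 180))
    }
  }
  excl <- paste(top$exclusions[, 1], top$exclusions[, 2])
  p14 <- paste(top$pairs14[, 1], top$pairs14[, 2])
  n <- nrow(conf)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (paste(i, j) %in% excl) next
    s <- if (paste(i, j) %in% p14) c(ps$scee, ps$scnb) else c(1, 1)
    r <- sqrt(sum((conf[i, ] - conf[j, ])^2))
    E <- E + 332.0637 * charges[i] * charges[j] / r / s[1]
    ri <- ps$vdw$rmin_half[match(lab[i], ps$vdw$type)]
    rj <- ps$vdw$rmin_half[match(lab[j], ps$vdw$type)]
    ei <- ps$vdw$epsilon[match(lab[i], ps$vdw$type)]
    ej <- ps$vdw$epsilon[match(lab[j], ps$vdw$type)]
    sr <- ((ri + rj) / r)^6
    E <- E + sqrt(ei * ej) * (sr^2 - 2 * sr) / s[2]
  }
  E
}

# dihedral via projection onto the plane normal to the central bond
# (deliberately different route than the engine's atan2-of-cross-products)
brute_dihedral <- function(p1, p2, p3, p4) {
  b <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  u <- (p1 - p2) - sum((p1 - p2) * b) * b
  v <- (p4 - p3) - sum((p4 - p3) * b) * b
  ang <- acos(max(-1, min(1, sum(u * v) / sqrt(sum(u^2) * sum(v^2)))))
  cr <- c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
          u[1] * v[2] - u[2] * v[1])
  if (sum(cr * b) < 0) ang <- -ang
  ang
}

# default small benchmark ring shared across refit tests
make_bench_ring <- function(n_units = 7, truth_seed = 3) {
  ring <- build_ring(ring_spec(n_units))
  truth <- ground_truth_params(ring$topology, seed = truth_seed)
  minimized <- minimize_energy(ring$topology, truth, ring$conf)
  list(top = ring$topology, truth = truth, conf = minimized$conf)
}

# per-type bonded energy profiles, for phase-degeneracy-aware recovery
# comparisons: bond E(r) on a grid, angle E(theta), torsion E(phi)
profile_rms <- function(psA, psB) {
  out <- c()
  for (r in seq_len(nrow(psA$bonds))) {
    key <- psA$bonds$type_key[r]
    rB <- match(key, psB$bonds$type_key)
    x <- seq(1.0, 2.0, length.out = 41)
    pa <- psA$bonds$k[r] * (x - psA$bonds$r0[r])^2
    pb <- psB$bonds$k[rB] * (x - psB$bonds$r0[rB])^2
    out <- c(out, max(abs(pa - pb)) / max(diff(range(pa)), 1e-9))
  }
  for (r in seq_len(nrow(psA$angles))) {
    key <- psA$angles$type_key[r]
    rB <- match(key, psB$angles$type_key)
    x <- seq(80, 160, length.out = 41) * pi / 180
    pa <- psA$angles$k[r] * (x - psA$angles$theta0[r] * pi / 180)^2
    pb <- psB$angles$k[rB] * (x - psB$angles$theta0[rB] * pi / 180)^2
    out <- c(out, max(abs(pa - pb)) / max(diff(range(pa)), 1e-9))
  }
  tor_profile <- function(ps, key, x) {
    rows <- which(ps$torsions$type_key == key)
    p <- rep(0, length(x))
    for (r in rows)
      p <- p + ps$torsions$v[r] / 2 *
        (1 + cos(ps$torsions$n[r] * x - ps$torsions$gamma[r] * pi / 180))
    p
  }
  x <- seq(0, 2 * pi, length.out = 73)
  for (key in unique(psA$torsions$type_key)) {
    pa <- tor_profile(psA, key, x)
    pb <- tor_profile(psB, key, x)
    # profiles share an arbitrary constant only through their mean level
    out <- c(out, max(abs(pa - pb)) / max(diff(range(pa)), 0.5))
  }
  out
}
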