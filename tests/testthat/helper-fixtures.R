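# Shared helpers and independent oracles for the test suite.

# a bare point cloud from coordinates of one type
testCloud <- function(xyz, type = "C.3", charge = 0) {
  xyz <- as.matrix(xyz)
  new("PointCloud", atoms = data.frame(
    sybyl_type = type, effective_type = type,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    charge = charge, source_entry = "test",
    source_atom_id = seq_len(nrow(xyz)), stringsAsFactors = FALSE))
}

randomCloud <- function(n, seed, types = c("C.3", "C.ar", "N.3", "O.3"),
                        box = 6) {
  set.seed(seed)
  new("PointCloud", atoms = data.frame(
    sybyl_type = ty <- sample(types, n, replace = TRUE),
    effective_type = ty,
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    charge = round(runif(n, -0.5, 0.5), 3), source_entry = "rand",
    source_atom_id = seq_len(n), stringsAsFactors = FALSE))
}

# O(n^3) matrix-rescan oracle for greedy clustering: per type, rebuild the
# full item distance matrix from scratch at every step, merge the closest
# admissible pair (ties: lexicographic), items located at running centroids
greedyOracle <- function(cloud, cutoffs = defaultCutoffs()) {
  df <- atoms(cloud)
  out <- list()
  for (ty in sort(unique(df$effective_type))) {
    idx <- which(df$effective_type == ty)
    cut <- cutoffFor(cutoffs, ty)
    items <- lapply(seq_along(idx), function(i) idx[i])
    repeat {
      k <- length(items)
      if (k < 2) break
      cent <- t(vapply(items, function(m)
        c(mean(df$x[m]), mean(df$y[m]), mean(df$z[m])), numeric(3)))
      best <- NULL; bd <- Inf
      for (i in seq_len(k - 1)) for (j in (i + 1):k) {
        d <- sqrt(sum((cent[i, ] - cent[j, ])^2))
        if (d < bd - 1e-15) { bd <- d; best <- c(i, j) }
      }
      if (bd > cut) break
      items[[best[1]]] <- c(items[[best[1]]], items[[best[2]]])
      items[[best[2]]] <- NULL
    }
    out <- c(out, items)
  }
  # canonical form: sorted member sets
  canonicalPartition(out)
}

canonicalPartition <- function(members) {
  sets <- lapply(members, function(m) sort(if (is.list(m)) m$members else m))
  sets[order(vapply(sets, min, numeric(1)))]
}

# O(n^2) brute-force edge oracle
edgeOracle <- function(cloud, cutoffs = defaultCutoffs()) {
  df <- atoms(cloud)
  n <- nrow(df)
  rows <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (df$effective_type[i] != df$effective_type[j]) next
    cut <- cutoffFor(cutoffs, df$effective_type[i])
    d <- sqrt((df$x[i] - df$x[j])^2 + (df$y[i] - df$y[j])^2 +
                (df$z[i] - df$z[j])^2)
    if (d <= cut)
      rows[[length(rows) + 1]] <- data.frame(
        i = i, j = j, similarity = cut^2 - d^2,
        effective_type = df$effective_type[i])
  }
  if (length(rows) == 0)
    return(data.frame(i = integer(0), j = integer(0),
                      similarity = numeric(0), effective_type = character(0)))
  do.call(rbind, rows)
}

# exhaustive concordant-pair AUC oracle (ties 0.5)
pairAucOracle <- function(scores, labels) {
  act <- scores[labels]; dec <- scores[!labels]
  tot <- 0
  for (a in act) for (d in dec)
    tot <- tot + if (a > d) 1 else if (a == d) 0.5 else 0
  tot / (length(act) * length(dec))
}

# a methanol-like entry: C with 3 H, O with 1 H
methanolEntry <- function() {
  atoms <- data.frame(
    atom_id = 1:6,
    name = c("C1", "O1", "H1", "H2", "H3", "H4"),
    sybyl_type = c("C.3", "O.3", "H", "H", "H", "H"),
    x = c(0, 1.4, -0.5, -0.5, -0.5, 1.8),
    y = c(0, 0, 0.9, -0.9, 0, 0.8),
    z = c(0, 0, 0, 0, 1, 0),
    charge = c(0.1, -0.6, 0.05, 0.05, 0.05, 0.4),
    stringsAsFactors = FALSE)
  bonds <- data.frame(from = c(1, 1, 1, 1, 2), to = c(2, 3, 4, 5, 6),
                      order = "1", stringsAsFactors = FALSE)
  new("Mol2Molecule", name = "methanol_like", atoms = atoms, bonds = bonds)
}

randomEntry <- function(name, n, seed, box = 8) {
  set.seed(seed)
  mol2Molecule(name, data.frame(
    sybyl_type = sample(c("C.3", "C.ar", "N.3", "O.2"), n, replace = TRUE),
    x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
    charge = round(runif(n, -0.4, 0.4), 3)))
}

# A hand-built screen where one model atom overlaps decoys only:
# 4 C.3 anchor atoms form the true model; each active matches one anchor
# plus two off-site atoms; each decoy is a single atom sitting on the
# injected fifth model atom far from the anchors. With the injected atom
# the decoys outscore the actives; without it the actives win.
plantedFixture <- function() {
  anchors <- data.frame(sybyl_type = "C.3",
                        x = c(0, 4, 0, 4), y = c(0, 0, 4, 4), z = 0,
                        charge = 0)
  bad <- data.frame(sybyl_type = "C.3", x = 20, y = 20, z = 20, charge = 0)
  model <- cavityModel(rbind(anchors, bad))
  actives <- lapply(1:6, function(k) {
    anch <- anchors[(k - 1) %% 4 + 1, ]
    mol2Molecule(sprintf("act%d_conf_01", k), data.frame(
      sybyl_type = "C.3",
      x = c(anch$x, -15 - 3 * k, -15 - 3 * k),
      y = c(anch$y, 0, 5), z = c(anch$z, 0, 0), charge = 0))
  })
  decoys <- lapply(1:6, function(k)
    mol2Molecule(sprintf("dec%d_conf_01", k), data.frame(
      sybyl_type = "C.3", x = 20 + 0.05 * k, y = 20, z = 20, charge = 0)))
  labels <- data.frame(
    compound_id = c(sprintf("act%d", 1:6), sprintf("dec%d", 1:6)),
    is_active = rep(c(TRUE, FALSE), each = 6))
  list(model = model, poses = c(actives, decoys), labels = labels,
       bad_id = nrow(anchors) + 1L)
}

writeTempMol2 <- function(entries, includeBonds = TRUE) {
  path <- tempfile(fileext = ".mol2")
  writeMol2(entries, path, includeBonds = includeBonds)
  path
}
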