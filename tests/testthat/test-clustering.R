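test_that("a 3-clique within cutoff plus an outlier clusters to sizes 3 and 1", {
  # C.ar cutoff 1.38: a-c mutually close, d beyond reach
  cloud <- testCloud(rbind(c(0, 0, 0), c(1.0, 0, 0), c(0.5, 0.8, 0),
                           c(5, 5, 0)), type = "C.ar")
  cl <- greedyCluster(cloud)
  expect_length(cl, 2)
  expect_setequal(vapply(cl, function(c) length(c$members), integer(1)),
                  c(3L, 1L))
})

test_that("a single atom becomes a singleton cluster at its own position", {
  cloud <- testCloud(rbind(c(1, 2, 3)))
  cl <- greedyCluster(cloud)
  expect_length(cl, 1)
  expect_equal(unname(cl[[1]]$centroid), c(1, 2, 3))
})

test_that("greedy clustering matches the exhaustive matrix-rescan oracle", {
  for (seed in 1:30) {
    n <- sample(5:30, 1)
    cloud <- randomCloud(n, seed = seed, box = 4)
    got <- canonicalPartition(greedyCluster(cloud))
    expect_equal(got, greedyOracle(cloud), info = paste("seed", seed))
  }
})

test_that("every merge recorded in the log respects the type cutoff", {
  cloud <- randomCloud(120, seed = 404, box = 5)
  cl <- greedyCluster(cloud)
  log <- attr(cl, "merge_log")
  expect_gt(nrow(log), 0)
  expect_true(all(log$distance <= log$cutoff))
  # atom conservation: every atom in exactly one cluster
  all_members <- sort(unlist(lapply(cl, function(c) c$members)))
  expect_equal(all_members, seq_len(nAtoms(cloud)))
})

test_that("the partition is invariant to atom order and to rigid motion", {
  cloud <- randomCloud(40, seed = 55, box = 4)
  base <- greedyCluster(cloud)
  keyOf <- function(cl, df) {
    sets <- lapply(cl, function(c)
      sort(sprintf("%.6f_%.6f_%.6f", df$x[c$members], df$y[c$members],
                   df$z[c$members])))
    sets[order(vapply(sets, `[`, character(1), 1))]
  }
  # permutation
  set.seed(1); perm <- sample(nAtoms(cloud))
  df2 <- atoms(cloud)[perm, ]; df2$source_atom_id <- seq_len(nrow(df2))
  cl2 <- greedyCluster(new("PointCloud", atoms = `rownames<-`(df2, NULL)))
  expect_equal(keyOf(cl2, df2), keyOf(base, atoms(cloud)))
  # rotation + translation
  th <- 0.83
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3,
              byrow = TRUE)
  df3 <- atoms(cloud)
  xyz <- as.matrix(df3[, c("x", "y", "z")]) %*% t(R)
  df3$x <- xyz[, 1] + 10; df3$y <- xyz[, 2] - 3; df3$z <- xyz[, 3] + 1
  cl3 <- greedyCluster(new("PointCloud", atoms = df3))
  expect_equal(canonicalPartition(cl3), canonicalPartition(base))
})

test_that("edge weights follow the squared-distance similarity and its bounds", {
  # d = 0 at C.ar cutoff 1.38: similarity = 1.38^2 = 1.9044
  cloud <- testCloud(rbind(c(0, 0, 0), c(0, 0, 0)), type = "C.ar")
  e <- buildEdges(cloud)
  expect_equal(e$similarity, 1.9044)
  # d exactly at the cutoff: similarity 0, edge still present
  cloud2 <- testCloud(rbind(c(0, 0, 0), c(1.38, 0, 0)), type = "C.ar")
  e2 <- buildEdges(cloud2)
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$similarity, 0)
  # just beyond: no edge
  cloud3 <- testCloud(rbind(c(0, 0, 0), c(1.3801, 0, 0)), type = "C.ar")
  expect_equal(nrow(buildEdges(cloud3)), 0L)
})

test_that("edge construction matches the brute-force all-pairs oracle", {
  for (seed in c(7, 19, 101)) {
    cloud <- randomCloud(60, seed = seed, box = 5)
    got <- buildEdges(cloud)
    want <- edgeOracle(cloud)
    ord <- function(d) `rownames<-`(d[order(d$i, d$j), ], NULL)
    expect_equal(ord(got), ord(want), tolerance = 1e-12)
    cuts <- cutoffFor(defaultCutoffs(), got$effective_type)
    expect_true(all(got$similarity >= 0 & got$similarity <= cuts^2))
  }
})

test_that("ABC export re-imported reproduces the edge list exactly", {
  cloud <- randomCloud(50, seed = 31, box = 5)
  e <- buildEdges(cloud)
  path <- tempfile(fileext = ".abc")
  writeABC(e, path)
  got <- readABC(path, cloud)
  expect_equal(got$i, e$i)
  expect_equal(got$j, e$j)
  expect_equal(got$similarity, e$similarity, tolerance = 1e-9)
  expect_equal(got$effective_type, e$effective_type)
})

test_that("similar-type groups make listed types co-clusterable", {
  df <- data.frame(sybyl_type = c("C.2", "C.3"), effective_type = c("C.2", "C.3"),
                   x = c(0, 0.5), y = 0, z = 0, charge = 0,
                   source_entry = "t", source_atom_id = 1:2)
  cloud <- new("PointCloud", atoms = df)
  expect_length(greedyCluster(cloud), 2)  # different types never merge
  g <- similarityGroups(list(c("C.2", "C.3")))
  merged <- greedyCluster(applySimilarGroups(cloud, g), groups = g)
  expect_length(merged, 1)
  # empty groups are the identity
  expect_equal(atoms(applySimilarGroups(cloud, similarityGroups())), df)
})

test_that("merged-group clustering never yields more clusters than unmerged", {
  g <- similarityGroups(list(c("C.2", "C.3")))
  for (seed in 1:8) {
    set.seed(seed + 300)
    n <- 30
    df <- data.frame(sybyl_type = sample(c("C.2", "C.3"), n, TRUE),
                     effective_type = NA_character_,
                     x = runif(n, 0, 5), y = runif(n, 0, 5), z = runif(n, 0, 5),
                     charge = 0, source_entry = "t", source_atom_id = 1:n)
    df$effective_type <- df$sybyl_type
    cloud <- new("PointCloud", atoms = df)
    n_plain <- length(greedyCluster(cloud))
    n_merged <- length(greedyCluster(applySimilarGroups(cloud, g), groups = g))
    expect_lte(n_merged, n_plain)
  }
})

test_that("a merged group clusters with the max of its member cutoffs", {
  # C.3 cutoff ~1.458, H cutoff ~1.036: two atoms 1.2 A apart merge only
  # because the group inherits the larger C.3 radius
  df <- data.frame(sybyl_type = c("H", "H"), effective_type = c("H", "H"),
                   x = c(0, 1.2), y = 0, z = 0, charge = 0,
                   source_entry = "t", source_atom_id = 1:2)
  cloud <- new("PointCloud", atoms = df)
  expect_length(greedyCluster(cloud), 2)
  g <- similarityGroups(list(c("C.3", "H")))
  expect_length(greedyCluster(applySimilarGroups(cloud, g), groups = g), 1)
})

test_that("Markov clustering separates disconnected components and singletons", {
  xyz <- rbind(c(0, 0, 0), c(0.5, 0, 0), c(0.25, 0.4, 0),
               c(10, 0, 0), c(10.5, 0, 0), c(10.25, 0.4, 0))
  cloud <- testCloud(xyz)
  cl <- mclCluster(cloud, buildEdges(cloud), inflation = 2)
  expect_length(cl, 2)
  expect_equal(sort(vapply(cl, function(c) length(c$members), integer(1))),
               c(3L, 3L))
  # no edges at all: every atom a singleton
  far <- testCloud(rbind(c(0, 0, 0), c(10, 0, 0), c(20, 0, 0)))
  cl0 <- mclCluster(far, buildEdges(far))
  expect_length(cl0, 3)
  expect_true(all(vapply(cl0, function(c) length(c$members), integer(1)) == 1L))
})

test_that("larger inflation never coarsens the Markov partition", {
  for (seed in c(3, 14)) {
    cloud <- randomCloud(40, seed = seed, box = 5,
                         types = c("C.3", "C.ar"))
    e <- buildEdges(cloud)
    sizes <- vapply(c(2, 5, 10, 20), function(I)
      length(mclCluster(cloud, e, inflation = I)), integer(1))
    expect_true(all(diff(sizes) >= 0),
                info = paste("seed", seed, ":", paste(sizes, collapse = ",")))
  }
})

test_that("Markov clustering is identical for any thread count", {
  cloud <- randomCloud(30, seed = 9, box = 4)
  e <- buildEdges(cloud)
  expect_equal(canonicalPartition(mclCluster(cloud, e, 2, nThreads = 1)),
               canonicalPartition(mclCluster(cloud, e, 2, nThreads = 8)))
})

test_that("centroid atoms take the mean position and the max-magnitude charge", {
  df <- data.frame(sybyl_type = "C.3", effective_type = "C.3",
                   x = c(0, 1, 0.5), y = c(0, 0, 1), z = 0,
                   charge = c(0.10, -0.31, 0.20),
                   source_entry = "t", source_atom_id = 1:3)
  cloud <- new("PointCloud", atoms = df)
  model <- makeCentroids(cloud, list(list(members = 1:3, effective_type = "C.3",
                                          centroid = c(0.5, 1 / 3, 0))))
  a <- atoms(model)
  expect_equal(c(a$x, a$y, a$z), c(0.5, 1 / 3, 0))
  expect_equal(a$charge, -0.31)
  expect_equal(a$cluster_size, 3L)
  # singleton: identical to the input atom
  m1 <- makeCentroids(cloud, list(list(members = 2L, effective_type = "C.3",
                                       centroid = c(1, 0, 0))))
  expect_equal(atoms(m1)[, c("x", "y", "z", "charge")],
               df[2, c("x", "y", "z", "charge")], ignore_attr = TRUE)
})

test_that("model atom count never exceeds input count, with equality iff no pair is in range", {
  cloud <- randomCloud(80, seed = 66, box = 5)
  cl <- greedyCluster(cloud)
  model <- makeCentroids(cloud, cl)
  expect_lte(nAtoms(model), nAtoms(cloud))
  expect_equal(nAtoms(model) == nAtoms(cloud), nrow(buildEdges(cloud)) == 0)
  # well-separated atoms: identity
  sparse <- testCloud(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0)))
  expect_equal(nAtoms(makeCentroids(sparse, greedyCluster(sparse))), 3L)
})
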