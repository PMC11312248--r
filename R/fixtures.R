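.NEUTRAL_TYPES <- c("C.3", "C.ar", "N.am", "O.2", "S.3")

#' Generate hotspot anchor atoms
#'
#' Anchors are the planted binding-hotspot atoms a synthetic benchmark is
#' built around: typed, charged points in a cubic box with a minimum
#' pairwise separation of 2.5 A. A `chargedFraction` of them is charged
#' (`|q|` uniform in [0.3, 0.6], random sign; positive anchors are typed
#' `N.3`, negative `O.3`); the rest are near-neutral (`|q| <= 0.1`) with
#' types drawn from common neutral Sybyl types.
#'
#' @param nAnchors number of anchors (>= 3).
#' @param box cubic box edge length in Angstrom (default 12).
#' @param chargedFraction fraction of charged anchors in [0, 1].
#' @param seed integer seed; the generator is fully reproducible.
#' @return data.frame with `sybyl_type`, `x`, `y`, `z`, `charge`.
#' @export
makeAnchors <- function(nAnchors, box = 12, chargedFraction = 0.3, seed = 1) {
  stopifnot(nAnchors >= 3, box > 0)
  set.seed(seed)
  minsep <- 2.5
  pos <- matrix(NA_real_, nAnchors, 3)
  placed <- 0L
  attempts <- 0L
  while (placed < nAnchors) {
    attempts <- attempts + 1L
    if (attempts > 5000L * nAnchors)
      stop("box too small to place ", nAnchors,
           " anchors with 2.5 A separation; increase box")
    p <- runif(3, 0, box)
    if (placed == 0L ||
        min(sqrt(rowSums(sweep(pos[seq_len(placed), , drop = FALSE], 2, p)^2))) >= minsep) {
      placed <- placed + 1L
      pos[placed, ] <- p
    }
  }
  n_charged <- round(chargedFraction * nAnchors)
  charged <- seq_len(nAnchors) %in% sample(nAnchors, n_charged)
  q <- numeric(nAnchors); ty <- character(nAnchors)
  sign <- sample(c(-1, 1), nAnchors, replace = TRUE)
  q[charged] <- sign[charged] * runif(sum(charged), 0.3, 0.6)
  q[!charged] <- runif(sum(!charged), -0.1, 0.1)
  ty[charged] <- ifelse(q[charged] > 0, "N.3", "O.3")
  ty[!charged] <- sample(.NEUTRAL_TYPES, sum(!charged), replace = TRUE)
  data.frame(sybyl_type = ty, x = pos[, 1], y = pos[, 2], z = pos[, 3],
             charge = q, stringsAsFactors = FALSE)
}

.linkerPositions <- function(n, anchors, margin = 2) {
  lo <- vapply(anchors[, c("x", "y", "z")], min, numeric(1)) - margin
  hi <- vapply(anchors[, c("x", "y", "z")], max, numeric(1)) + margin
  out <- matrix(NA_real_, n, 3)
  got <- 0L
  while (got < n) {
    p <- c(runif(1, lo[1], hi[1]), runif(1, lo[2], hi[2]), runif(1, lo[3], hi[3]))
    d <- sqrt((anchors$x - p[1])^2 + (anchors$y - p[2])^2 + (anchors$z - p[3])^2)
    if (min(d) >= 2.0) { got <- got + 1L; out[got, ] <- p }
  }
  out
}

#' Generate synthetic active poses around the anchors
#'
#' Emulates the top-ranked docked poses of active ligands: each active
#' places one atom of the anchor's Sybyl type near a random subset
#' (fraction `occupancy`) of the anchors with isotropic Gaussian jitter of
#' standard deviation `jitterSd`, inheriting the anchor charge with noise
#' (sd 0.05 e), plus 2-6 random `C.3` linker atoms placed at least 2 A
#' away from every anchor. Entries are named `active_NNN_conf_01` and are
#' bond-free, round-trippable MOL2 molecules.
#'
#' @param anchors anchor data.frame from [makeAnchors()].
#' @param nLigands number of active poses.
#' @param jitterSd positional jitter sd in Angstrom (>= 0).
#' @param occupancy fraction of anchors each active occupies, in (0, 1].
#' @param seed integer seed.
#' @return list of [Mol2Molecule-class] entries.
#' @export
makeActivePoses <- function(anchors, nLigands, jitterSd = 0.3,
                            occupancy = 0.8, seed = 1) {
  stopifnot(jitterSd >= 0, occupancy > 0, occupancy <= 1)
  set.seed(seed)
  n_anch <- nrow(anchors)
  n_occ <- max(1L, round(occupancy * n_anch))
  lapply(seq_len(nLigands), function(i) {
    pick <- sort(sample(n_anch, n_occ))
    hot <- anchors[pick, , drop = FALSE]
    hx <- hot$x + rnorm(n_occ, 0, jitterSd)
    hy <- hot$y + rnorm(n_occ, 0, jitterSd)
    hz <- hot$z + rnorm(n_occ, 0, jitterSd)
    hq <- hot$charge + rnorm(n_occ, 0, 0.05)
    n_link <- sample(2:6, 1)
    lp <- .linkerPositions(n_link, anchors)
    df <- data.frame(
      sybyl_type = c(hot$sybyl_type, rep("C.3", n_link)),
      x = c(hx, lp[, 1]), y = c(hy, lp[, 2]), z = c(hz, lp[, 3]),
      charge = c(hq, runif(n_link, -0.05, 0.05)),
      stringsAsFactors = FALSE)
    mol2Molecule(sprintf("active_%03d_conf_01", i), df)
  })
}

#' Generate synthetic decoy poses
#'
#' Decoys have no hotspot structure: atom counts are drawn from the
#' actives' atom-count distribution, atom (type, charge) pairs are sampled
#' from the actives' pooled atoms, and positions are uniform in the box.
#' Entries are named `decoy_NNN_conf_01`.
#'
#' @param nDecoys number of decoy poses.
#' @param box cubic box edge length in Angstrom.
#' @param atomCounts integer vector to draw per-decoy atom counts from
#'   (typically the actives' counts).
#' @param atomPool data.frame with `sybyl_type` and `charge` to sample
#'   atoms from.
#' @param seed integer seed.
#' @return list of [Mol2Molecule-class] entries.
#' @export
makeDecoyPoses <- function(nDecoys, box = 12, atomCounts = 8:14,
                           atomPool = NULL, seed = 1) {
  set.seed(seed)
  if (is.null(atomPool))
    atomPool <- data.frame(sybyl_type = .NEUTRAL_TYPES,
                           charge = rep(0, length(.NEUTRAL_TYPES)),
                           stringsAsFactors = FALSE)
  lapply(seq_len(nDecoys), function(i) {
    n <- sample(rep(atomCounts, 2), 1)  # rep(): guard length-1 sample()
    rowsel <- sample(nrow(atomPool), n, replace = TRUE)
    df <- data.frame(
      sybyl_type = atomPool$sybyl_type[rowsel],
      x = runif(n, 0, box), y = runif(n, 0, box), z = runif(n, 0, box),
      charge = atomPool$charge[rowsel],
      stringsAsFactors = FALSE)
    mol2Molecule(sprintf("decoy_%03d_conf_01", i), df)
  })
}

#' Generate a full synthetic screening benchmark
#'
#' Anchors, actives, decoys, activity labels, and a stratified random
#' 70/30 train/test split (by label), reproducible bit-for-bit from the
#' seed. With `outDir` set, writes `poses.mol2`, `labels.tsv`,
#' `reference.mol2` (the anchors as a pseudo co-crystal ligand) and
#' `manifest.json`.
#'
#' @param nActives number of active compounds (>= 10; one pose each).
#' @param nDecoys number of decoy compounds (>= 10).
#' @param split training fraction (default 0.7).
#' @param seed integer seed driving all randomness.
#' @param nAnchors number of hotspot anchors (default 10).
#' @param box box edge length in Angstrom (default 12).
#' @param jitterSd active-pose jitter sd in Angstrom (default 0.3).
#' @param occupancy anchor occupancy per active (default 0.8).
#' @param chargedFraction fraction of charged anchors (default 0.3).
#' @param outDir optional output directory.
#' @return a [SyntheticBenchmark-class].
#' @export
makeBenchmark <- function(nActives = 50, nDecoys = 500, split = 0.7, seed = 1,
                          nAnchors = 10, box = 12, jitterSd = 0.3,
                          occupancy = 0.8, chargedFraction = 0.3,
                          outDir = NULL) {
  stopifnot(nActives >= 10, nDecoys >= 10, split > 0, split < 1)
  set.seed(seed)
  sub <- sample.int(2^31 - 1, 4)  # independent sub-streams per stage
  anchors <- makeAnchors(nAnchors, box, chargedFraction, seed = sub[1])
  actives <- makeActivePoses(anchors, nActives, jitterSd, occupancy,
                             seed = sub[2])
  counts <- vapply(actives, nAtoms, integer(1))
  pool <- do.call(rbind, lapply(actives, function(e)
    e@atoms[, c("sybyl_type", "charge")]))
  decoys <- makeDecoyPoses(nDecoys, box, counts, pool, seed = sub[3])
  labels <- data.frame(
    compound_id = c(sprintf("active_%03d", seq_len(nActives)),
                    sprintf("decoy_%03d", seq_len(nDecoys))),
    is_active = c(rep(TRUE, nActives), rep(FALSE, nDecoys)),
    subset = "test", stringsAsFactors = FALSE)
  set.seed(sub[4])
  tr_a <- sample(nActives, round(split * nActives))
  tr_d <- nActives + sample(nDecoys, round(split * nDecoys))
  labels$subset[c(tr_a, tr_d)] <- "train"
  manifest <- list(seed = seed, n_actives = nActives, n_decoys = nDecoys,
                   split = split, n_anchors = nAnchors, box = box,
                   jitter_sd = jitterSd, occupancy = occupancy,
                   charged_fraction = chargedFraction,
                   generator = "ShapePharm synthetic benchmark v1")
  bench <- new("SyntheticBenchmark", anchors = anchors,
               poses = c(actives, decoys), labels = labels,
               manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeMol2(bench@poses, file.path(outDir, "poses.mol2"))
    write.table(labels, file.path(outDir, "labels.tsv"), sep = "\t",
                row.names = FALSE, quote = FALSE)
    writeMol2(referenceLigand(bench), file.path(outDir, "reference.mol2"))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  bench
}

#' The anchor set as a pseudo co-crystal reference ligand
#'
#' Synthetic stand-in for an X-ray co-crystal ligand, used for pocket
#' limiting with [limitByReference()].
#'
#' @param bench a [SyntheticBenchmark-class].
#' @return a [Mol2Molecule-class].
#' @export
referenceLigand <- function(bench) {
  stopifnot(is(bench, "SyntheticBenchmark"))
  mol2Molecule("synthetic_reference", bench@anchors)
}

#' Poses and labels of one benchmark subset
#'
#' @param bench a [SyntheticBenchmark-class].
#' @param subset `"train"`, `"test"` or `"all"`.
#' @param activesOnly keep only active compounds?
#' @return list with `poses` (list of [Mol2Molecule-class]) and `labels`
#'   (data.frame).
#' @export
benchmarkSubset <- function(bench, subset = c("train", "test", "all"),
                            activesOnly = FALSE) {
  stopifnot(is(bench, "SyntheticBenchmark"))
  subset <- match.arg(subset)
  lb <- bench@labels
  keep <- if (subset == "all") rep(TRUE, nrow(lb)) else lb$subset == subset
  if (activesOnly) keep <- keep & lb$is_active
  list(poses = bench@poses[keep], labels = lb[keep, , drop = FALSE])
}

#' Pseudo-docking ranking table for a benchmark
#'
#' A deterministic stand-in for the docking score ranking used by
#' [selectTopActives()]: uniform pseudo-scores drawn from a seed derived
#' from the benchmark's manifest seed.
#'
#' @param bench a [SyntheticBenchmark-class].
#' @return data.frame with `ligand_id`, `pose_id`, `score`, `is_active`.
#' @export
benchmarkRanking <- function(bench) {
  stopifnot(is(bench, "SyntheticBenchmark"))
  set.seed((bench@manifest$seed + 7919L) %% (2^31 - 1))
  nm <- vapply(bench@poses, function(p) p@name, character(1))
  data.frame(ligand_id = bench@labels$compound_id, pose_id = nm,
             score = runif(length(nm)),
             is_active = bench@labels$is_active, stringsAsFactors = FALSE)
}
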