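#' Van der Waals radii used by the Gaussian shape scorer
#'
#' Fixed per-element table (Angstrom); elements outside the table default
#' to the carbon radius 1.70 A.
#'
#' @return named numeric vector of radii.
#' @export
vdwRadii <- function() {
  c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80, H = 1.20,
    F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98)
}

.elementOf <- function(type) sub("\\..*$", "", type)

# Gaussian exponent alpha such that the Gaussian's volume (amplitude 1)
# equals the hard sphere's: (pi/alpha)^{3/2} = (4/3) pi R^3.
.alphaFor <- function(types) {
  r <- vdwRadii()[.elementOf(types)]
  r[is.na(r)] <- 1.70
  pi * ((4 / 3) * pi * r^3)^(-2 / 3)
}

# total pairwise Gaussian overlap between atom sets, optionally
# charge-weighted: sum_ij w_i w_j (pi/(ai+aj))^{3/2} exp(-ai aj d2/(ai+aj))
.gaussOverlap <- function(xyzA, alphaA, xyzB, alphaB,
                          wA = NULL, wB = NULL) {
  asum <- outer(alphaA, alphaB, "+")
  aprod <- outer(alphaA, alphaB, "*")
  d2 <- outer(rowSums(xyzA^2), rowSums(xyzB^2), "+") -
    2 * (xyzA %*% t(xyzB))
  d2[d2 < 0] <- 0
  O <- (pi / asum)^1.5 * exp(-(aprod / asum) * d2)
  if (!is.null(wA)) O <- O * outer(wA, wB)
  sum(O)
}

.atomFrameOf <- function(x) {
  if (is(x, "CavityModel") || is(x, "Mol2Molecule") || is(x, "PointCloud"))
    return(atoms(x))
  as.data.frame(x)
}

#' Gaussian-volume shape similarity of two atom sets
#'
#' Each atom is a spherical Gaussian whose volume equals its hard
#' van-der-Waals sphere's; the score is the Gaussian-overlap Tanimoto
#' `O_ab / (O_aa + O_bb - O_ab)`, in [0, 1]: 1 for a perfect match, 0 in
#' the no-overlap limit. Symmetric and invariant under a joint rigid
#' motion of both sets.
#'
#' @param a,b atom sets: [CavityModel-class], [Mol2Molecule-class],
#'   [PointCloud-class] or a data.frame with `sybyl_type`, `x`, `y`, `z`.
#' @return numeric scalar in [0, 1].
#' @export
shapeSimilarity <- function(a, b) {
  fa <- .atomFrameOf(a); fb <- .atomFrameOf(b)
  if (nrow(fa) == 0 || nrow(fb) == 0)
    stop("shape similarity of an empty atom set is undefined")
  xa <- as.matrix(fa[, c("x", "y", "z")]); xb <- as.matrix(fb[, c("x", "y", "z")])
  aa <- .alphaFor(fa$sybyl_type); ab <- .alphaFor(fb$sybyl_type)
  Oab <- .gaussOverlap(xa, aa, xb, ab)
  Oaa <- .gaussOverlap(xa, aa, xa, aa)
  Obb <- .gaussOverlap(xb, ab, xb, ab)
  max(0, min(1, Oab / (Oaa + Obb - Oab)))
}

#' Electrostatic-potential similarity of two charged atom sets
#'
#' Each set's partial charges are smoothed into a Gaussian field (same
#' widths as the shape scorer); the normalized cross-correlation
#' `c` in [-1, 1] of the two fields is mapped to [0, 1] as `(1 + c)/2`.
#' Identical charged sets give 1; the same geometry with all charges
#' negated gives 0. When either field is identically zero (all-neutral
#' set) the score is the uninformative convention 0.5.
#'
#' @inheritParams shapeSimilarity
#' @return numeric scalar in [0, 1].
#' @export
espSimilarity <- function(a, b) {
  fa <- .atomFrameOf(a); fb <- .atomFrameOf(b)
  if (nrow(fa) == 0 || nrow(fb) == 0)
    stop("ESP similarity of an empty atom set is undefined")
  xa <- as.matrix(fa[, c("x", "y", "z")]); xb <- as.matrix(fb[, c("x", "y", "z")])
  aa <- .alphaFor(fa$sybyl_type); ab <- .alphaFor(fb$sybyl_type)
  Pab <- .gaussOverlap(xa, aa, xb, ab, fa$charge, fb$charge)
  Paa <- .gaussOverlap(xa, aa, xa, aa, fa$charge, fa$charge)
  Pbb <- .gaussOverlap(xb, ab, xb, ab, fb$charge, fb$charge)
  if (Paa < 1e-12 || Pbb < 1e-12) return(0.5)
  cc <- Pab / sqrt(Paa * Pbb)
  cc <- max(-1, min(1, cc))
  (1 + cc) / 2
}

#' Combined shape/ESP similarity of one pose against a model
#'
#' `w * shape + (1 - w) * esp` with shape weight `w` (default 0.5, the
#' 50/50 weighting; `w = 1` is shape-only scoring).
#'
#' @param model a [CavityModel-class] (or any atom set).
#' @param pose an atom set in the model's coordinate frame.
#' @param shapeWeight shape weight in [0, 1].
#' @return list with `shape`, `esp`, `combined`, each in [0, 1].
#' @export
similarityScore <- function(model, pose, shapeWeight = 0.5) {
  stopifnot(shapeWeight >= 0, shapeWeight <= 1)
  sh <- shapeSimilarity(model, pose)
  es <- if (shapeWeight < 1) espSimilarity(model, pose) else 0
  list(shape = sh, esp = es,
       combined = shapeWeight * sh + (1 - shapeWeight) * es)
}

.ligandIdOf <- function(names) sub("(_conf_?[0-9]+|_pose_?[0-9]+)$", "", names)

#' Rescore docked poses against a cavity model
#'
#' Scores every pose in place — no alignment optimization or superposition
#' (the fixed-pose, `-noOpt`-style mode) — and reduces multiple poses of
#' one ligand to the ligand's best (maximum) combined score. Poses must
#' already sit in the model's coordinate frame, as docked poses do.
#'
#' @param model a [CavityModel-class].
#' @param poses list of [Mol2Molecule-class] pose entries.
#' @param shapeWeight shape weight in [0, 1] (default 0.5; 1 = shape
#'   only).
#' @param ligandIds optional character vector of ligand ids, one per pose;
#'   by default a trailing `_conf_NN` / `_poseNN` suffix is stripped from
#'   the entry name.
#' @param aggregate `"max"` (best pose per ligand, default) or `"first"`
#'   (score only each ligand's first listed pose).
#' @return a [ScreenRanking-class]; its table carries per-ligand `shape`,
#'   `esp` and `combined` (= `score`) of the winning pose plus `pose_id`.
#' @export
rescore <- function(model, poses, shapeWeight = 0.5, ligandIds = NULL,
                    aggregate = c("max", "first")) {
  stopifnot(is(model, "CavityModel"))
  aggregate <- match.arg(aggregate)
  if (is(poses, "Mol2Molecule")) poses <- list(poses)
  if (length(poses) == 0) stop("no poses to rescore")
  nm <- vapply(poses, function(p) p@name, character(1))
  lig <- if (is.null(ligandIds)) .ligandIdOf(nm) else as.character(ligandIds)
  stopifnot(length(lig) == length(poses))
  if (aggregate == "first") {
    keep <- !duplicated(lig)
    poses <- poses[keep]; nm <- nm[keep]; lig <- lig[keep]
  }
  rows <- vector("list", length(poses))
  for (k in seq_along(poses)) {
    a <- poses[[k]]@atoms
    heavy <- a[!.isHydrogenType(a$sybyl_type), , drop = FALSE]
    if (nrow(heavy) == 0) {
      warning("pose '", nm[k], "' has no heavy atoms; skipped")
      next
    }
    sc <- similarityScore(model, poses[[k]], shapeWeight)
    rows[[k]] <- data.frame(compound_id = lig[k], pose_id = nm[k],
                            shape = sc$shape, esp = sc$esp,
                            score = sc$combined, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(df) || nrow(df) == 0) stop("no scoreable poses")
  # best pose per ligand
  df <- df[order(df$compound_id, -df$score, df$pose_id), , drop = FALSE]
  df <- df[!duplicated(df$compound_id), , drop = FALSE]
  screenRanking(df)
}

#' Attach activity labels to a screen ranking
#'
#' @param x a [ScreenRanking-class].
#' @param labels data.frame with `compound_id` and `is_active`.
#' @return the labeled [ScreenRanking-class].
#' @export
addLabels <- function(x, labels) {
  stopifnot(is(x, "ScreenRanking"))
  df <- x@ranking
  m <- match(df$compound_id, labels$compound_id)
  if (anyNA(m))
    stop("no label for compound(s): ",
         paste(head(df$compound_id[is.na(m)], 5), collapse = ", "))
  df$is_active <- as.logical(labels$is_active[m])
  screenRanking(df)
}
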