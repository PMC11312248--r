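.rotMat <- function(rx, ry, rz) {
  cx <- cos(rx); sx <- sin(rx); cy <- cos(ry); sy <- sin(ry)
  cz <- cos(rz); sz <- sin(rz)
  Rx <- matrix(c(1, 0, 0, 0, cx, -sx, 0, sx, cx), 3, 3, byrow = TRUE)
  Ry <- matrix(c(cy, 0, sy, 0, 1, 0, -sy, 0, cy), 3, 3, byrow = TRUE)
  Rz <- matrix(c(cz, -sz, 0, sz, cz, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  Rz %*% Ry %*% Rx
}

# apply a 6-parameter rigid motion (rotation about the set's centroid,
# then translation) to an n x 3 coordinate matrix
.applyTransform <- function(xyz, par, center) {
  R <- .rotMat(par[4], par[5], par[6])
  sweep(sweep(xyz, 2, center) %*% t(R), 2, center + par[1:3], "+")
}

.principalAxes <- function(xyz) {
  c0 <- colMeans(xyz)
  X <- sweep(xyz, 2, c0)
  eg <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  V <- eg$vectors
  if (det(V) < 0) V[, 3] <- -V[, 3]
  list(center = c0, axes = V, values = eg$values)
}

# derivative-free coordinate search over the 6 rigid-motion parameters
.refineAlignment <- function(scoreFun, xyz, center,
                             stepT = 0.5, stepR = 0.2,
                             tol = 1e-4, maxEval = 500L) {
  par <- rep(0, 6)
  best <- scoreFun(.applyTransform(xyz, par, center))
  evals <- 1L
  steps <- c(rep(stepT, 3), rep(stepR, 3))
  while (evals < maxEval && max(steps) > 1e-4) {
    improved <- FALSE
    for (p in 1:6) {
      for (sgn in c(1, -1)) {
        if (evals >= maxEval) break
        cand <- par
        cand[p] <- cand[p] + sgn * steps[p]
        val <- scoreFun(.applyTransform(xyz, cand, center))
        evals <- evals + 1L
        if (val > best + tol) { best <- val; par <- cand; improved <- TRUE }
      }
    }
    if (!improved) steps <- steps / 2
  }
  list(par = par, score = best, evals = evals)
}

# starting rigid transforms: principal-axes superposition of the conformer
# onto the model (4 proper axis-sign combinations, optionally also the
# inertia-order swaps), plus the identity placement
.alignmentStarts <- function(modelXyz, confXyz, orderSwaps = FALSE) {
  pm <- .principalAxes(modelXyz)
  pc <- .principalAxes(confXyz)
  degenerate <- pc$values[2] < 1e-8  # collinear conformer
  starts <- list(diag(3))  # identity rotation marker handled below
  out <- list(list(R = diag(3), shift = c(0, 0, 0)))  # original placement
  if (!degenerate) {
    signsets <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
    orders <- if (orderSwaps)
      list(c(1, 2, 3), c(2, 1, 3), c(1, 3, 2), c(3, 2, 1), c(2, 3, 1), c(3, 1, 2))
    else list(c(1, 2, 3))
    for (ord in orders) for (s in signsets) {
      Vc <- pc$axes[, ord, drop = FALSE] %*% diag(s)
      R <- pm$axes %*% t(Vc)
      if (det(R) < 0) next
      out[[length(out) + 1L]] <-
        list(R = R, shift = pm$center - as.vector(R %*% pc$center))
    }
  } else {
    # fallback: centroid alignment plus a coarse rotation grid
    grid <- seq(0, 2 * pi, length.out = 7)[-7]
    for (rx in grid[c(1, 3, 5)]) for (rz in grid) {
      R <- .rotMat(rx, 0, rz)
      out[[length(out) + 1L]] <-
        list(R = R, shift = pm$center - as.vector(R %*% pc$center))
    }
  }
  out
}

#' Rigid-dock free conformers onto a cavity model
#'
#' For each conformer, searches rigid-body placements maximizing the
#' combined shape/ESP similarity to the model: starting guesses come from
#' principal-axes superposition (the four proper axis-sign combinations;
#' `orderSwaps = TRUE` adds inertia-order permutations) plus the original
#' placement, each refined by a deterministic derivative-free coordinate
#' search over the six rigid-motion parameters (score tolerance 1e-4, at
#' most 500 evaluations per start). Degenerate (collinear) conformers fall
#' back to centroid alignment with a rotation grid. Multiple conformers of
#' one ligand reduce to the ligand's best score. Because the original
#' placement is among the starts, the rigid-docking score of a docked pose
#' is never below its fixed-pose [rescore()] score.
#'
#' @param model a [CavityModel-class].
#' @param conformers list of [Mol2Molecule-class] free 3D conformers.
#' @param shapeWeight shape weight in [0, 1] (default 0.5).
#' @param ligandIds optional ligand ids, one per conformer (default:
#'   strip a trailing pose suffix from the entry name).
#' @param orderSwaps also try inertia-axis order permutations as starts?
#' @return a [ScreenRanking-class] of best aligned scores per ligand.
#' @export
rigidDock <- function(model, conformers, shapeWeight = 0.5, ligandIds = NULL,
                      orderSwaps = FALSE) {
  stopifnot(is(model, "CavityModel"))
  if (is(conformers, "Mol2Molecule")) conformers <- list(conformers)
  if (length(conformers) == 0) stop("no conformers to dock")
  nm <- vapply(conformers, function(p) p@name, character(1))
  lig <- if (is.null(ligandIds)) .ligandIdOf(nm) else as.character(ligandIds)
  fm <- model@atoms
  modelXyz <- as.matrix(fm[, c("x", "y", "z")])
  rows <- vector("list", length(conformers))
  for (k in seq_along(conformers)) {
    a <- conformers[[k]]@atoms
    xyz <- as.matrix(a[, c("x", "y", "z")])
    probe <- a
    scoreFun <- function(newXyz) {
      probe$x <- newXyz[, 1]; probe$y <- newXyz[, 2]; probe$z <- newXyz[, 3]
      sh <- shapeSimilarity(fm, probe)
      if (shapeWeight < 1)
        shapeWeight * sh + (1 - shapeWeight) * espSimilarity(fm, probe)
      else sh
    }
    best <- -Inf
    for (st in .alignmentStarts(modelXyz, xyz, orderSwaps)) {
      placed <- sweep(xyz %*% t(st$R), 2, st$shift, "+")
      ref <- .refineAlignment(scoreFun, placed, colMeans(placed))
      if (ref$score > best) best <- ref$score
    }
    rows[[k]] <- data.frame(compound_id = lig[k], pose_id = nm[k],
                            score = best, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  df <- df[order(df$compound_id, -df$score, df$pose_id), , drop = FALSE]
  df <- df[!duplicated(df$compound_id), , drop = FALSE]
  screenRanking(df)
}
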