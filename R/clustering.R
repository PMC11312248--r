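#' Map atom types onto their similar-group representatives
#'
#' Sets each atom's `effective_type` to the canonical representative of its
#' group (the lexicographically first token), so atoms of the grouped types
#' become co-clusterable. Original Sybyl types are retained for output
#' labeling. Atoms whose type is in no group keep their own type.
#'
#' @param cloud a [PointCloud-class].
#' @param groups a [SimilarityGroups-class].
#' @return a [PointCloud-class] with updated effective types.
#' @export
applySimilarGroups <- function(cloud, groups) {
  stopifnot(is(cloud, "PointCloud"), is(groups, "SimilarityGroups"))
  df <- cloud@atoms
  df$effective_type <- df$sybyl_type
  for (g in groups@groups) {
    if (length(g) == 0) next
    rep_tok <- sort(g)[1]
    df$effective_type[df$sybyl_type %in% g] <- rep_tok
  }
  new("PointCloud", atoms = df)
}

.effectiveCutoffs <- function(cloud, cutoffs, groups = NULL) {
  # per effective type: the cutoff of that type, or for a merged group the
  # max over the group's member-type cutoffs
  df <- cloud@atoms
  eff <- unique(df$effective_type)
  out <- setNames(cutoffFor(cutoffs, eff), eff)
  if (!is.null(groups)) {
    for (g in groups@groups) {
      if (length(g) == 0) next
      rep_tok <- sort(g)[1]
      if (rep_tok %in% eff)
        out[rep_tok] <- max(cutoffFor(cutoffs, g))
    }
  }
  out
}

#' Greedy shortest-pair clustering of a point cloud
#'
#' The default clustering: independently for each effective atom type,
#' repeatedly find the globally shortest pair among the current items
#' (atoms or clusters, a cluster located at its running centroid) with
#' distance at most the type's cutoff, merge the pair, recompute the
#' centroid, and repeat until no pair is within the cutoff. Distance ties
#' are broken by (smaller first item index, then smaller second index), so
#' the result is deterministic. Every atom ends in exactly one cluster;
#' isolated atoms become singletons.
#'
#' @param cloud a [PointCloud-class] (effective types already set if
#'   similar groups are in use).
#' @param cutoffs a [CutoffTable-class].
#' @param groups optional [SimilarityGroups-class] used only to widen the
#'   cutoff of merged groups to the max over member types.
#' @return list of clusters, each `list(members, effective_type, centroid)`
#'   with `members` indexing rows of `atoms(cloud)`; attribute
#'   `"merge_log"` records every merge as a data.frame (`effective_type`,
#'   `distance`, `cutoff`).
#' @export
greedyCluster <- function(cloud, cutoffs = defaultCutoffs(), groups = NULL) {
  stopifnot(is(cloud, "PointCloud"))
  df <- cloud@atoms
  if (nrow(df) == 0) stop("cannot cluster an empty cloud")
  effcut <- .effectiveCutoffs(cloud, cutoffs, groups)
  clusters <- list()
  log_type <- character(0); log_d <- numeric(0); log_cut <- numeric(0)
  for (ty in sort(unique(df$effective_type))) {
    idx <- which(df$effective_type == ty)
    cut <- effcut[[ty]]
    pos <- as.matrix(df[idx, c("x", "y", "z")])
    members <- as.list(seq_along(idx))
    cent <- pos
    repeat {
      k <- nrow(cent)
      if (k < 2) break
      dm <- as.matrix(stats::dist(cent))
      dm[lower.tri(dm, diag = TRUE)] <- Inf
      d <- min(dm)
      if (!is.finite(d) || d > cut) break
      cand <- which(dm == d, arr.ind = TRUE)  # ties: smallest (i, then j)
      best <- cand[order(cand[, 1], cand[, 2])[1], ]
      i <- best[[1]]; j <- best[[2]]
      log_type <- c(log_type, ty); log_d <- c(log_d, d); log_cut <- c(log_cut, cut)
      members[[i]] <- c(members[[i]], members[[j]])
      members[[j]] <- NULL
      cent[i, ] <- colMeans(pos[members[[i]], , drop = FALSE])
      cent <- cent[-j, , drop = FALSE]
    }
    for (s in seq_along(members)) {
      clusters[[length(clusters) + 1L]] <- list(
        members = idx[members[[s]]],
        effective_type = ty,
        centroid = colMeans(pos[members[[s]], , drop = FALSE]))
    }
  }
  attr(clusters, "merge_log") <- data.frame(
    effective_type = log_type, distance = log_d, cutoff = log_cut,
    stringsAsFactors = FALSE)
  clusters
}

#' Build the same-type similarity edge list
#'
#' For every pair of atoms sharing an effective type with distance `d` at
#' most the type's cutoff `MAX`, emits one edge weighted by the
#' squared-distance similarity `MAX^2 - d^2` (>= 0, with 0 exactly at
#' `d = MAX`). This is the weighted graph on which Markov clustering
#' operates; it exports to the ABC text format via [writeABC()].
#'
#' @inheritParams greedyCluster
#' @return data.frame with columns `i`, `j` (row indices into
#'   `atoms(cloud)`, `i < j`), `similarity`, `effective_type`.
#' @export
buildEdges <- function(cloud, cutoffs = defaultCutoffs(), groups = NULL) {
  stopifnot(is(cloud, "PointCloud"))
  df <- cloud@atoms
  effcut <- .effectiveCutoffs(cloud, cutoffs, groups)
  out <- list()
  for (ty in sort(unique(df$effective_type))) {
    idx <- which(df$effective_type == ty)
    if (length(idx) < 2) next
    cut <- effcut[[ty]]
    dm <- as.matrix(stats::dist(df[idx, c("x", "y", "z")]))
    sel <- which(upper.tri(dm) & dm <= cut, arr.ind = TRUE)
    if (nrow(sel) == 0) next
    out[[ty]] <- data.frame(
      i = idx[sel[, 1]], j = idx[sel[, 2]],
      similarity = cut^2 - dm[sel]^2,
      effective_type = ty, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(i = integer(0), j = integer(0), similarity = numeric(0),
                      effective_type = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$i, res$j), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Write an edge list in ABC format
#'
#' Whitespace-separated `id_i id_j weight` lines, one per edge — the
#' interchange format of Markov-clustering tools.
#'
#' @param edges edge data.frame from [buildEdges()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeABC <- function(edges, path) {
  writeLines(sprintf("%d\t%d\t%.10g", edges$i, edges$j, edges$similarity),
             path)
  invisible(path)
}

#' Read an ABC edge file
#'
#' @param path path to a file of `id_i id_j weight` lines.
#' @param cloud optional [PointCloud-class] used to restore the
#'   `effective_type` column.
#' @return edge data.frame (`i`, `j`, `similarity`, `effective_type`).
#' @export
readABC <- function(path, cloud = NULL) {
  if (!file.exists(path)) stop("ABC file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0)
    return(data.frame(i = integer(0), j = integer(0), similarity = numeric(0),
                      effective_type = character(0), stringsAsFactors = FALSE))
  f <- do.call(rbind, strsplit(trimws(lines), "\\s+"))
  df <- data.frame(i = as.integer(f[, 1]), j = as.integer(f[, 2]),
                   similarity = as.numeric(f[, 3]),
                   effective_type = NA_character_, stringsAsFactors = FALSE)
  if (!is.null(cloud)) df$effective_type <- cloud@atoms$effective_type[df$i]
  df
}

#' Turn clusters into a cavity model of centroid atoms
#'
#' One model atom per cluster at the arithmetic-mean position. The atom is
#' typed by the cluster's representative original Sybyl type (the most
#' common member type; lexicographic tie-break) and charged by the member
#' charge of maximal magnitude — the partial charge with the biggest
#' difference against zero; a magnitude tie takes the lower-index member.
#' Cluster size is recorded as provenance.
#'
#' @param cloud the clustered [PointCloud-class].
#' @param clusters cluster list from [greedyCluster()] or [mclCluster()].
#' @param settings named list stored as the model's settings fingerprint.
#' @return a [CavityModel-class].
#' @export
makeCentroids <- function(cloud, clusters, settings = list()) {
  stopifnot(is(cloud, "PointCloud"))
  if (length(clusters) == 0) stop("no clusters to convert")
  df <- cloud@atoms
  rows <- lapply(clusters, function(cl) {
    m <- cl$members
    tys <- df$sybyl_type[m]
    tt <- table(tys)
    rep_ty <- sort(names(tt)[tt == max(tt)])[1]
    q <- df$charge[m]
    qi <- which(abs(q) == max(abs(q)))[1]  # tie -> lower-index member
    data.frame(sybyl_type = rep_ty,
               x = mean(df$x[m]), y = mean(df$y[m]), z = mean(df$z[m]),
               charge = q[qi], cluster_size = length(m),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$atom_id <- seq_len(nrow(out))
  cavityModel(out, settings = settings)
}
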