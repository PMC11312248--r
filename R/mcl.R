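#' Markov clustering of the same-type similarity graph
#'
#' Native Markov Cluster (MCL) process run independently on each effective
#' type's weighted subgraph: self-loops (weight = the node's maximum
#' incident edge weight, or 1 for isolated nodes) are added, columns are
#' normalized to stochastic, then expansion (matrix squaring) alternates
#' with inflation (entrywise power `inflation` followed by column
#' renormalization), pruning entries below 1e-6, until the matrix changes
#' by less than 1e-8 (max absolute entry difference) or 200 iterations.
#' Larger inflation values increase inequality among transition
#' probabilities and refine the partition. Clusters are the connected
#' components of the converged matrix's nonzero structure (attractor
#' systems plus the nodes they attract); atoms with no edge become
#' singletons. Fully deterministic; `nThreads` is accepted for interface
#' compatibility and never affects the partition.
#'
#' @param cloud a [PointCloud-class].
#' @param edges edge data.frame from [buildEdges()] (or [readABC()]).
#' @param inflation inflation exponent, >= 1 (default 2).
#' @param nThreads ignored beyond validation; the partition is identical
#'   for any value.
#' @return cluster list in the same shape as [greedyCluster()] returns.
#' @export
mclCluster <- function(cloud, edges, inflation = 2, nThreads = 1) {
  stopifnot(is(cloud, "PointCloud"), inflation >= 1, nThreads >= 1)
  df <- cloud@atoms
  n <- nrow(df)
  if (n == 0) stop("cannot cluster an empty cloud")
  assignment <- integer(n)  # cluster id per atom
  next_id <- 0L
  for (ty in sort(unique(df$effective_type))) {
    idx <- which(df$effective_type == ty)
    e <- edges[edges$i %in% idx & edges$j %in% idx, , drop = FALSE]
    if (nrow(e) == 0) {
      assignment[idx] <- next_id + seq_along(idx)
      next_id <- next_id + length(idx)
      next
    }
    comp <- .mclComponents(idx, e, inflation)
    assignment[idx] <- next_id + comp
    next_id <- next_id + max(comp)
  }
  ids <- sort(unique(assignment))
  clusters <- lapply(ids, function(cid) {
    m <- which(assignment == cid)
    list(members = m, effective_type = df$effective_type[m[1]],
         centroid = c(mean(df$x[m]), mean(df$y[m]), mean(df$z[m])))
  })
  clusters
}

# MCL on one type's subgraph; returns component id (1..k) per node of idx
.mclComponents <- function(idx, e, inflation,
                           prune = 1e-6, tol = 1e-8, max_iter = 200L) {
  k <- length(idx)
  loc <- match(seq_along(idx), seq_along(idx))  # identity; nodes are 1..k
  ii <- match(e$i, idx); jj <- match(e$j, idx)
  M <- matrix(0, k, k)
  M[cbind(ii, jj)] <- e$similarity
  M[cbind(jj, ii)] <- e$similarity
  # self-loops: max incident weight (1 for isolated nodes)
  loops <- apply(M, 2, max)
  loops[loops <= 0] <- 1
  diag(M) <- loops
  M <- sweep(M, 2, colSums(M), "/")
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    M2 <- M %*% M                      # expansion
    M2 <- M2^inflation                 # inflation
    M2[M2 < prune] <- 0
    cs <- colSums(M2)
    cs[cs == 0] <- 1
    M2 <- sweep(M2, 2, cs, "/")
    if (max(abs(M2 - M)) < tol) { M <- M2; converged <- TRUE; break }
    M <- M2
  }
  if (!converged)
    warning("MCL did not converge in ", max_iter,
            " iterations; returning current partition")
  # clusters = connected components of the nonzero structure
  A <- (M > prune) | (t(M) > prune)
  comp <- integer(k)
  cid <- 0L
  for (s in seq_len(k)) {
    if (comp[s] != 0L) next
    cid <- cid + 1L
    queue <- s
    comp[s] <- cid
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(A[v, ] & comp == 0L)
      comp[nb] <- cid
      queue <- c(queue, nb)
    }
  }
  comp
}
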