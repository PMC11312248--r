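#' Atom table of a molecule-like object
#'
#' @param x a [Mol2Molecule-class], [PointCloud-class] or
#'   [CavityModel-class].
#' @return the atom data.frame.
#' @export
setGeneric("atoms", function(x) standardGeneric("atoms"))

#' @rdname atoms
#' @export
setMethod("atoms", "Mol2Molecule", function(x) x@atoms)
#' @rdname atoms
#' @export
setMethod("atoms", "PointCloud", function(x) x@atoms)
#' @rdname atoms
#' @export
setMethod("atoms", "CavityModel", function(x) x@atoms)

#' Number of atoms
#' @param x an object with an atom table.
#' @return integer atom count.
#' @export
setGeneric("nAtoms", function(x) standardGeneric("nAtoms"))
#' @rdname nAtoms
#' @export
setMethod("nAtoms", "Mol2Molecule", function(x) nrow(x@atoms))
#' @rdname nAtoms
#' @export
setMethod("nAtoms", "PointCloud", function(x) nrow(x@atoms))
#' @rdname nAtoms
#' @export
setMethod("nAtoms", "CavityModel", function(x) nrow(x@atoms))

#' Atom coordinates as an n x 3 matrix
#' @param x an object with an atom table.
#' @return numeric matrix with columns x, y, z (Angstrom).
#' @export
coords <- function(x) {
  df <- atoms(x)
  as.matrix(df[, c("x", "y", "z")])
}

#' Restrict atoms to a pocket around a reference ligand
#'
#' Keeps exactly the atoms whose distance to the nearest reference heavy
#' atom is at most `radius` (default 2.0 Angstrom). Reference hydrogens are
#' ignored. Works on the merged input cloud (before modeling) or on a
#' finished cavity model (after modeling); the two orders are both valid
#' and neither is preferred.
#'
#' @param x a [PointCloud-class] or [CavityModel-class].
#' @param reference a [Mol2Molecule-class], e.g. the X-ray co-crystal
#'   ligand.
#' @param radius pocket radius in Angstrom, > 0.
#' @return an object of the same class as `x`.
#' @export
setGeneric("limitByReference",
           function(x, reference, radius = 2.0) standardGeneric("limitByReference"))

#' Ranking table of a screen
#' @param x a [ScreenRanking-class].
#' @return the ranking data.frame, sorted by descending score.
#' @export
ranking <- function(x) {
  stopifnot(is(x, "ScreenRanking"))
  x@ranking
}

#' Settings fingerprint of a cavity model
#' @param x a [CavityModel-class].
#' @return named list of generating options.
#' @export
modelSettings <- function(x) {
  stopifnot(is(x, "CavityModel"))
  x@settings
}

#' Generations table of an optimization trace
#' @param x an [OptimizationTrace-class].
#' @return data.frame of per-generation removals.
#' @export
generations <- function(x) {
  stopifnot(is(x, "OptimizationTrace"))
  x@generations
}

setMethod("show", "Mol2Molecule", function(object) {
  cat(sprintf("Mol2Molecule '%s': %d atoms, %d bonds\n",
              object@name, nrow(object@atoms), nrow(object@bonds)))
})

setMethod("show", "PointCloud", function(object) {
  tys <- sort(table(object@atoms$sybyl_type), decreasing = TRUE)
  cat(sprintf("PointCloud: %d atoms from %d entries; %d Sybyl types\n",
              nrow(object@atoms), length(unique(object@atoms$source_entry)),
              length(tys)))
  if (length(tys) > 0)
    cat("  top types:", paste(sprintf("%s(%d)", names(head(tys, 6)),
                                      head(tys, 6)), collapse = " "), "\n")
})

setMethod("show", "CutoffTable", function(object) {
  cat(sprintf("CutoffTable: %d typed cutoffs, fallback %.3f A\n",
              length(object@cutoffs), object@globalFallback))
})

setMethod("show", "SimilarityGroups", function(object) {
  cat(sprintf("SimilarityGroups: %d group(s)\n", length(object@groups)))
  for (g in object@groups) cat("  {", paste(g, collapse = ", "), "}\n")
})

setMethod("show", "CavityModel", function(object) {
  cat(sprintf("CavityModel: %d atoms (cluster sizes %d-%d)\n",
              nrow(object@atoms), min(object@atoms$cluster_size),
              max(object@atoms$cluster_size)))
  tys <- sort(table(object@atoms$sybyl_type), decreasing = TRUE)
  cat("  types:", paste(sprintf("%s(%d)", names(tys), tys), collapse = " "), "\n")
})

setMethod("show", "ScreenRanking", function(object) {
  df <- object@ranking
  na <- sum(df$is_active %in% TRUE); nd <- sum(df$is_active %in% FALSE)
  cat(sprintf("ScreenRanking: %d compounds (%d actives, %d decoys)\n",
              nrow(df), na, nd))
})

setMethod("show", "OptimizationTrace", function(object) {
  g <- object@generations
  cat(sprintf("OptimizationTrace: %d generation(s), %s %.4f -> %.4f\n",
              nrow(g), object@metric, object@initialMetric,
              if (nrow(g) > 0) g$metric_after[nrow(g)] else object@initialMetric))
})

setMethod("show", "SyntheticBenchmark", function(object) {
  lb <- object@labels
  cat(sprintf(
    "SyntheticBenchmark: %d anchors; %d actives / %d decoys (train %d / test %d); seed %s\n",
    nrow(object@anchors), sum(lb$is_active), sum(!lb$is_active),
    sum(lb$subset == "train"), sum(lb$subset == "test"),
    as.character(object@manifest$seed)))
})
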