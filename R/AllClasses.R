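#' @import methods
#' @importFrom stats setNames rnorm runif
#' @importFrom utils head read.delim write.table
NULL

.validAtomFrame <- function(df, required) {
  miss <- setdiff(required, names(df))
  if (length(miss) > 0)
    return(sprintf("missing atom columns: %s", paste(miss, collapse = ", ")))
  if (nrow(df) > 0) {
    if (!all(is.finite(df$x)) || !all(is.finite(df$y)) || !all(is.finite(df$z)))
      return("atom coordinates must be finite")
    if (any(!nzchar(df$sybyl_type)))
      return("sybyl_type must be non-empty for every atom")
  }
  TRUE
}

#' A single molecule entry from a Sybyl MOL2 file
#'
#' Holds one `@<TRIPOS>MOLECULE` record: an ordered atom table (id, name,
#' Sybyl atom type, coordinates in Angstrom, partial charge in elementary
#' charge units) and a bond table. Created by [readMol2()] or
#' [mol2Molecule()].
#'
#' @slot name entry name (deduplicated across a multi-entry file).
#' @slot atoms data.frame with columns `atom_id`, `name`, `sybyl_type`,
#'   `x`, `y`, `z`, `charge`.
#' @slot bonds data.frame with columns `from`, `to`, `order` (order is the
#'   MOL2 order token, e.g. `"1"`, `"2"`, `"ar"`, `"am"`).
#' @exportClass Mol2Molecule
setClass("Mol2Molecule",
  representation(name = "character", atoms = "data.frame", bonds = "data.frame"))

setValidity("Mol2Molecule", function(object) {
  df <- object@atoms
  ok <- .validAtomFrame(df, c("atom_id", "name", "sybyl_type", "x", "y", "z", "charge"))
  if (!isTRUE(ok)) return(ok)
  if (nrow(df) == 0) return("molecule entry has zero atoms")
  if (anyDuplicated(df$atom_id)) return("atom_id values must be unique within an entry")
  b <- object@bonds
  if (nrow(b) > 0 && !all(c(b$from, b$to) %in% df$atom_id))
    return("bond endpoints must reference existing atom ids")
  TRUE
})

#' Constructor for a Mol2Molecule
#'
#' @param name entry name.
#' @param atoms atom data.frame (`atom_id`, `name`, `sybyl_type`, `x`, `y`,
#'   `z`, `charge`); `atom_id` defaults to `1:nrow`, `name` to the type.
#' @param bonds optional bond data.frame (`from`, `to`, `order`).
#' @return a [Mol2Molecule-class] object.
#' @export
mol2Molecule <- function(name, atoms, bonds = NULL) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$atom_id)) atoms$atom_id <- seq_len(nrow(atoms))
  if (is.null(atoms$name)) atoms$name <- atoms$sybyl_type
  if (is.null(atoms$charge)) atoms$charge <- 0
  atoms <- atoms[, c("atom_id", "name", "sybyl_type", "x", "y", "z", "charge")]
  rownames(atoms) <- NULL
  if (is.null(bonds))
    bonds <- data.frame(from = integer(0), to = integer(0), order = character(0),
                        stringsAsFactors = FALSE)
  new("Mol2Molecule", name = as.character(name), atoms = atoms,
      bonds = as.data.frame(bonds))
}

#' Bond-free point cloud of typed, charged atoms
#'
#' The clustering substrate: atoms from one or several merged molecule
#' entries with all covalent bonding information discarded. Each atom keeps
#' its Sybyl type, partial charge, an effective type used during clustering
#' (identical to the Sybyl type until similar-type groups are applied), and
#' provenance (source entry name and original atom id).
#'
#' @slot atoms data.frame with columns `sybyl_type`, `effective_type`, `x`,
#'   `y`, `z`, `charge`, `source_entry`, `source_atom_id`.
#' @exportClass PointCloud
setClass("PointCloud", representation(atoms = "data.frame"))

setValidity("PointCloud", function(object) {
  .validAtomFrame(object@atoms,
    c("sybyl_type", "effective_type", "x", "y", "z", "charge",
      "source_entry", "source_atom_id"))
})

#' Atom-type search-radius table
#'
#' Maps Sybyl atom types to the clustering search radius (the cutoff
#' distance, in Angstrom, below which two same-type atoms may merge).
#' Defaults derive from GAFF equilibrium bond lengths reduced by 5%, with
#' the fixed value 1.38 A for all aromatic (`.ar`) types; see
#' [defaultCutoffs()]. Types absent from the table fall back to
#' `globalFallback`.
#'
#' @slot cutoffs named numeric vector, Angstrom.
#' @slot globalFallback numeric scalar used for unlisted types.
#' @exportClass CutoffTable
setClass("CutoffTable",
  representation(cutoffs = "numeric", globalFallback = "numeric"))

setValidity("CutoffTable", function(object) {
  if (length(object@cutoffs) > 0 && is.null(names(object@cutoffs)))
    return("cutoffs must be named by Sybyl type")
  if (any(!is.finite(object@cutoffs)) || any(object@cutoffs <= 0))
    return("every cutoff must be a positive finite number")
  if (length(object@globalFallback) != 1 || !is.finite(object@globalFallback) ||
      object@globalFallback <= 0)
    return("globalFallback must be a single positive number")
  TRUE
})

#' Groups of Sybyl types treated as one type during clustering
#'
#' @slot groups list of character vectors; a type token appears in at most
#'   one group.
#' @exportClass SimilarityGroups
setClass("SimilarityGroups", representation(groups = "list"))

setValidity("SimilarityGroups", function(object) {
  toks <- unlist(object@groups, use.names = FALSE)
  if (length(toks) > 0 && !is.character(toks))
    return("groups must contain character type tokens")
  if (anyDuplicated(toks))
    return(sprintf("type token appears in more than one group: %s",
                   paste(unique(toks[duplicated(toks)]), collapse = ", ")))
  TRUE
})

#' Constructor for SimilarityGroups
#' @param groups list of character vectors of Sybyl type tokens.
#' @return a [SimilarityGroups-class] object.
#' @export
similarityGroups <- function(groups = list()) {
  new("SimilarityGroups", groups = lapply(groups, as.character))
}

#' Shape-focused pharmacophore (cavity) model
#'
#' The product of the clustering pipeline: centroid atoms with Sybyl types,
#' positions, partial charges, and the size of the originating cluster as
#' provenance. `settings` is a fingerprint of the options that generated the
#' model; replaying it reproduces the model.
#'
#' @slot atoms data.frame with columns `atom_id`, `sybyl_type`, `x`, `y`,
#'   `z`, `charge`, `cluster_size`.
#' @slot settings named list recording the generating configuration.
#' @exportClass CavityModel
setClass("CavityModel",
  representation(atoms = "data.frame", settings = "list"))

setValidity("CavityModel", function(object) {
  df <- object@atoms
  ok <- .validAtomFrame(df, c("atom_id", "sybyl_type", "x", "y", "z",
                              "charge", "cluster_size"))
  if (!isTRUE(ok)) return(ok)
  if (nrow(df) == 0) return("cavity model has zero atoms")
  if (any(df$cluster_size < 1)) return("cluster_size must be >= 1")
  if (anyDuplicated(df$atom_id)) return("model atom_id values must be unique")
  TRUE
})

#' Constructor for a CavityModel
#' @param atoms data.frame with `sybyl_type`, `x`, `y`, `z`, `charge`,
#'   `cluster_size` (and optionally `atom_id`).
#' @param settings named list fingerprint of generating options.
#' @return a [CavityModel-class] object.
#' @export
cavityModel <- function(atoms, settings = list()) {
  atoms <- as.data.frame(atoms)
  if (is.null(atoms$atom_id)) atoms$atom_id <- seq_len(nrow(atoms))
  if (is.null(atoms$cluster_size)) atoms$cluster_size <- 1L
  atoms <- atoms[, c("atom_id", "sybyl_type", "x", "y", "z", "charge",
                     "cluster_size")]
  rownames(atoms) <- NULL
  new("CavityModel", atoms = atoms, settings = settings)
}

#' Scored, labeled compound ranking from a virtual screen
#'
#' One row per compound: the similarity (or docking) score and the
#' active/decoy label. Enrichment metrics ([rocAuc()], [efd()], [bedroc()])
#' are computed from this object. Rows are stored sorted by descending
#' score; tied scores are ordered actives-last so reported enrichment never
#' benefits from ties.
#'
#' @slot ranking data.frame with columns `compound_id`, `score`,
#'   `is_active` (logical; may be NA until labels are attached), plus any
#'   extra score components.
#' @exportClass ScreenRanking
setClass("ScreenRanking", representation(ranking = "data.frame"))

setValidity("ScreenRanking", function(object) {
  df <- object@ranking
  miss <- setdiff(c("compound_id", "score", "is_active"), names(df))
  if (length(miss) > 0)
    return(sprintf("missing ranking columns: %s", paste(miss, collapse = ", ")))
  if (nrow(df) > 0 && any(!is.finite(df$score)))
    return("scores must be finite")
  if (anyDuplicated(df$compound_id))
    return("compound_id values must be unique")
  TRUE
})

#' Constructor for a ScreenRanking
#'
#' Sorts by descending score with the pessimistic tie order (actives last
#' within a tied score).
#'
#' @param ranking data.frame with `compound_id`, `score` and optionally
#'   `is_active`.
#' @return a [ScreenRanking-class] object.
#' @export
screenRanking <- function(ranking) {
  df <- as.data.frame(ranking)
  if (is.null(df$is_active)) df$is_active <- NA
  df$is_active <- as.logical(df$is_active)
  act <- ifelse(is.na(df$is_active), FALSE, df$is_active)
  df <- df[order(-df$score, act, as.character(df$compound_id)), , drop = FALSE]
  rownames(df) <- NULL
  new("ScreenRanking", ranking = df)
}

#' Record of an enrichment-driven greedy optimization run
#'
#' One row per generation of single-atom removal: the id of the deleted
#' model atom, the training metric after deletion, and the remaining atom
#' count. The training metric is strictly increasing across generations.
#'
#' @slot generations data.frame with columns `generation`,
#'   `removed_atom_id`, `metric_after`, `n_atoms_after`.
#' @slot initialMetric training metric of the starting model.
#' @slot metric name of the optimized metric (e.g. `"bedroc"`).
#' @slot settings named list (alpha, shape weight, ...).
#' @exportClass OptimizationTrace
setClass("OptimizationTrace",
  representation(generations = "data.frame", initialMetric = "numeric",
                 metric = "character", settings = "list"))

setValidity("OptimizationTrace", function(object) {
  g <- object@generations
  miss <- setdiff(c("generation", "removed_atom_id", "metric_after",
                    "n_atoms_after"), names(g))
  if (length(miss) > 0)
    return(sprintf("missing trace columns: %s", paste(miss, collapse = ", ")))
  if (nrow(g) > 0) {
    vals <- c(object@initialMetric, g$metric_after)
    if (any(diff(vals) <= 0)) return("metric must strictly increase per generation")
    if (any(diff(g$n_atoms_after) != -1L) && nrow(g) > 1)
      return("atom count must decrease by exactly 1 per generation")
  }
  TRUE
})

#' Synthetic docked-pose benchmark
#'
#' A self-contained virtual-screening benchmark: hotspot anchors, active
#' poses whose atoms co-localize with the anchors under jitter, spatially
#' random decoy poses, activity labels, and a stratified train/test split.
#' Reproducible bit-for-bit from its parameters and seed (see `manifest`).
#'
#' @slot anchors data.frame of hotspot atoms (`sybyl_type`, `x`, `y`, `z`,
#'   `charge`).
#' @slot poses list of [Mol2Molecule-class] pose entries (actives then
#'   decoys), one pose per compound.
#' @slot labels data.frame `compound_id`, `is_active`, `subset`
#'   (`"train"`/`"test"`).
#' @slot manifest named list of every generator parameter including the
#'   seed.
#' @exportClass SyntheticBenchmark
setClass("SyntheticBenchmark",
  representation(anchors = "data.frame", poses = "list", labels = "data.frame",
                 manifest = "list"))

setValidity("SyntheticBenchmark", function(object) {
  lb <- object@labels
  miss <- setdiff(c("compound_id", "is_active", "subset"), names(lb))
  if (length(miss) > 0)
    return(sprintf("missing label columns: %s", paste(miss, collapse = ", ")))
  if (!all(lb$subset %in% c("train", "test")))
    return("subset must be 'train' or 'test'")
  if (length(object@poses) != nrow(lb))
    return("one pose entry per labeled compound required")
  TRUE
})
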