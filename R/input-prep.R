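.isHydrogenType <- function(type) type == "H" | startsWith(type, "H.")

#' Read a pose ranking table
#'
#' A delimited text table with columns `ligand_id`, `pose_id`, `score`,
#' `is_active` (logical or 0/1). `pose_id` values match the entry names of
#' the pose MOL2 file; `ligand_id` groups poses of one ligand.
#'
#' @param path path to a tab- or comma-delimited file with a header.
#' @return data.frame with those four columns.
#' @export
readPoseRanking <- function(path) {
  if (!file.exists(path)) stop("ranking table not found: ", path)
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE)
  need <- c("ligand_id", "pose_id", "score", "is_active")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("ranking table missing columns: ", paste(miss, collapse = ", "))
  df$is_active <- as.logical(df$is_active)
  if (anyDuplicated(df[, c("ligand_id", "pose_id")]))
    stop("(ligand_id, pose_id) pairs must be unique in the ranking table")
  df[, need]
}

#' Select the best pose of the top-ranked active ligands
#'
#' Mirrors the model-input recipe: from the docking ranking, take the
#' `nLigands` best-scoring active ligands and, for each, exactly its
#' best-ranked pose (the `conf_01` analogue). Higher score = better rank by
#' default (`decreasing = TRUE`); flip for energy-like scores. Ties in
#' score are broken by ligand id lexicographically, so the selection is
#' deterministic under input shuffling.
#'
#' @param entries list of [Mol2Molecule-class] pose entries; entry names
#'   match `pose_id` in the ranking.
#' @param rankingTable data.frame as returned by [readPoseRanking()].
#' @param nLigands number of active ligands to keep (default 50).
#' @param decreasing is a larger score a better rank?
#' @return list of [Mol2Molecule-class], one best pose per selected ligand,
#'   in ranking order.
#' @export
selectTopActives <- function(entries, rankingTable, nLigands = 50,
                             decreasing = TRUE) {
  rk <- rankingTable[rankingTable$is_active %in% TRUE, , drop = FALSE]
  if (nrow(rk) == 0) stop("ranking table contains no active ligands")
  s <- if (decreasing) -rk$score else rk$score
  rk <- rk[order(s, as.character(rk$ligand_id), as.character(rk$pose_id)), ,
           drop = FALSE]
  best <- rk[!duplicated(rk$ligand_id), , drop = FALSE]  # best pose per ligand
  if (nrow(best) < nLigands) {
    warning(sprintf("only %d active ligands available (requested %d)",
                    nrow(best), nLigands))
    nLigands <- nrow(best)
  }
  best <- best[seq_len(nLigands), , drop = FALSE]
  nm <- vapply(entries, function(e) e@name, character(1))
  idx <- match(best$pose_id, nm)
  if (anyNA(idx))
    stop("pose entry not found for ligand(s): ",
         paste(best$ligand_id[is.na(idx)], collapse = ", "))
  entries[idx]
}

#' Remove non-polar hydrogens from a molecule entry
#'
#' Hydrogens bonded to carbon are removed; hydrogens bonded to N/O/S (or
#' any non-carbon heavy atom) are polar and retained. When an H has no bond
#' record, the nearest heavy atom within 1.2 A classifies it; an
#' unclassifiable H is retained with a warning. Heavy atoms are never
#' touched; bonds to removed atoms are dropped.
#'
#' @param entry a [Mol2Molecule-class].
#' @return a [Mol2Molecule-class] with non-polar hydrogens removed.
#' @export
stripNonpolarHydrogens <- function(entry) {
  stopifnot(is(entry, "Mol2Molecule"))
  a <- entry@atoms
  isH <- .isHydrogenType(a$sybyl_type)
  if (!any(isH)) return(entry)
  b <- entry@bonds
  drop <- logical(nrow(a))
  unclassified <- character(0)
  heavy <- a[!isH, , drop = FALSE]
  for (j in which(isH)) {
    id <- a$atom_id[j]
    nbr <- c(b$to[b$from == id], b$from[b$to == id])
    if (length(nbr) > 0) {
      ntypes <- a$sybyl_type[match(nbr, a$atom_id)]
      drop[j] <- any(startsWith(ntypes, "C.") | ntypes == "C")
    } else if (nrow(heavy) > 0) {
      d2 <- (heavy$x - a$x[j])^2 + (heavy$y - a$y[j])^2 + (heavy$z - a$z[j])^2
      near <- which(d2 <= 1.2^2)
      if (length(near) == 0) {
        unclassified <- c(unclassified, a$name[j])
      } else {
        nt <- heavy$sybyl_type[near[which.min(d2[near])]]
        drop[j] <- startsWith(nt, "C.") || nt == "C"
      }
    } else {
      unclassified <- c(unclassified, a$name[j])
    }
  }
  if (length(unclassified) > 0)
    warning("hydrogen(s) retained, cannot classify (no bond, no heavy atom within 1.2 A): ",
            paste(unclassified, collapse = ", "))
  if (!any(drop)) return(entry)
  keep_ids <- a$atom_id[!drop]
  bonds <- b[b$from %in% keep_ids & b$to %in% keep_ids, , drop = FALSE]
  rownames(bonds) <- NULL
  new("Mol2Molecule", name = entry@name,
      atoms = `rownames<-`(a[!drop, , drop = FALSE], NULL), bonds = bonds)
}

#' Merge molecule entries into a bond-free point cloud
#'
#' All atoms of all entries become one [PointCloud-class]; covalent bonds
#' are discarded and per-atom provenance (source entry and original atom
#' id) is recorded.
#'
#' @param entries list of [Mol2Molecule-class] (>= 1).
#' @return a [PointCloud-class].
#' @export
mergeToCloud <- function(entries) {
  if (is(entries, "Mol2Molecule")) entries <- list(entries)
  if (length(entries) == 0) stop("no entries to merge")
  parts <- lapply(entries, function(e) {
    a <- e@atoms
    data.frame(sybyl_type = a$sybyl_type, effective_type = a$sybyl_type,
               x = a$x, y = a$y, z = a$z, charge = a$charge,
               source_entry = e@name, source_atom_id = a$atom_id,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, parts)
  rownames(df) <- NULL
  new("PointCloud", atoms = df)
}

.limitAtomFrame <- function(df, reference, radius) {
  stopifnot(is(reference, "Mol2Molecule"))
  if (!is.finite(radius)) return(rep(TRUE, nrow(df)))
  if (radius <= 0) stop("radius must be > 0")
  ra <- reference@atoms
  ra <- ra[!.isHydrogenType(ra$sybyl_type), , drop = FALSE]
  if (nrow(ra) == 0) stop("reference ligand has no heavy atoms")
  keep <- logical(nrow(df))
  for (j in seq_len(nrow(df))) {
    d2 <- (ra$x - df$x[j])^2 + (ra$y - df$y[j])^2 + (ra$z - df$z[j])^2
    keep[j] <- min(d2) <= radius^2
  }
  keep
}

#' @rdname limitByReference
#' @export
setMethod("limitByReference", "PointCloud", function(x, reference, radius = 2.0) {
  keep <- .limitAtomFrame(x@atoms, reference, radius)
  if (!any(keep))
    stop("no atoms within ", radius, " A of the reference; use a larger radius")
  new("PointCloud", atoms = `rownames<-`(x@atoms[keep, , drop = FALSE], NULL))
})

#' @rdname limitByReference
#' @export
setMethod("limitByReference", "CavityModel", function(x, reference, radius = 2.0) {
  keep <- .limitAtomFrame(x@atoms, reference, radius)
  if (!any(keep))
    stop("no model atoms within ", radius, " A of the reference; use a larger radius")
  st <- x@settings
  st$limit_radius <- radius
  new("CavityModel", atoms = `rownames<-`(x@atoms[keep, , drop = FALSE], NULL),
      settings = st)
})
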