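#' Drop model atoms from small clusters
#'
#' Removes every model atom whose originating cluster had fewer than
#' `minSize` members — the `--clustermin` post-filter that focuses the
#' model on features shared by multiple closely aligned active ligands.
#'
#' @param model a [CavityModel-class].
#' @param minSize minimum cluster size to keep (>= 1).
#' @return a filtered [CavityModel-class].
#' @export
applyClusterMin <- function(model, minSize) {
  stopifnot(is(model, "CavityModel"), minSize >= 1)
  keep <- model@atoms$cluster_size >= minSize
  if (!any(keep))
    stop("no clusters of size >= ", minSize, "; use a smaller --clustermin")
  st <- model@settings; st$clustermin <- max(minSize, st$clustermin %||% 1)
  new("CavityModel",
      atoms = `rownames<-`(model@atoms[keep, , drop = FALSE], NULL),
      settings = st)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Drop charged model atoms from small clusters
#'
#' The `--clusterminchr` post-filter: an atom counts as charged when its
#' partial charge magnitude strictly exceeds `threshold` (the
#' `--nibthreshold` value, default 0.2 e); charged atoms from clusters
#' smaller than `minSizeCharged` are removed, neutral atoms are untouched.
#'
#' @param model a [CavityModel-class].
#' @param minSizeCharged minimum cluster size for charged atoms (>= 1).
#' @param threshold charge-magnitude threshold in elementary charges.
#' @return a filtered [CavityModel-class].
#' @export
applyClusterMinChr <- function(model, minSizeCharged, threshold = 0.2) {
  stopifnot(is(model, "CavityModel"), minSizeCharged >= 1)
  a <- model@atoms
  charged <- abs(a$charge) > threshold
  keep <- !charged | a$cluster_size >= minSizeCharged
  if (!any(keep))
    stop("clusterminchr filter removed every model atom")
  st <- model@settings
  st$clusterminchr <- minSizeCharged; st$nibthreshold <- threshold
  new("CavityModel", atoms = `rownames<-`(a[keep, , drop = FALSE], NULL),
      settings = st)
}

#' Delete model atoms of listed Sybyl types
#'
#' The `--deletetypes` post-filter (e.g. to drop dummy `Du` atoms).
#'
#' @param model a [CavityModel-class].
#' @param types character vector of Sybyl type tokens to remove.
#' @return a filtered [CavityModel-class].
#' @export
deleteTypes <- function(model, types) {
  stopifnot(is(model, "CavityModel"))
  if (length(types) == 0) return(model)
  keep <- !(model@atoms$sybyl_type %in% types)
  if (!any(keep))
    stop("--deletetypes removed every model atom")
  st <- model@settings; st$deletetypes <- types
  new("CavityModel",
      atoms = `rownames<-`(model@atoms[keep, , drop = FALSE], NULL),
      settings = st)
}

#' Convert a model to negative-image-style atom classes
#'
#' The `--nib` conversion: every model atom becomes positive `N.3`
#' (charge > +threshold), negative `O.3` (charge < -threshold), or neutral
#' `C.ar` (originally aromatic) / `C.3` (otherwise). By default the
#' threshold values replace the charges (+threshold / -threshold / 0); with
#' `keepCharges = TRUE` (the `--nibcharged` option) the original partial
#' charges are retained. Idempotent in both charge modes.
#'
#' @param model a [CavityModel-class].
#' @param threshold charge classification threshold, > 0 (default 0.2 e).
#' @param keepCharges retain original charges instead of the threshold
#'   values?
#' @return a converted [CavityModel-class].
#' @export
nibConvert <- function(model, threshold = 0.2, keepCharges = FALSE) {
  stopifnot(is(model, "CavityModel"), threshold > 0)
  st0 <- model@settings
  # already converted with the same settings: a no-op (classification is
  # strict ">", so rewritten +/-threshold charges must not reclassify)
  if (isTRUE(st0$nib) && identical(st0$nibthreshold, threshold) &&
      identical(st0$nibcharged, keepCharges))
    return(model)
  a <- model@atoms
  pos <- a$charge > threshold
  neg <- a$charge < -threshold
  neu <- !pos & !neg
  aromatic <- .isAromaticType(a$sybyl_type)
  a$sybyl_type[pos] <- "N.3"
  a$sybyl_type[neg] <- "O.3"
  a$sybyl_type[neu] <- ifelse(aromatic[neu], "C.ar", "C.3")
  if (!keepCharges) {
    a$charge[pos] <- threshold
    a$charge[neg] <- -threshold
    a$charge[neu] <- 0
  }
  st <- model@settings
  st$nib <- TRUE; st$nibthreshold <- threshold; st$nibcharged <- keepCharges
  new("CavityModel", atoms = a, settings = st)
}
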