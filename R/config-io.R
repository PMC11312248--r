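#' Read a JSON cutoff-override configuration
#'
#' The JSON object maps Sybyl type tokens to positive distances in
#' Angstrom, e.g. `{"C.3": 1.10}`. Listed types override the base table;
#' unlisted types keep their defaults (or the global fallback). Overrides
#' win even for aromatic types.
#'
#' @param path path to the JSON file.
#' @param base base [CutoffTable-class] to override; defaults to
#'   [defaultCutoffs()].
#' @return a [CutoffTable-class].
#' @export
readCutoffConfig <- function(path, base = defaultCutoffs()) {
  if (!file.exists(path)) stop("cutoff config not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (length(cfg) == 0) return(base)
  if (is.null(names(cfg)) || any(!nzchar(names(cfg))))
    stop("cutoff config must be a JSON object mapping types to distances")
  cut <- base@cutoffs
  for (key in names(cfg)) {
    val <- cfg[[key]]
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val) || val <= 0)
      stop("invalid cutoff for type '", key, "': must be a positive number")
    cut[key] <- as.numeric(val)
  }
  new("CutoffTable", cutoffs = cut, globalFallback = base@globalFallback)
}

#' Read a JSON similar-type-group configuration
#'
#' The JSON is a list of groups, each a list of Sybyl type tokens to be
#' treated as one type during clustering, e.g. `[["N.3","N.4"]]`. A token
#' may appear in at most one group.
#'
#' @param path path to the JSON file.
#' @return a [SimilarityGroups-class].
#' @export
readSimilarConfig <- function(path) {
  if (!file.exists(path)) stop("similar-types config not found: ", path)
  cfg <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  groups <- lapply(cfg, function(g) vapply(g, as.character, character(1)))
  toks <- unlist(groups, use.names = FALSE)
  if (anyDuplicated(toks))
    stop("type token appears in more than one similar group: ",
         paste(unique(toks[duplicated(toks)]), collapse = ", "))
  similarityGroups(groups)
}

#' Parse a comma-separated similar-group string
#'
#' CLI form of the similar-type configuration: groups separated by `;`,
#' members by `,` (e.g. `"C.2,C.3;N.3,N.4"`).
#'
#' @param spec character scalar.
#' @return a [SimilarityGroups-class].
#' @export
parseSimilarSpec <- function(spec) {
  if (is.null(spec) || !nzchar(spec)) return(similarityGroups())
  groups <- lapply(strsplit(spec, ";", fixed = TRUE)[[1]], function(g)
    trimws(strsplit(g, ",", fixed = TRUE)[[1]]))
  groups <- lapply(groups, function(g) g[nzchar(g)])
  toks <- unlist(groups)
  if (anyDuplicated(toks))
    stop("type token appears in more than one similar group: ",
         paste(unique(toks[duplicated(toks)]), collapse = ", "))
  similarityGroups(groups)
}

#' Render similar-type groups as printable lines
#'
#' The format emitted by the `--showsimilar` CLI option.
#'
#' @param groups a [SimilarityGroups-class].
#' @return character vector of lines, one group per line.
#' @export
formatSimilarGroups <- function(groups) {
  stopifnot(is(groups, "SimilarityGroups"))
  if (length(groups@groups) == 0) return("(no similar-type groups)")
  vapply(groups@groups, function(g) paste(g, collapse = ","), character(1))
}
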