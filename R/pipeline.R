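#' Build a shape-focused pharmacophore model from pose entries
#'
#' The full modeling pipeline: strip non-polar hydrogens, merge the
#' entries into a bond-free point cloud, optionally map similar-type
#' groups, cluster (greedy shortest-pair merging by default, or native
#' Markov clustering with `method = "mcl"`), emit centroid atoms, then
#' apply the post-filters in the fixed order deletetypes -> clustermin ->
#' clusterminchr -> nib conversion. Optionally limits the cloud to a
#' pocket around a reference ligand before clustering (`limitWhen =
#' "before"`) or the model after (`"after"`). Every option is recorded in
#' the model's settings fingerprint.
#'
#' @param entries list of [Mol2Molecule-class] pose entries (already
#'   selected, e.g. via [selectTopActives()]).
#' @param method `"greedy"` (default) or `"mcl"`.
#' @param cutoffs a [CutoffTable-class] (default [defaultCutoffs()]).
#' @param groups optional [SimilarityGroups-class].
#' @param inflation MCL inflation (default 2; used when `method="mcl"`).
#' @param clustermin minimum cluster size kept (default 1 = keep all).
#' @param clusterminchr minimum cluster size for charged atoms (default 1).
#' @param deletetypes character vector of Sybyl types to drop entirely.
#' @param nib convert atoms to negative-image classes (N.3/O.3/C.3/C.ar)?
#' @param nibthreshold charge classification threshold (default 0.2 e).
#' @param nibcharged keep original charges after nib conversion?
#' @param stripH strip non-polar hydrogens first (default TRUE)?
#' @param reference optional [Mol2Molecule-class] pocket reference.
#' @param limitRadius pocket radius in Angstrom (default 2.0).
#' @param limitWhen `"before"` (cloud) or `"after"` (model).
#' @return a [CavityModel-class].
#' @export
buildModel <- function(entries, method = c("greedy", "mcl"),
                       cutoffs = defaultCutoffs(), groups = NULL,
                       inflation = 2, clustermin = 1, clusterminchr = 1,
                       deletetypes = character(0), nib = FALSE,
                       nibthreshold = 0.2, nibcharged = FALSE,
                       stripH = TRUE, reference = NULL, limitRadius = 2.0,
                       limitWhen = c("before", "after")) {
  method <- match.arg(method)
  limitWhen <- match.arg(limitWhen)
  if (is(entries, "Mol2Molecule")) entries <- list(entries)
  if (stripH) entries <- lapply(entries, stripNonpolarHydrogens)
  cloud <- mergeToCloud(entries)
  if (!is.null(reference) && limitWhen == "before")
    cloud <- limitByReference(cloud, reference, limitRadius)
  if (!is.null(groups)) cloud <- applySimilarGroups(cloud, groups)
  clusters <- if (method == "greedy") {
    greedyCluster(cloud, cutoffs, groups)
  } else {
    mclCluster(cloud, buildEdges(cloud, cutoffs, groups), inflation)
  }
  settings <- list(method = method, inflation = inflation,
                   clustermin = clustermin, clusterminchr = clusterminchr,
                   deletetypes = deletetypes, nib = nib,
                   nibthreshold = nibthreshold, nibcharged = nibcharged,
                   strip_hydrogens = stripH,
                   global_cutoff = cutoffs@globalFallback,
                   n_input_atoms = nAtoms(cloud),
                   filter_order = "deletetypes,clustermin,clusterminchr,nib")
  model <- makeCentroids(cloud, clusters, settings = settings)
  if (length(deletetypes) > 0) model <- deleteTypes(model, deletetypes)
  if (clustermin > 1) model <- applyClusterMin(model, clustermin)
  if (clusterminchr > 1)
    model <- applyClusterMinChr(model, clusterminchr, nibthreshold)
  if (nib) model <- nibConvert(model, nibthreshold, nibcharged)
  if (!is.null(reference) && limitWhen == "after")
    model <- limitByReference(model, reference, limitRadius)
  model
}
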