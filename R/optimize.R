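.trainMetric <- function(model, poses, labels, shapeWeight,
                         metric, alpha, efdFraction, ligandIds = NULL) {
  rk <- addLabels(rescore(model, poses, shapeWeight, ligandIds = ligandIds),
                  labels)
  switch(metric,
         bedroc = bedroc(rk, alpha),
         auc = rocAuc(rk)$auc,
         efd = efd(rk, efdFraction))
}

#' Greedy enrichment-driven model optimization
#'
#' Backward-elimination search over model atoms: each generation rescores
#' the training set once per candidate single-atom deletion and adopts the
#' deletion that improves the training metric (BEDROC with `alpha = 20` by
#' default) the most; the reduced model becomes the template for the next
#' generation. The search stops when no deletion strictly improves the
#' metric (by more than 1e-12) or the model has shrunk to `minAtoms`
#' atoms. Candidate evaluations are independent; they are scanned in atom
#' order and an improvement tie is resolved to the lowest atom id, so the
#' trace is deterministic.
#'
#' @param model starting [CavityModel-class] with more than `minAtoms`
#'   atoms.
#' @param trainingPoses list of [Mol2Molecule-class] docked training
#'   poses.
#' @param labels data.frame with `compound_id`, `is_active` covering the
#'   training ligands (both classes required).
#' @param shapeWeight shape weight used during rescoring (default 0.5).
#' @param metric optimized metric: `"bedroc"` (default), `"auc"` or
#'   `"efd"`.
#' @param alpha BEDROC alpha (default 20).
#' @param efdFraction decoy percentage when `metric = "efd"`.
#' @param minAtoms smallest allowed model (default 3).
#' @param ligandIds optional ligand ids for the training poses.
#' @return list with `model` (the optimized [CavityModel-class]) and
#'   `trace` (an [OptimizationTrace-class]).
#' @export
greedyOptimize <- function(model, trainingPoses, labels, shapeWeight = 0.5,
                           metric = c("bedroc", "auc", "efd"), alpha = 20,
                           efdFraction = 1, minAtoms = 3, ligandIds = NULL) {
  stopifnot(is(model, "CavityModel"))
  metric <- match.arg(metric)
  if (nAtoms(model) <= minAtoms)
    stop("model must have more than minAtoms = ", minAtoms, " atoms")
  current <- model
  initial <- .trainMetric(current, trainingPoses, labels, shapeWeight,
                          metric, alpha, efdFraction, ligandIds)
  best_now <- initial
  gen <- list()
  repeat {
    a <- current@atoms
    if (nrow(a) <= minAtoms) break
    cand_val <- rep(NA_real_, nrow(a))
    for (k in seq_len(nrow(a))) {
      reduced <- new("CavityModel",
                     atoms = `rownames<-`(a[-k, , drop = FALSE], NULL),
                     settings = current@settings)
      cand_val[k] <- .trainMetric(reduced, trainingPoses, labels, shapeWeight,
                                  metric, alpha, efdFraction, ligandIds)
    }
    top <- max(cand_val)
    if (!(top > best_now + 1e-12)) break
    k <- which(cand_val == top)[1]  # tie -> lowest atom id (atom order)
    removed_id <- a$atom_id[k]
    current <- new("CavityModel",
                   atoms = `rownames<-`(a[-k, , drop = FALSE], NULL),
                   settings = current@settings)
    best_now <- top
    gen[[length(gen) + 1L]] <- data.frame(
      generation = length(gen) + 1L, removed_atom_id = removed_id,
      metric_after = top, n_atoms_after = nrow(current@atoms))
  }
  trace <- new("OptimizationTrace",
               generations = if (length(gen) > 0) do.call(rbind, gen) else
                 data.frame(generation = integer(0),
                            removed_atom_id = integer(0),
                            metric_after = numeric(0),
                            n_atoms_after = integer(0)),
               initialMetric = initial, metric = metric,
               settings = list(alpha = alpha, shape_weight = shapeWeight,
                               efd_fraction = efdFraction,
                               min_atoms = minAtoms))
  st <- current@settings
  st$optimized <- TRUE; st$opt_metric <- metric; st$opt_alpha <- alpha
  current@settings <- st
  list(model = current, trace = trace)
}

#' Replay an optimization trace against its starting model
#'
#' Deletes the traced atom ids in order from `model` and returns the
#' resulting model; identical to the optimizer's final model.
#'
#' @param model the starting [CavityModel-class].
#' @param trace an [OptimizationTrace-class].
#' @return a [CavityModel-class].
#' @export
replayTrace <- function(model, trace) {
  stopifnot(is(model, "CavityModel"), is(trace, "OptimizationTrace"))
  a <- model@atoms
  for (id in trace@generations$removed_atom_id)
    a <- a[a$atom_id != id, , drop = FALSE]
  new("CavityModel", atoms = `rownames<-`(a, NULL),
      settings = model@settings)
}
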