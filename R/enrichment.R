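.rankingFrame <- function(r, requireLabels = TRUE) {
  df <- if (is(r, "ScreenRanking")) r@ranking else {
    screenRanking(as.data.frame(r))@ranking
  }
  if (requireLabels) {
    if (any(is.na(df$is_active)))
      stop("ranking has unlabeled compounds; attach labels first")
    if (!any(df$is_active) || all(df$is_active))
      stop("both actives and decoys are required for enrichment metrics")
  }
  df
}

#' ROC AUC of a labeled ranking, with Wilcoxon-statistic error
#'
#' The area under the ROC curve equals the Mann-Whitney U statistic
#' divided by `n_actives * n_decoys`, with tied scores credited 0.5. The
#' standard error uses the Hanley-McNeil (Wilcoxon statistic) formula.
#' Invariant under strictly monotone transformation of the scores.
#'
#' @param r a [ScreenRanking-class] (or a data.frame with `compound_id`,
#'   `score`, `is_active`).
#' @return list with `auc` and `se`.
#' @export
rocAuc <- function(r) {
  df <- .rankingFrame(r)
  na <- sum(df$is_active); nd <- sum(!df$is_active)
  rk <- rank(df$score)  # ties share the average rank -> 0.5 credit
  U <- sum(rk[df$is_active]) - na * (na + 1) / 2
  auc <- U / (na * nd)
  Q1 <- auc / (2 - auc)
  Q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (na - 1) * (Q1 - auc^2) +
                (nd - 1) * (Q2 - auc^2)) / (na * nd))
  list(auc = auc, se = se)
}

#' Enrichment factor at a decoy fraction (EFd)
#'
#' Walks the descending ranking until `ceiling(fraction/100 * n_decoys)`
#' decoys have been encountered and returns the true-positive rate at that
#' depth as a percentage: `100 * actives_seen / n_actives`. Tied scores
#' rank actives last (pessimistic), so the reported value never benefits
#' from ties.
#'
#' @param r a [ScreenRanking-class] or compatible data.frame.
#' @param decoyFraction decoy percentage in (0, 100], e.g. 1.0.
#' @return true-positive rate in percent (0-100).
#' @export
efd <- function(r, decoyFraction) {
  stopifnot(decoyFraction > 0, decoyFraction <= 100)
  df <- .rankingFrame(r)
  na <- sum(df$is_active); nd <- sum(!df$is_active)
  k <- ceiling(decoyFraction / 100 * nd)
  decoys_seen <- cumsum(!df$is_active)
  stop_at <- which(decoys_seen >= k)[1]
  actives_seen <- sum(df$is_active[seq_len(stop_at)])
  100 * actives_seen / na
}

#' BEDROC early-recognition metric
#'
#' Boltzmann-enhanced discrimination of the ROC (Truchon-Bailey): the
#' exponentially weighted sum `sum(exp(-alpha * r_i / N))` over the active
#' ranks `r_i` is converted to the robust initial enhancement (RIE) and
#' min/max-normalized to [0, 1]. `alpha = 20` (BR20) weights roughly the
#' top 8% of the ranking. Tied scores rank actives last (pessimistic).
#'
#' @param r a [ScreenRanking-class] or compatible data.frame.
#' @param alpha early-recognition weight, > 0 (default 20).
#' @return BEDROC value in [0, 1].
#' @export
bedroc <- function(r, alpha = 20) {
  stopifnot(alpha > 0)
  df <- .rankingFrame(r)
  N <- nrow(df)
  na <- sum(df$is_active)
  ra <- na / N
  ranks <- which(df$is_active)
  s <- sum(exp(-alpha * ranks / N))
  rie_denom <- ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1)
  rie <- s / rie_denom
  bed <- rie * ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * ra)) +
    1 / (1 - exp(alpha * (1 - ra)))
  max(0, min(1, bed))
}

#' ROC curve points, with a semilog-ready export
#'
#' Returns the (false-positive rate, true-positive rate) curve traversed
#' in descending score order, one point per distinct score threshold (tied
#' scores advance diagonally, so the trapezoidal area under the curve
#' equals [rocAuc()]'s tie-credited AUC). The `fpr_log` column clamps the
#' FPR to at least `1/n_decoys` for plotting on a logarithmic axis.
#'
#' @param r a [ScreenRanking-class] or compatible data.frame.
#' @return data.frame with `fpr`, `tpr`, `fpr_log`.
#' @export
semilogRoc <- function(r) {
  df <- .rankingFrame(r)
  na <- sum(df$is_active); nd <- sum(!df$is_active)
  # one point per distinct threshold
  grp <- cumsum(!duplicated(df$score))
  tp <- cumsum(df$is_active); fp <- cumsum(!df$is_active)
  last <- !duplicated(grp, fromLast = TRUE)
  fpr <- c(0, fp[last] / nd)
  tpr <- c(0, tp[last] / na)
  data.frame(fpr = fpr, tpr = tpr, fpr_log = pmax(fpr, 1 / nd))
}

#' Trapezoidal area under a ROC curve
#'
#' @param curve data.frame from [semilogRoc()].
#' @return numeric area (equals [rocAuc()]'s AUC).
#' @export
aucFromCurve <- function(curve) {
  sum(diff(curve$fpr) * (head(curve$tpr, -1) + curve$tpr[-1]) / 2)
}

#' Full enrichment report for a labeled ranking
#'
#' @param r a [ScreenRanking-class] or compatible data.frame.
#' @param fractions decoy percentages for [efd()] (default 0.1, 0.5, 1, 5).
#' @param alpha BEDROC alpha (default 20).
#' @return list with `auc`, `auc_se`, `efd` (named vector, %), `bedroc`,
#'   `n_actives`, `n_decoys`.
#' @export
enrichmentReport <- function(r, fractions = c(0.1, 0.5, 1, 5), alpha = 20) {
  df <- .rankingFrame(r)
  a <- rocAuc(df)
  ef <- vapply(fractions, function(f) efd(df, f), numeric(1))
  names(ef) <- sprintf("%g%%", fractions)
  list(auc = a$auc, auc_se = a$se, efd = ef, bedroc = bedroc(df, alpha),
       n_actives = sum(df$is_active), n_decoys = sum(!df$is_active))
}
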