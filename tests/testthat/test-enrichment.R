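rankingOf <- function(scores, labels) {
  screenRanking(data.frame(
    compound_id = sprintf("c%03d", seq_along(scores)),
    score = scores, is_active = labels))
}

test_that("AUC is 1 for perfect separation and ~0.5 under the null", {
  r <- rankingOf(c(9, 8, 7, 3, 2, 1), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(rocAuc(r)$auc, 1.0)
  set.seed(42)
  n <- 4000
  r0 <- rankingOf(runif(n), sample(c(TRUE, FALSE), n, TRUE))
  expect_equal(rocAuc(r0)$auc, 0.5, tolerance = 0.03)
})

test_that("AUC equals exhaustive concordant-pair counting, ties credited 0.5", {
  for (seed in 1:6) {
    set.seed(seed)
    scores <- sample(1:8, 12, replace = TRUE)  # deliberate ties
    labels <- rep(c(TRUE, FALSE), each = 6)
    r <- rankingOf(scores, labels)
    expect_equal(rocAuc(r)$auc, pairAucOracle(scores, labels))
  }
  # the 3v3 hand-enumerable case
  r <- rankingOf(c(5, 4, 2, 6, 3, 1), c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE))
  expect_equal(rocAuc(r)$auc, pairAucOracle(c(5, 4, 2, 6, 3, 1),
                                            c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)))
})

test_that("the AUC standard error follows the Hanley-McNeil formula", {
  r <- rankingOf(c(9, 8, 7, 6, 3, 2, 1, 0), rep(c(TRUE, FALSE), each = 4))
  got <- rocAuc(r)
  A <- got$auc; na <- 4; nd <- 4
  Q1 <- A / (2 - A); Q2 <- 2 * A^2 / (1 + A)
  expect_equal(got$se,
               sqrt((A * (1 - A) + (na - 1) * (Q1 - A^2) +
                       (nd - 1) * (Q2 - A^2)) / (na * nd)))
  # one class absent is an error
  expect_error(rocAuc(rankingOf(1:3, c(TRUE, TRUE, TRUE))), "actives and decoys")
})

test_that("EFd is 100 for a perfect ranking and 0 for an inverted one", {
  perfect <- rankingOf(100:1, rep(c(TRUE, FALSE), c(10, 90)))
  for (f in c(0.1, 0.5, 1, 5)) expect_equal(efd(perfect, f), 100)
  worst <- rankingOf(100:1, rep(c(FALSE, TRUE), c(90, 10)))
  for (f in c(0.1, 0.5, 1, 5)) expect_equal(efd(worst, f), 0)
})

test_that("EFd matches direct enumeration on a crafted 10/1000 ranking", {
  # 4 actives before the 10th decoy (ceiling(1% of 1000) = 10)
  n_act <- 10; n_dec <- 1000
  lab <- rep(FALSE, n_act + n_dec)
  lab[c(1, 3, 5, 7)] <- TRUE            # 4 actives in the top 9 positions
  lab[(n_act + n_dec - 5):(n_act + n_dec)] <- TRUE  # remaining 6 at the bottom
  r <- rankingOf(seq(length(lab), 1), lab)
  # walk: the 10th decoy is met at position 14 (9 head positions hold 5
  # decoys); count actives seen up to there by direct enumeration
  df <- ranking(r)
  k <- 10
  stop_at <- which(cumsum(!df$is_active) >= k)[1]
  want <- 100 * sum(df$is_active[1:stop_at]) / n_act
  expect_equal(efd(r, 1.0), want)
  expect_equal(want, 40)  # 4 of 10 actives
})

test_that("BEDROC saturates at 1 for top-ranked actives and 0 at the bottom", {
  top <- rankingOf(1000:1, rep(c(TRUE, FALSE), c(10, 990)))
  expect_equal(bedroc(top, 20), 1, tolerance = 1e-3)
  bottom <- rankingOf(1000:1, rep(c(FALSE, TRUE), c(990, 10)))
  expect_equal(bedroc(bottom, 20), 0, tolerance = 1e-3)
})

test_that("BEDROC matches a direct evaluation of the Truchon-Bailey formula", {
  # 2 actives at ranks 1 and 50 of N = 100, alpha = 20
  lab <- rep(FALSE, 100); lab[c(1, 50)] <- TRUE
  r <- rankingOf(100:1, lab)
  alpha <- 20; N <- 100; n <- 2; Ra <- n / N
  s <- exp(-alpha * 1 / N) + exp(-alpha * 50 / N)
  rie <- s / (Ra * (1 - exp(-alpha)) / (exp(alpha / N) - 1))
  want <- rie * Ra * sinh(alpha / 2) /
    (cosh(alpha / 2) - cosh(alpha / 2 - alpha * Ra)) +
    1 / (1 - exp(alpha * (1 - Ra)))
  expect_equal(bedroc(r, 20), want, tolerance = 1e-12)
})

test_that("BEDROC approaches the AUC as alpha shrinks", {
  set.seed(17)
  for (rep in 1:4) {
    r <- rankingOf(runif(300), sample(rep(c(TRUE, FALSE), c(40, 260))))
    expect_equal(bedroc(r, 1e-3), rocAuc(r)$auc, tolerance = 1e-3)
  }
})

test_that("the semilog ROC curve is monotone, hits (1/n_decoys, 1) when perfect, and integrates to the AUC", {
  perfect <- rankingOf(50:1, rep(c(TRUE, FALSE), c(10, 40)))
  cv <- semilogRoc(perfect)
  expect_true(all(diff(cv$fpr) >= 0) && all(diff(cv$tpr) >= 0))
  expect_true(any(abs(cv$fpr_log - 1 / 40) < 1e-12 & cv$tpr == 1))
  expect_equal(aucFromCurve(cv), 1.0, tolerance = 1e-9)
  set.seed(3)
  r <- rankingOf(sample(1:10, 40, TRUE), sample(c(TRUE, FALSE), 40, TRUE))
  expect_equal(aucFromCurve(semilogRoc(r)), rocAuc(r)$auc, tolerance = 1e-9)
})

test_that("all metrics are invariant under strictly monotone score transforms", {
  set.seed(23)
  scores <- runif(200); labels <- sample(rep(c(TRUE, FALSE), c(30, 170)))
  r1 <- rankingOf(scores, labels)
  r2 <- rankingOf(exp(3 * scores) + 5, labels)
  expect_equal(rocAuc(r1)$auc, rocAuc(r2)$auc)
  expect_equal(efd(r1, 1), efd(r2, 1))
  expect_equal(bedroc(r1), bedroc(r2))
})

test_that("tied scores never flatter the enrichment (actives ranked last)", {
  # 1 active tied with 9 decoys at the top score
  r <- rankingOf(rep(1, 10), c(TRUE, rep(FALSE, 9)))
  df <- ranking(r)
  expect_false(df$is_active[1])       # a decoy leads
  expect_true(df$is_active[10])       # the active is last in the tie
})
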