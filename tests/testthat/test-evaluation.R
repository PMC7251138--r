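# AUC examples verified against brute-force positive/negative pair
# counting (aucBrute in helper-fixtures.R): positives {0.9, 0.4} vs
# negatives {0.8, 0.3, 0.1} win 5 of 6 pairs -> AUC = 5/6.

fiveMirnaMDN <- function(w) {
  makeMDN(data.frame(disease = "d1", mirna = paste0("m", 1:5), weight = w))
}
truth12 <- makeTruth(list(d1 = c("m1", "m2")))

test_that("AUC matches the hand-counted 5/6 example and the two limits", {
  r <- computeROC(fiveMirnaMDN(c(0.9, 0.4, 0.8, 0.3, 0.1)), truth12, "d1")
  expect_equal(r$auc, 5 / 6, tolerance = 1e-12)
  expect_equal(r$n_pos, 2); expect_equal(r$n_neg, 3)
  expect_equal(r$roc_points[1, ], data.frame(fpr = 0, tpr = 0),
               ignore_attr = TRUE)
  expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$roc_points$fpr) >= 0))
  expect_true(all(diff(r$roc_points$tpr) >= 0))

  perfect <- computeROC(fiveMirnaMDN(c(0.9, 0.8, 0.3, 0.2, 0.1)),
                        truth12, "d1")
  expect_equal(perfect$auc, 1)
  ties <- computeROC(fiveMirnaMDN(rep(0.5, 5)), truth12, "d1")
  expect_equal(ties$auc, 0.5)
})

test_that("AUC errors without positives or negatives", {
  expect_error(computeROC(fiveMirnaMDN(1:5 / 10),
                          makeTruth(list(d1 = "zzz")), "d1"))
  expect_error(computeROC(fiveMirnaMDN(1:5 / 10),
                          makeTruth(list(d1 = paste0("m", 1:5))), "d1"),
               "no negatives")
  expect_error(computeROC(fiveMirnaMDN(1:5 / 10), truth12, "d9"),
               "not in")
})

test_that("trapezoid AUC equals brute-force pair counting, including ties", {
  set.seed(42)
  for (i in 1:25) {
    n <- sample(6:40, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # many ties
    labels <- c(1, 0, rbinom(n - 2, 1, 0.4))                   # both classes
    mdn <- makeMDN(data.frame(disease = "d1",
                              mirna = sprintf("m%02d", 1:n),
                              weight = scores))
    tr <- makeTruth(list(d1 = sprintf("m%02d", which(labels == 1))))
    expect_equal(computeROC(mdn, tr, "d1")$auc, aucBrute(scores, labels),
                 tolerance = 1e-12)
  }
})

test_that("reversing the ranking complements the AUC", {
  set.seed(7)
  scores <- runif(30)
  labels <- c(1, 0, rbinom(28, 1, 0.3))
  mk <- function(w) makeMDN(data.frame(disease = "d1",
                                       mirna = sprintf("m%02d", 1:30),
                                       weight = w))
  tr <- makeTruth(list(d1 = sprintf("m%02d", which(labels == 1))))
  a1 <- computeROC(mk(scores), tr, "d1")$auc
  a2 <- computeROC(mk(max(scores) - scores), tr, "d1")$auc
  expect_equal(a1 + a2, 1, tolerance = 1e-12)
})

test_that("DeLong: self-comparison is null, separation vs anti-separation is significant", {
  w1 <- c(0.9, 0.8, 0.7, 0.65, 0.6, 0.3, 0.25, 0.2, 0.15, 0.1)
  mdn1 <- makeMDN(data.frame(disease = "d1", mirna = sprintf("m%02d", 1:10),
                             weight = w1))
  mdn2 <- makeMDN(data.frame(disease = "d1", mirna = sprintf("m%02d", 1:10),
                             weight = rev(w1)))
  tr <- makeTruth(list(d1 = sprintf("m%02d", 1:5)))
  r1 <- computeROC(mdn1, tr, "d1")
  r2 <- computeROC(mdn2, tr, "d1")
  self <- delongTest(r1, r1)
  expect_equal(self$z, 0); expect_equal(self$p_value, 1)
  opp <- delongTest(r1, r2)
  expect_lt(opp$p_value, 0.05)
  expect_error(delongTest(r1, computeROC(mdn1, makeTruth(
    list(d1 = sprintf("m%02d", 1:4))), "d1")), "instance sets")
})

test_that("DeLong p-values are roughly uniform under the null", {
  set.seed(11)
  n <- 60
  labels <- rep(c(1, 0), each = n / 2)
  mir <- sprintf("m%02d", 1:n)
  tr <- makeTruth(list(d1 = mir[labels == 1]))
  ps <- replicate(200, {
    s <- runif(n)
    r1 <- computeROC(makeMDN(data.frame(disease = "d1", mirna = mir,
                                        weight = s)), tr, "d1")
    r2 <- computeROC(makeMDN(data.frame(disease = "d1", mirna = mir,
                                        weight = sample(s))), tr, "d1")
    delongTest(r1, r2)$p_value
  })
  # under H0 about 95% of p-values exceed 0.05
  expect_gt(mean(ps > 0.05), 0.88)
  expect_lt(mean(ps > 0.05), 1)
})

test_that("edge-weight shuffling preserves per-disease weight multisets", {
  mdn <- makeMDN(data.frame(
    disease = rep(c("d1", "d2"), each = 4),
    mirna = rep(paste0("m", 1:4), 2),
    weight = c(1, 2, 3, 4, 10, 20, 30, 40) / 100))
  sh <- shuffleNull(mdn, "edge_weight", seed = 5)
  e0 <- mdnEdges(mdn); e1 <- mdnEdges(sh)
  for (d in c("d1", "d2"))
    expect_setequal(e1$weight[e1$disease == d], e0$weight[e0$disease == d])
  expect_identical(e1$mirna, e0$mirna)
})

test_that("node-label shuffling is deterministic and preserves structure", {
  mdn <- makeMDN(data.frame(
    disease = rep(c("d1", "d2", "d3"), each = 3),
    mirna = rep(paste0("m", 1:3), 3),
    weight = (1:9) / 10))
  s1 <- shuffleNull(mdn, "node_label", seed = 99)
  s2 <- shuffleNull(mdn, "node_label", seed = 99)
  expect_identical(mdnEdges(s1), mdnEdges(s2))
  expect_setequal(mdnEdges(s1)$weight, mdnEdges(mdn)$weight)
  # per-node edge counts (degree sequence) survive the relabeling
  expect_setequal(as.integer(table(mdnEdges(s1)$disease)),
                  as.integer(table(mdnEdges(mdn)$disease)))
  expect_setequal(as.integer(table(mdnEdges(s1)$mirna)),
                  as.integer(table(mdnEdges(mdn)$mirna)))
  expect_error(shuffleNull(mdn, "banana", seed = 1))
})

test_that("fold-change correlation recovers monotone relations and the hand-ranked 0.8 case", {
  fc <- data.frame(disease = "d1", mirna = paste0("m", 1:5),
                   fold_change = c(1, 2, 3, 4, 5))
  mk <- function(w) makeMDN(data.frame(disease = "d1",
                                       mirna = paste0("m", 1:5), weight = w))
  tr <- function(f) makeTruth(list(d1 = paste0("m", 1:5)),
                              fold_change = f)
  up <- suppressWarnings(
    foldchangeCorrelation(mk(c(1, 2, 3, 4, 5) / 10), tr(fc), "d1"))
  expect_equal(up$spearman_rho, 1)
  expect_gt(up$slope, 0)
  down <- suppressWarnings(
    foldchangeCorrelation(mk(c(5, 4, 3, 2, 1) / 10), tr(fc), "d1"))
  expect_equal(down$spearman_rho, -1)
  # ranks x = 1:5 vs y = (1,3,2,5,4): sum d^2 = 4, rho = 1 - 24/120 = 0.8
  mixed <- foldchangeCorrelation(mk(c(1, 3, 2, 5, 4) / 10), tr(fc), "d1")
  expect_equal(mixed$spearman_rho, 0.8, tolerance = 1e-12)
  expect_equal(sum(mixed$bins$n), 5)
})

test_that("fold-change correlation rejects degenerate inputs and honors abs()", {
  fc3 <- data.frame(disease = "d1", mirna = paste0("m", 1:2),
                    fold_change = c(1, 2))
  mdn <- makeMDN(data.frame(disease = "d1", mirna = paste0("m", 1:5),
                            weight = (1:5) / 10))
  expect_error(foldchangeCorrelation(
    mdn, makeTruth(list(d1 = paste0("m", 1:2)), fc3), "d1"),
    "fewer than 3")
  const <- data.frame(disease = "d1", mirna = paste0("m", 1:4),
                      fold_change = rep(2, 4))
  expect_error(foldchangeCorrelation(
    mdn, makeTruth(list(d1 = paste0("m", 1:4)), const), "d1"),
    "constant")
  neg <- data.frame(disease = "d1", mirna = paste0("m", 1:5),
                    fold_change = c(-5, -4, 3, 4, 5))
  r_abs <- foldchangeCorrelation(mdn, makeTruth(list(), neg), "d1",
                                 abs_foldchange = TRUE)
  r_raw <- foldchangeCorrelation(mdn, makeTruth(list(), neg), "d1")
  expect_false(isTRUE(all.equal(r_abs$spearman_rho, r_raw$spearman_rho)))
})
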