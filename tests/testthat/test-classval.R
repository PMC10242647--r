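test_that("wilson_ci matches the closed form and its boundary behavior", {
  # spec's worked case
  ci <- wilson_ci(0, 10)
  expect_equal(unname(ci[1]), 0)
  expect_equal(unname(ci[2]), 0.2775328, tolerance = 1e-6)
  expect_equal(unname(wilson_ci(10, 10)[2]), 1)
  set.seed(2)
  for (i in 1:25) {
    n <- sample(1:100, 1); k <- sample(0:n, 1)
    got <- wilson_ci(k, n)
    ref <- oracle_wilson(k, n)
    expect_equal(unname(got), ref, tolerance = 1e-12)
    expect_true(got[1] - 1e-12 <= k / n && k / n <= got[2] + 1e-12)
  }
  expect_error(wilson_ci(1, 0), "n")
  expect_error(wilson_ci(5, 3), "k")
})

test_that("ROC-integrated AUC equals the pairwise-count oracle with ties", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(4:12, 1)
    scores <- sample(c(0, 0.5, 1, 2), n, replace = TRUE)
    labs <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labs)) < 2) labs[1:2] <- c(TRUE, FALSE)
    roc <- roc_points(scores, labs)
    expect_true(all(diff(roc$fpr) >= 0) && all(diff(roc$tpr) >= 0))
    expect_equal(c(roc$fpr[1], roc$tpr[1]), c(0, 0))
    expect_equal(c(roc$fpr[nrow(roc)], roc$tpr[nrow(roc)]), c(1, 1))
    oracle <- oracle_auc_paircount(scores, labs)
    expect_equal(auc_mann_whitney(scores, labs), oracle, tolerance = 1e-12)
    expect_equal(hfsig:::trapezoid_auc(roc$fpr, roc$tpr), oracle,
                 tolerance = 1e-12)
  }
})

test_that("centroid model and prediction score behave algebraically", {
  co <- toy_bulk(n_per_class = 4)
  feats <- rownames(co$matrix)
  model <- fit_centroid(co, feats)
  X <- unclass(co$matrix)
  expect_equal(model$positive, rowMeans(X[, 1:4]))
  expect_equal(model$negative, rowMeans(X[, 5:8]))
  # duplicated training samples leave the model unchanged
  dup_m <- unclass(co$matrix)[, rep(1:8, 2)]
  colnames(dup_m) <- sprintf("d%02d", 1:16)
  md <- co$metadata[rep(1:8, 2), ]; md$id <- colnames(dup_m)
  co2 <- cohort(expr_matrix(dup_m, "lognorm", validate = FALSE), md)
  expect_equal(fit_centroid(co2, feats)$positive, model$positive)
  # score at the positive centroid equals the centroid distance
  expect_equal(predict_score(model, model$positive),
               sqrt(sum((model$positive - model$negative)^2)))
  # equidistant point scores zero
  expect_equal(predict_score(model, (model$positive + model$negative) / 2), 0)
  # label swap negates scores
  co_sw <- co
  co_sw$metadata$class_label <- rev(co$metadata$class_label)
  m_sw <- fit_centroid(co_sw, feats)
  x <- X[, 1]
  expect_equal(predict_score(m_sw, x), -predict_score(model, x))
  # single feature: score reduces to the signed distance along that gene
  m1 <- fit_centroid(co, "gA")
  expect_equal(predict_score(m1, c(gA = 3)),
               unname(abs(3 - m1$negative) - abs(3 - m1$positive)))
  expect_error(fit_centroid(co, c("gA", "nope")), "nope")
  expect_error(predict_score(model, c(gA = 1)), "features")
  expect_error(predict_score(model, stats::setNames(rep(NA_real_, 4), feats)),
               "non-finite")
})

test_that("splits are stratified and scores match an independent centroid oracle", {
  labels <- rep(c("positive", "negative"), c(11, 7))
  splits <- hfsig:::draw_splits(labels, 25L, 2 / 3, seed = 5)
  for (sp in splits) {
    expect_identical(sort(c(sp$train, sp$test)), seq_along(labels))
    expect_identical(sum(labels[sp$train] == "positive"), 7L)  # round(2/3*11)
    expect_identical(sum(labels[sp$train] == "negative"), 5L)  # round(2/3*7)
  }
  co <- toy_bulk(n_per_class = 6, seed = 3)
  sp <- hfsig:::draw_splits(co$metadata$class_label, 1L, 2 / 3, seed = 9)[[1]]
  occ <- hfsig:::mrv_pool_scores(co, rownames(co$matrix), list(sp), "euclidean")
  for (r in seq_len(nrow(occ)))
    expect_equal(occ$score[r],
                 oracle_centroid_score(unclass(co$matrix), sp$train,
                                       co$metadata$class_label,
                                       occ$index[r], rownames(co$matrix)))
})

test_that("multiple random validation: separable, null, and deterministic", {
  co <- toy_bulk(n_per_class = 8, seed = 11)   # gA separates perfectly
  vr <- multiple_random_validation(co, "gA", n_splits = 40L, seed = 2L)
  expect_equal(vr$auc, 1.0)
  expect_equal(vr$sens, 1.0)
  expect_equal(vr$spec, 1.0)
  # pooled AUC equals the pairwise-count oracle on the pooled scores
  expect_equal(vr$auc, oracle_auc_paircount(vr$scores$score,
                                            vr$scores$label == "positive"))
  # determinism
  vr2 <- multiple_random_validation(co, "gA", n_splits = 40L, seed = 2L)
  expect_identical(vr, vr2)
  # label swap: refitting with swapped labels negates every pooled score, and
  # the AUC of the *fixed* scores against flipped labels is 1 - auc
  co_sw <- co
  co_sw$metadata$class_label <- ifelse(co$metadata$class_label == "positive",
                                       "negative", "positive")
  vr_sw <- multiple_random_validation(co_sw, "gA", n_splits = 40L, seed = 2L)
  expect_equal(vr_sw$scores$score, -vr$scores$score)
  expect_equal(auc_mann_whitney(vr$scores$score, vr$scores$label == "negative"),
               1 - vr$auc)
  # null features: mean AUC across seeds stays near 1/2
  aucs <- vapply(1:20, function(s)
    multiple_random_validation(toy_bulk(8, seed = 100 + s), c("gB", "gC", "gD"),
                               n_splits = 20L, seed = s)$auc, numeric(1))
  expect_lt(abs(mean(aucs) - 0.5), 0.08)
})

test_that("evaluate_gene_set restricts to measured members and records loss", {
  co <- toy_bulk(n_per_class = 5, seed = 13)
  vr <- evaluate_gene_set(co, c("gA", "gB", "ghost"), n_splits = 10L, seed = 1L)
  expect_identical(attr(vr, "features_dropped"), "ghost")
  expect_setequal_chr(vr$features, c("gA", "gB"))
  expect_error(evaluate_gene_set(co, c("no1", "no2")), "no set member")
  expect_identical(evaluate_gene_set(co, c("gA", "gB", "ghost"), 10L, seed = 1L),
                   vr)
})

test_that("roc_p is uniform under the feature-null at one split", {
  ## at n_splits = 1 held-out scores are independent of held-out labels under
  ## the null, so the Welch p-value is calibrated; repeated overlapping splits
  ## induce same-class score correlation and are anti-conservative by
  ## construction of the framework (see the methods vignette)
  ps <- vapply(1:50, function(s) {
    spec <- small_spec(seed = 900 + s, panel_effect = 0, n_genes = 300L,
                       n_bulk_samples_per_class = 20L)
    bk <- simulate_bulk_cohort(spec)
    evaluate_gene_set(bk$cohort, bk$truth$panel, n_splits = 1L,
                      seed = derive_seed(s, 3))$roc_p
  }, numeric(1))
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})
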