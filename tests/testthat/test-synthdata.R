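test_that("spec validation names the offending field", {
  expect_error(synthetic_spec(panel_size = 0), "panel_size")
  expect_error(synthetic_spec(panel_size = 5000), "panel_size")
  expect_error(synthetic_spec(n_markers_per_cluster = 500,
                              n_genes = 400), "n_markers_per_cluster")
  expect_error(synthetic_spec(marker_log2_shift = NA), "marker_log2_shift")
  expect_error(synthetic_spec(baseline_params = list(bogus = 1)), "bogus")
})

test_that("identical spec + seed give bit-identical cohorts, new seeds differ", {
  spec <- small_spec(seed = 4)
  a <- simulate_cell_cohort(spec); b <- simulate_cell_cohort(spec)
  expect_identical(digest::digest(unclass(a$cohort$matrix)),
                   digest::digest(unclass(b$cohort$matrix)))
  expect_identical(a$cohort$metadata, b$cohort$metadata)
  ba <- simulate_bulk_cohort(spec, 1); bb <- simulate_bulk_cohort(spec, 1)
  expect_identical(unclass(ba$cohort$matrix), unclass(bb$cohort$matrix))
  expect_false(identical(unclass(simulate_bulk_cohort(spec, 2)$cohort$matrix),
                         unclass(ba$cohort$matrix)))
  other <- simulate_cell_cohort(small_spec(seed = 5))
  expect_false(identical(unclass(a$cohort$matrix),
                         unclass(other$cohort$matrix)))
  ca <- simulate_geneset_collection(spec, a$truth)
  cb <- simulate_geneset_collection(spec, b$truth)
  expect_identical(ca, cb)
})

test_that("ground truth ids exist in the generated matrices", {
  spec <- small_spec(seed = 2)
  cc <- simulate_cell_cohort(spec)
  bk <- simulate_bulk_cohort(spec)
  genes <- rownames(cc$cohort$matrix)
  expect_true(all(unlist(cc$truth$marker_map) %in% genes))
  expect_true(all(cc$truth$panel %in% rownames(bk$cohort$matrix)))
  expect_identical(cc$truth$panel,
                   intersect(cc$truth$marker_map[[1L]], cc$truth$panel))
})

test_that("zero marker shift gives ~zero empirical log2 marker shift", {
  spec <- small_spec(seed = 3, marker_log2_shift = 0, n_cells_per_cluster = 80L)
  cc <- simulate_cell_cohort(spec)
  X <- log2(unclass(cc$cohort$matrix))
  shifts <- vapply(names(cc$truth$marker_map), function(cl) {
    inside <- cc$cohort$metadata$subcluster == cl
    mk <- cc$truth$marker_map[[cl]]
    mean(rowMeans(X[mk, inside]) - rowMeans(X[mk, !inside]))
  }, numeric(1))
  expect_lt(max(abs(shifts)), 0.15)
})

test_that("planted markers carry the requested expected log2 shift", {
  for (model in c("lognormal", "negative_binomial")) {
    spec <- small_spec(seed = 8, marker_log2_shift = 2,
                       n_cells_per_cluster = 100L, baseline_model = model)
    cc <- simulate_cell_cohort(spec)
    X <- unclass(cc$cohort$matrix)
    if (model == "negative_binomial")
      expect_true(all(X == floor(X)) && all(X >= 0))
    cl <- names(cc$truth$marker_map)[1L]
    inside <- cc$cohort$metadata$subcluster == cl
    mk <- cc$truth$marker_map[[cl]]
    ## shift of mean expression on the raw scale, in log2
    obs <- mean(log2(rowMeans(X[mk, inside]) / rowMeans(X[mk, !inside])))
    expect_lt(abs(obs - 2), 0.5)
  }
})

test_that("planted markers are recovered by marker detection (3 seeds)", {
  for (s in 1:3) {
    spec <- small_spec(seed = s, marker_log2_shift = 2,
                       n_cells_per_cluster = 200L)
    cc <- simulate_cell_cohort(spec)
    logn <- lognormalize(cc$cohort$matrix)
    mk <- find_cluster_markers(logn, cc$cohort$metadata$subcluster)
    for (cl in names(cc$truth$marker_map)) {
      truth <- cc$truth$marker_map[[cl]]
      found <- mk[[cl]]$gene
      expect_gte(mean(truth %in% found), 0.9)
      expect_lte(mean(!(found %in% truth)), 0.1)
    }
  }
})

test_that("bulk panel genes behave as planted: null effect and strong effect", {
  ## panel_effect = 0: per-gene two-sample t statistics on panel genes are null
  tstats <- unlist(lapply(1:20, function(s) {
    spec <- small_spec(seed = 100 + s, panel_effect = 0,
                       n_bulk_samples_per_class = 15L)
    bk <- simulate_bulk_cohort(spec)
    X <- unclass(bk$cohort$matrix)
    pos <- bk$cohort$metadata$class_label == "positive"
    vapply(bk$truth$panel, function(g)
      stats::t.test(X[g, pos], X[g, !pos])$statistic, numeric(1))
  }))
  expect_lt(abs(mean(tstats)), 0.5)
  ## panel_effect = 3, 40 vs 40: single-gene AUC > 0.9 in expectation
  spec <- small_spec(seed = 7, panel_effect = 3, n_bulk_samples_per_class = 40L)
  bk <- simulate_bulk_cohort(spec)
  pos <- bk$cohort$metadata$class_label == "positive"
  aucs <- vapply(bk$truth$panel, function(g)
    auc_mann_whitney(unclass(bk$cohort$matrix)[g, ], pos), numeric(1))
  expect_gt(mean(aucs), 0.9)
})

test_that("increasing panel_effect weakly increases expected panel AUC", {
  mean_auc <- vapply(c(0, 1, 2), function(eff) {
    mean(vapply(1:3, function(s) {
      spec <- small_spec(seed = 200 + s, panel_effect = eff)
      bk <- simulate_bulk_cohort(spec)
      pos <- bk$cohort$metadata$class_label == "positive"
      mean(vapply(bk$truth$panel, function(g)
        auc_mann_whitney(unclass(bk$cohort$matrix)[g, ], pos), numeric(1)))
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean_auc) > -0.02))
})

test_that("gene-set planting: boundaries, membership and enrichment", {
  spec <- small_spec(seed = 5, set_size = 1L)
  truth <- ground_truth(spec)
  coll <- simulate_geneset_collection(spec, truth)
  expect_true(all(lengths(coll$sets) == 1L))

  spec <- small_spec(seed = 5, panel_size = 13L, n_markers_per_cluster = 13L)
  cc <- simulate_cell_cohort(spec)
  coll <- simulate_geneset_collection(spec, cc$truth)
  planted <- unique(c(cc$truth$panel, unlist(cc$truth$marker_map)))
  for (nm in cc$truth$true_sets)
    expect_gte(mean(coll$sets[[nm]] %in% planted), 0.8)
  expect_true(all(unlist(coll$sets) %in% rownames(cc$cohort$matrix)))
  ## a true set built on the 13-gene panel is found by ORA on the panel query
  res <- enrich_overrepresentation(cc$truth$panel, coll,
                                   rownames(cc$cohort$matrix))
  expect_true("TRUE_SET_01" %in% res$set)
  expect_true(all(res$q[res$set == "TRUE_SET_01"] < 0.05))
  expect_error(simulate_geneset_collection(small_spec(set_size = 290L),
                                           truth), "set_size")
})

test_that("null-only collections give valid (sub-uniform) enrichment p-values", {
  ## hypergeometric p on planted-gene queries against null sets: P(p <= a) <= a
  ## (+ Monte-Carlo slack).  A literal KS-vs-U(0,1) check is not applicable:
  ## the null p-values are heavily discrete (most draws have zero overlap).
  ps <- unlist(lapply(1:50, function(s) {
    spec <- small_spec(seed = 300 + s, n_true_sets = 0L, n_null_sets = 6L)
    truth <- ground_truth(spec)
    coll <- simulate_geneset_collection(spec, truth)
    res <- enrich_overrepresentation(truth$panel, coll,
                                     sprintf("gene_%05d", 1:300), q_max = 1.1,
                                     top_k = Inf)
    res$p
  }))
  for (a in c(0.01, 0.05, 0.1, 0.25))
    expect_lte(mean(ps <= a), a + 3 * sqrt(a * (1 - a) / length(ps)) + 0.01)
})

test_that("with all effects at zero, DE controls false positives at BH level", {
  fdp <- vapply(1:20, function(s) {
    spec <- small_spec(seed = 400 + s, marker_log2_shift = 0,
                       n_cells_per_cluster = 40L)
    cc <- simulate_cell_cohort(spec)
    logn <- lognormalize(cc$cohort$matrix)
    meta <- cc$cohort$metadata
    de <- de_two_group(logn, which(meta$condition == "disease"),
                       which(meta$condition == "normal"))
    sum(de$p_adj < 0.05) / max(1L, nrow(de))
  }, numeric(1))
  expect_lte(mean(fdp), 1.5 * 0.05)
})
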