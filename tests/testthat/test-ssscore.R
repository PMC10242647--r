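strip_scores <- function(x) {
  x <- unclass(x)
  attributes(x) <- attributes(x)[c("dim", "dimnames")]
  x
}

rand_expr <- function(g, s, seed, layer = "lognorm") {
  set.seed(seed)
  X <- matrix(abs(rnorm(g * s)), g, s,
              dimnames = list(sprintf("g%03d", 1:g), sprintf("s%03d", 1:s)))
  expr_matrix(X, layer, validate = FALSE)
}

test_that("single-gene-set scores follow the gene's within-sample rank exactly", {
  for (kc in c("gaussian", "ecdf")) {
    m <- rand_expr(15, 8, seed = 31)
    sc <- gsva_score(m, geneset_collection(list(one = "g007"), "GOBP"),
                     kcdf_mode = kc)
    ## closed form for a one-gene set: ES = 1 - 2 (pos - 1) / (g - 1), where
    ## pos is the gene's position in the sample's descending kcdf ranking
    kfun <- switch(kc, gaussian = hfsig:::kcdf_gaussian, ecdf = hfsig:::kcdf_ecdf)
    Fm <- t(apply(unclass(m), 1L, kfun))
    pos <- apply(-Fm, 2L, rank, ties.method = "first")["g007", ]
    expect_equal(unname(as.numeric(sc)), unname(1 - 2 * (pos - 1) / (15 - 1)))
  }
  ## the score ordering across samples follows the gene's within-sample rank
  ## position (the exact reading of the rank-preservation property; the
  ## cross-sample expression ordering can differ when other genes reshuffle
  ## within-sample positions — see the methods vignette)
  m <- rand_expr(12, 7, seed = 37)
  sc <- gsva_score(m, geneset_collection(list(one = "g005"), "GOBP"),
                   kcdf_mode = "ecdf")
  Fm <- t(apply(unclass(m), 1L, hfsig:::kcdf_ecdf))
  pos <- apply(-Fm, 2L, rank, ties.method = "first")["g005", ]
  expect_identical(order(as.numeric(sc)), order(-pos))
})

test_that("scores are invariant to gene order and equivariant to sample order", {
  m <- rand_expr(30, 10, seed = 5)
  coll <- geneset_collection(list(A = c("g003", "g010", "g021"),
                                  B = sprintf("g%03d", 22:28)), "GOBP")
  sc <- gsva_score(m, coll)
  set.seed(1); pg <- sample(nrow(m)); ps <- sample(ncol(m))
  sc_g <- gsva_score(m[pg, ], coll)
  expect_equal(strip_scores(sc_g), strip_scores(sc))
  sc_s <- gsva_score(m[, ps], coll)
  expect_equal(strip_scores(sc_s), strip_scores(sc)[, ps])
})

test_that("a sample-specific constant shift leaves that sample's scores alone", {
  ## exact-ECDF mode: a shift small enough not to reorder any gene's
  ## cross-sample ranks changes nothing at all
  m <- rand_expr(25, 9, seed = 13)
  gaps <- apply(unclass(m), 1L, function(v) min(diff(sort(v))))
  eps <- min(gaps) / 3
  m2 <- unclass(m); m2[, 4] <- m2[, 4] + eps
  coll <- geneset_collection(list(S = sprintf("g%03d", 3:9)), "GOBP")
  expect_equal(unclass(gsva_score(expr_matrix(m2, "lognorm", validate = FALSE),
                                  coll, kcdf_mode = "ecdf")),
               unclass(gsva_score(m, coll, kcdf_mode = "ecdf")))
})

test_that("a set of one sample's top genes maximizes that sample's score", {
  m0 <- rand_expr(40, 6, seed = 17)
  X <- unclass(m0)
  X[1:6, 3] <- X[1:6, 3] + 50    # sample s003 dominates genes g001-g006
  m <- expr_matrix(X, "lognorm", validate = FALSE)
  for (st in c("max_diff", "two_sided_max")) {
    sc <- gsva_score(m, geneset_collection(list(top = sprintf("g%03d", 1:6)),
                                           "GOBP"), stat_mode = st)
    expect_identical(which.max(as.numeric(sc)), 3L)
    if (st == "two_sided_max") expect_true(all(abs(sc) <= 1))
  }
})

test_that("coordinately up-regulated sets separate the classes (3 seeds)", {
  for (s in 1:3) {
    spec <- small_spec(seed = 800 + s, panel_effect = 2,
                       n_bulk_samples_per_class = 25L)
    bk <- simulate_bulk_cohort(spec)
    sc <- gsva_score(bk$cohort$matrix,
                     geneset_collection(list(panel = bk$truth$panel), "GOBP"))
    pos <- bk$cohort$metadata$class_label == "positive"
    expect_gte(auc_mann_whitney(as.numeric(sc), pos), 0.9)
  }
})

test_that("degenerate inputs are handled as specified", {
  m <- rand_expr(10, 2, seed = 1)
  coll <- geneset_collection(list(S = c("g001", "g002")), "GOBP")
  expect_error(gsva_score(m, coll), ">= 3 samples")
  m2 <- rand_expr(10, 5, seed = 2)
  expect_warning(
    sc <- gsva_score(m2, geneset_collection(list(S = c("g001", "g002"),
                                                 none = c("zz1", "zz2")),
                                            "GOBP")),
    "skipped")
  expect_identical(rownames(sc), "S")
})

test_that("score_group_compare: symmetry, nulls and planted separation", {
  m <- rand_expr(30, 12, seed = 23)
  coll <- geneset_collection(list(A = sprintf("g%03d", 1:6),
                                  B = sprintf("g%03d", 10:16)), "GOBP")
  sc <- gsva_score(m, coll)
  # two-sided symmetry under label swap
  a <- score_group_compare(sc, 1:6, 7:12)
  b <- score_group_compare(sc, 7:12, 1:6)
  expect_equal(a$p, b$p)
  # identical groups: p = 1 (duplicate the score columns)
  sc2 <- cbind(unclass(sc), unclass(sc))
  colnames(sc2) <- sprintf("d%02d", seq_len(ncol(sc2)))
  expect_true(all(score_group_compare(sc2, 1:12, 13:24)$p == 1))
  # constant scores: warning and p = 1
  scc <- unclass(sc); scc[1, ] <- 0.5
  expect_warning(r <- score_group_compare(scc, 1:6, 7:12), "constant")
  expect_identical(r$p[1L], 1)
  # planted separation reaches q < 0.05
  spec <- small_spec(seed = 27, panel_effect = 2, n_bulk_samples_per_class = 25L)
  bk <- simulate_bulk_cohort(spec)
  scp <- gsva_score(bk$cohort$matrix,
                    geneset_collection(list(panel = bk$truth$panel,
                                            null = sprintf("gene_%05d", 250:260)),
                                       "GOBP"))
  pos <- which(bk$cohort$metadata$class_label == "positive")
  neg <- which(bk$cohort$metadata$class_label == "negative")
  cmp <- score_group_compare(scp, pos, neg)
  expect_lt(cmp$q[cmp$set == "panel"], 0.05)
})
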