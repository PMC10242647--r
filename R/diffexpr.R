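## Normalization, two-group DE and cluster marker detection.
## The DE engine is a two-sided Wilcoxon rank-sum test behind Seurat-style
## expression-fraction and log-fold-change gates: exact enumeration (midranks)
## when both groups have <= 8 observations, normal approximation with
## mid-ranks, tie correction and continuity correction otherwise.

#' Differential-expression parameters
#'
#' @param min_pct minimum expression fraction (proportion of cells/samples
#'   with value > 0) required in at least one group. Default 0.1.
#' @param logfc_threshold minimum natural-log fold change (per `direction`).
#'   Default 0.25.
#' @param alpha BH-adjusted significance level. Default 0.05.
#' @param direction `"both"`, `"up"` (group 1 higher) or `"down"`.
#' @return a `de_params` list.
#' @export
de_params <- function(min_pct = 0.1, logfc_threshold = 0.25, alpha = 0.05,
                      direction = c("both", "up", "down")) {
  direction <- match.arg(direction)
  if (!is_fraction(min_pct, open = FALSE)) stop_field("min_pct", "must be in [0,1]")
  if (!is.numeric(logfc_threshold) || logfc_threshold < 0)
    stop_field("logfc_threshold", "must be >= 0")
  if (!is_fraction(alpha)) stop_field("alpha", "must be in (0,1)")
  structure(list(min_pct = min_pct, logfc_threshold = logfc_threshold,
                 alpha = alpha, direction = direction), class = "de_params")
}

#' Library-size log-normalization (scale factor 10,000)
#'
#' Each value `v` in column `c` maps to `ln(1 + 10000 * v / colsum(c))`.
#'
#' @param m a counts-layer [expr_matrix()].
#' @param scale_factor library scale factor. Default 10000.
#' @return a lognorm-layer [expr_matrix()].
#' @export
lognormalize <- function(m, scale_factor = 1e4) {
  stopifnot(inherits(m, "expr_matrix"))
  if (em_layer(m) != "counts") stop_field("m", "lognormalize expects the counts layer")
  cs <- colSums(m)
  if (any(cs == 0))
    stop(sprintf("zero-total column(s): %s",
                 paste(colnames(m)[cs == 0], collapse = ", ")), call. = FALSE)
  out <- log1p(sweep(unclass(m), 2L, cs, "/") * scale_factor)
  expr_matrix(out, "lognorm", validate = FALSE)
}

## exact two-sided rank-sum p by enumeration of all C(n1+n2, n1) label
## assignments over the observed mid-ranks; `combs` may be precomputed
ranksum_exact_p <- function(x, y, combs = NULL) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)])
  if (is.null(combs)) combs <- utils::combn(n1 + n2, n1)
  ws <- colSums(matrix(r[combs], nrow = n1))
  min(1, 2 * min(mean(ws <= w_obs + 1e-9), mean(ws >= w_obs - 1e-9)))
}

## vectorized rank-sum p over the rows of X; group 1 = idx1, group 2 = idx2
ranksum_p_rows <- function(X, idx1, idx2, exact_max = 8L) {
  n1 <- length(idx1); n2 <- length(idx2); n <- n1 + n2
  sub <- X[, c(idx1, idx2), drop = FALSE]
  if (n1 <= exact_max && n2 <= exact_max) {
    combs <- utils::combn(n, n1)
    return(apply(sub, 1L, function(v)
      ranksum_exact_p(v[seq_len(n1)], v[n1 + seq_len(n2)], combs)))
  }
  R <- matrixStats::rowRanks(sub, ties.method = "average")
  W <- rowSums(R[, seq_len(n1), drop = FALSE])
  mu <- n1 * (n + 1) / 2
  tie_term <- apply(sub, 1L, function(v) { t <- tabulate(match(v, unique(v)))
                                           sum(t^3 - t) })
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  d <- W - mu
  z <- ifelse(sigma2 > 0, (d - sign(d) * 0.5) / sqrt(sigma2), 0)
  p <- 2 * stats::pnorm(-abs(z))
  p[sigma2 == 0] <- 1
  pmin(1, p)
}

#' Two-group differential expression (Wilcoxon rank-sum)
#'
#' For each gene passing the `min_pct` and `logfc_threshold` gates (per
#' `direction`), computes a two-sided rank-sum p-value; BH adjustment is over
#' tested genes only.  The result is sorted by decreasing |log_fc| (ties
#' broken lexicographically by gene id) — the ordering submitted to
#' enrichment.  `log_fc` is the natural-log fold change of `expm1`-means
#' (Seurat convention), so the default 0.25 threshold is on that scale.
#'
#' @param m a lognorm-layer [expr_matrix()].
#' @param group1,group2 column ids (or indices) of the two groups; `log_fc > 0`
#'   means higher in `group1`.
#' @param params a [de_params()].
#' @return data frame `gene`, `log_fc`, `pct_1`, `pct_2`, `p`, `p_adj`, with
#'   attribute `measured` = all gene ids in `m` (the enrichment universe).
#' @export
de_two_group <- function(m, group1, group2, params = de_params()) {
  stopifnot(inherits(m, "expr_matrix"), inherits(params, "de_params"))
  if (em_layer(m) != "lognorm") stop_field("m", "DE expects the lognorm layer")
  idx1 <- if (is.character(group1)) match(group1, colnames(m)) else as.integer(group1)
  idx2 <- if (is.character(group2)) match(group2, colnames(m)) else as.integer(group2)
  if (length(idx1) == 0L || length(idx2) == 0L)
    stop_field("groups", "both groups must be non-empty")
  if (anyNA(idx1) || anyNA(idx2)) stop_field("groups", "unknown column id(s)")
  X <- unclass(m)
  x1 <- X[, idx1, drop = FALSE]; x2 <- X[, idx2, drop = FALSE]
  log_fc <- log(rowMeans(expm1(x1)) + 1) - log(rowMeans(expm1(x2)) + 1)
  pct_1 <- rowMeans(x1 > 0); pct_2 <- rowMeans(x2 > 0)
  pass_pct <- pmax(pct_1, pct_2) >= params$min_pct
  pass_fc <- switch(params$direction,
                    up = log_fc >= params$logfc_threshold,
                    down = log_fc <= -params$logfc_threshold,
                    both = abs(log_fc) >= params$logfc_threshold)
  tested <- which(pass_pct & pass_fc)
  p <- rep(NA_real_, length(tested))
  if (length(tested))
    p <- ranksum_p_rows(X[tested, , drop = FALSE], idx1, idx2)
  out <- data.frame(gene = rownames(m)[tested],
                    log_fc = log_fc[tested], pct_1 = pct_1[tested],
                    pct_2 = pct_2[tested], p = p,
                    p_adj = stats::p.adjust(p, "BH"),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$log_fc), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "measured") <- rownames(m)
  out
}

#' One-vs-rest cluster marker detection
#'
#' Runs [de_two_group()] (direction `"up"`) for every cluster against all
#' other columns and keeps genes with `p_adj < alpha` as markers.  Singleton
#' clusters are skipped with a warning (empty result, attribute
#' `skipped = TRUE`).
#'
#' @param m a lognorm-layer [expr_matrix()].
#' @param clusters character/factor of cluster labels, one per column of `m`.
#' @param params a [de_params()]; `direction` is forced to `"up"`.
#' @return named list (one entry per cluster) of marker data frames.
#' @export
find_cluster_markers <- function(m, clusters, params = de_params()) {
  stopifnot(inherits(m, "expr_matrix"))
  clusters <- as.character(clusters)
  if (length(clusters) != ncol(m))
    stop_field("clusters", "must have one label per column")
  levs <- unique(clusters)
  if (length(levs) < 2L) stop_field("clusters", "need >= 2 clusters")
  params$direction <- "up"
  out <- stats::setNames(vector("list", length(levs)), levs)
  for (cl in levs) {
    in_cl <- which(clusters == cl)
    if (length(in_cl) < 2L) {
      warning(sprintf("cluster '%s' is a singleton; skipped", cl), call. = FALSE)
      res <- data.frame(gene = character(0), log_fc = numeric(0),
                        pct_1 = numeric(0), pct_2 = numeric(0),
                        p = numeric(0), p_adj = numeric(0),
                        stringsAsFactors = FALSE)
      attr(res, "measured") <- rownames(m)
      attr(res, "skipped") <- TRUE
      out[[cl]] <- res
      next
    }
    de <- de_two_group(m, in_cl, setdiff(seq_len(ncol(m)), in_cl), params)
    res <- de[!is.na(de$p_adj) & de$p_adj < params$alpha, , drop = FALSE]
    rownames(res) <- NULL
    attr(res, "measured") <- attr(de, "measured")
    out[[cl]] <- res
  }
  out
}

#' Top n genes by absolute log fold change
#'
#' Returns the first `min(n, nrow)` gene ids ordered by decreasing |log_fc|,
#' ties broken lexicographically by gene id (all genes if fewer than `n`).
#'
#' @param de a DE result data frame (from [de_two_group()]).
#' @param n maximum number of genes.
#' @return character vector of gene ids.
#' @export
top_n_by_abs_logfc <- function(de, n = 500L) {
  if (!is_count(n)) stop_field("n", "must be a positive integer")
  if (nrow(de) == 0L) return(character(0))
  ord <- order(-abs(de$log_fc), de$gene)
  de$gene[ord][seq_len(min(n, nrow(de)))]
}
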