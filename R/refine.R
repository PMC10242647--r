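## Cyclic leave-one-out, AUC-maximizing signature refinement.  Each cycle
## forms all n leave-one-out subsets of the current n-gene list, evaluates
## every subset with multiple random validation against one shared, pre-drawn
## split sequence (so AUC differences reflect gene content, not split noise),
## keeps the argmax-AUC subset, and recurses until no more than `stop_size`
## genes remain.  For the euclidean distance the evaluation is vectorized:
## per-gene squared-distance contributions are subtracted from the full-list
## totals, which is algebraically identical to refitting each subset.

#' Build the candidate gene pool from qualifying enriched sets
#'
#' Union of the member genes of all sets with `p_adj < alpha` (the `q` column
#' of an enrichment table), deduplicated and lexicographically ordered.
#'
#' @param enriched_sets an enrichment result data frame with columns `set`
#'   and `q` (e.g. from [enrich_overrepresentation()], or a screening table
#'   with `roc_fdr` renamed to `q`).
#' @param collection the [geneset_collection()] the sets come from.
#' @param alpha qualification threshold. Default 0.05.
#' @return character vector of pooled gene ids.
#' @export
build_candidate_pool <- function(enriched_sets, collection, alpha = 0.05) {
  stopifnot(inherits(collection, "geneset_collection"))
  qual <- enriched_sets$set[enriched_sets$q < alpha]
  if (length(qual) == 0L)
    stop(sprintf("no set qualifies at p.adjust < %g", alpha), call. = FALSE)
  pool <- sort(unique(unlist(collection$sets[qual], use.names = FALSE)))
  if (length(pool) == 0L) stop("empty gene pool", call. = FALSE)
  pool
}

## vectorized euclidean leave-one-out evaluation for one cycle:
## returns list(auc = per-subset AUC (names = left-out gene), full_auc)
loo_cycle_euclidean <- function(X, pool, labels, splits) {
  Xp <- X[pool, , drop = FALSE]
  n <- length(pool)
  N <- ncol(Xp)
  pos_lab <- labels == "positive"
  SUM <- matrix(0, N, n)     # per-sample score sums, one column per subset
  FSUM <- numeric(N)         # full-pool score sums
  CNT <- integer(N)          # held-out occurrence counts
  for (sp in splits) {
    tr <- sp$train; te <- sp$test
    cen_pos <- rowMeans(Xp[, tr[pos_lab[tr]], drop = FALSE])
    cen_neg <- rowMeans(Xp[, tr[!pos_lab[tr]], drop = FALSE])
    Dpos <- (Xp[, te, drop = FALSE] - cen_pos)^2   # n genes x t test samples
    Dneg <- (Xp[, te, drop = FALSE] - cen_neg)^2
    totpos <- colSums(Dpos); totneg <- colSums(Dneg)
    ## subset j leaves out gene j: d^2 = total - contribution of gene j
    Spos <- pmax(outer(totpos, rep(1, n)) - t(Dpos), 0)
    Sneg <- pmax(outer(totneg, rep(1, n)) - t(Dneg), 0)
    SUM[te, ] <- SUM[te, ] + (sqrt(Sneg) - sqrt(Spos))   # t x n
    FSUM[te] <- FSUM[te] + (sqrt(totneg) - sqrt(totpos))
    CNT[te] <- CNT[te] + 1L
  }
  keep <- CNT > 0L
  P <- SUM[keep, , drop = FALSE] / CNT[keep]       # per-sample mean scores
  y <- pos_lab[keep]
  n1 <- sum(y); n2 <- sum(!y)
  auc <- apply(P, 2L, function(s) {
    r <- rank(s); (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  })
  names(auc) <- pool
  list(auc = auc, full_auc = auc_mann_whitney(FSUM[keep] / CNT[keep], y))
}

## generic (any distance) leave-one-out evaluation via the standard path
loo_cycle_generic <- function(cohort_obj, pool, splits, distance,
                              eval_pool = pool) {
  auc <- vapply(eval_pool, function(g) {
    ps <- aggregate_per_sample(mrv_pool_scores(cohort_obj, setdiff(pool, g),
                                               splits, distance))
    auc_mann_whitney(ps$score, ps$label == "positive")
  }, numeric(1))
  names(auc) <- eval_pool
  full <- aggregate_per_sample(mrv_pool_scores(cohort_obj, pool, splits, distance))
  list(auc = auc,
       full_auc = auc_mann_whitney(full$score, full$label == "positive"))
}

#' Cyclic leave-one-out signature refinement
#'
#' @param pool candidate gene ids (all measured in the cohort); length must
#'   exceed `stop_size`.
#' @param cohort a two-class bulk [cohort()].
#' @param n_splits,train_fraction,distance validation settings (shared split
#'   sequence within each cycle; fresh splits per cycle from the seeded
#'   stream).
#' @param stop_size recurse while the current list is larger than this.
#'   Default 3 (at size 3 only three leave-one-out subsets remain).
#' @param seed master seed for the split streams.
#' @param selection_rule `"smallest_max"` (default: smallest size attaining
#'   the global maximum AUC) or `"largest_max"`.
#' @param subset_sample if finite, at most this many randomly chosen
#'   leave-one-out subsets are evaluated per cycle (seeded); default `Inf`
#'   evaluates all of them.
#' @return a `refinement_trace`: `cycles` (per-cycle candidate AUCs and the
#'   winning subset `genelist_maxAUC`), `auc_by_size` (size -> best AUC,
#'   including the initial pool), `selected_signature`,
#'   `selection_rule_applied`, `seed`.
#' @export
refine_signature <- function(pool, cohort, n_splits = 200L,
                             train_fraction = 2 / 3,
                             distance = c("euclidean", "correlation"),
                             stop_size = 3L, seed = 1L,
                             selection_rule = c("smallest_max", "largest_max"),
                             subset_sample = Inf) {
  distance <- match.arg(distance)
  selection_rule <- match.arg(selection_rule)
  stopifnot(inherits(cohort, "cohort"))
  pool <- sort(unique(as.character(pool)))
  if (!is_count(stop_size)) stop_field("stop_size", "must be a positive integer")
  if (length(pool) <= stop_size)
    stop_field("pool", sprintf("needs more than stop_size = %d genes", stop_size))
  missing <- setdiff(pool, rownames(cohort$matrix))
  if (length(missing))
    stop(sprintf("pool gene(s) not measured: %s", paste(missing, collapse = ", ")),
         call. = FALSE)
  labels <- cohort$metadata$class_label
  if (length(unique(labels)) != 2L) stop("cohort must be two-class", call. = FALSE)
  X <- unclass(cohort$matrix)

  current <- pool
  cycles <- list()
  genelist_by_size <- list()
  best_by_size <- numeric(0)
  cycle_i <- 0L
  while (length(current) > stop_size) {
    cycle_i <- cycle_i + 1L
    sp_seed <- derive_seed(seed, 500L + cycle_i)
    splits <- draw_splits(labels, n_splits, train_fraction, sp_seed)
    eval_pool <- current
    if (is.finite(subset_sample) && length(current) > subset_sample)
      eval_pool <- withr::with_seed(derive_seed(seed, 900L + cycle_i),
                                    sort(sample(current, subset_sample)))
    ev <- tryCatch(
      if (distance == "euclidean")
        loo_cycle_euclidean(X, current, labels, splits)
      else loo_cycle_generic(cohort, current, splits, distance, eval_pool),
      error = function(e) stop(sprintf("AUC evaluation failed in cycle %d (size %d): %s",
                                       cycle_i, length(current), conditionMessage(e)),
                               call. = FALSE))
    auc <- ev$auc[eval_pool]
    if (cycle_i == 1L) {  # record the initial pool's own AUC (same splits)
      best_by_size[as.character(length(current))] <- ev$full_auc
      genelist_by_size[[as.character(length(current))]] <- current
    }
    ## argmax; AUC ties break toward the lexicographically largest left-out gene
    mx <- max(auc)
    cand <- names(auc)[auc >= mx - 1e-12]
    left_out <- max(cand)
    winner <- setdiff(current, left_out)
    cycles[[cycle_i]] <- list(cycle_index = cycle_i,
                              input_size = length(current),
                              candidate_auc = auc,
                              left_out = left_out,
                              genelist_maxAUC = winner,
                              max_auc = unname(auc[left_out]))
    best_by_size[as.character(length(winner))] <- unname(auc[left_out])
    genelist_by_size[[as.character(length(winner))]] <- winner
    current <- winner
  }
  sizes <- as.integer(names(best_by_size))
  abs_tab <- data.frame(size = sizes, best_auc = unname(best_by_size))
  abs_tab <- abs_tab[order(-abs_tab$size), , drop = FALSE]
  rownames(abs_tab) <- NULL
  gmax <- max(abs_tab$best_auc)
  attain <- abs_tab$size[abs_tab$best_auc >= gmax - 1e-12]
  sel_size <- if (selection_rule == "smallest_max") min(attain) else max(attain)
  structure(list(cycles = cycles, auc_by_size = abs_tab,
                 genelist_by_size = genelist_by_size,
                 selected_signature = genelist_by_size[[as.character(sel_size)]],
                 selected_size = sel_size, max_auc = gmax,
                 selection_rule_applied = selection_rule,
                 n_splits = n_splits, train_fraction = train_fraction,
                 distance = distance, stop_size = as.integer(stop_size),
                 seed = as.integer(seed)),
            class = "refinement_trace")
}

#' @export
print.refinement_trace <- function(x, ...) {
  cat(sprintf("<refinement_trace> %d -> %d genes; best AUC %.3f at size %d (%s)\n",
              x$auc_by_size$size[1L], x$stop_size, x$max_auc, x$selected_size,
              x$selection_rule_applied))
  invisible(x)
}

#' Size-vs-AUC table (and optional bar plot) of a refinement trace
#'
#' @param trace a [refine_signature()] trace.
#' @param path optional TSV destination (`size`, `best_auc`, `selected`).
#' @param plot_file optional file for a bar plot (device chosen by
#'   extension: `.pdf` or `.png`) with the selected size marked.
#' @return the table, invisibly when writing.
#' @export
plot_auc_by_size <- function(trace, path = NULL, plot_file = NULL) {
  stopifnot(inherits(trace, "refinement_trace"))
  tab <- trace$auc_by_size
  tab$selected <- tab$size == trace$selected_size
  if (!is.null(path)) {
    con <- file(path, "wb"); on.exit(close(con), add = TRUE)
    writeLines(paste(colnames(tab), collapse = "\t"), con)
    writeLines(sprintf("%d\t%s\t%s", tab$size,
                       format(tab$best_auc, digits = 15, trim = TRUE,
                              scientific = FALSE),
                       ifelse(tab$selected, "true", "false")), con)
  }
  if (!is.null(plot_file)) {
    if (grepl("\\.png$", plot_file)) grDevices::png(plot_file, 900, 500)
    else grDevices::pdf(plot_file, width = 9, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
    cols <- ifelse(tab$selected, "firebrick", "grey60")
    graphics::barplot(tab$best_auc, names.arg = tab$size, col = cols,
                      xlab = "signature size", ylab = "best AUC",
                      main = "AUC by gene-combination size", border = NA)
    graphics::abline(h = trace$max_auc, lty = 2)
  }
  if (is.null(path) && is.null(plot_file)) tab else invisible(tab)
}
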