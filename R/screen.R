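## Cell-type screening: which cell types' differential-expression programs
## predict the bulk phenotype.  Per cell type, the top up-regulated genes by
## |logFC| go to over-representation analysis; every enriched set is
## evaluated as a classifier on each bulk cohort; the set-level Welch-t ROC
## p-values are BH-adjusted within the (cell type, cohort) list; a cell type
## passes a cohort iff at least half of its enriched sets reach ROC FDR
## < `fdr_alpha`; the final call is the intersection across cohorts.

#' Screening parameters
#'
#' @param top_n genes submitted to enrichment per DE list (all if fewer).
#'   Default 500.
#' @param q_max,top_k over-representation cut-off and truncation (defaults
#'   0.05 and 10, the enrichment tool's display defaults).
#' @param apply_top_k apply the top-10 truncation before screening (default
#'   TRUE; set FALSE to screen all q-passing sets).
#' @param fdr_alpha ROC FDR threshold for the >= half rule. Default 0.05.
#' @param n_splits,train_fraction,distance classifier validation settings.
#' @param seed master seed; per-(cell type, set, cohort) child seeds are
#'   derived deterministically.
#' @return a `screen_params` list.
#' @export
screen_params <- function(top_n = 500L, q_max = 0.05, top_k = 10L,
                          apply_top_k = TRUE, fdr_alpha = 0.05,
                          n_splits = 200L, train_fraction = 2 / 3,
                          distance = "euclidean", seed = 1L) {
  structure(list(top_n = as.integer(top_n), q_max = q_max,
                 top_k = as.integer(top_k), apply_top_k = isTRUE(apply_top_k),
                 fdr_alpha = fdr_alpha, n_splits = as.integer(n_splits),
                 train_fraction = train_fraction, distance = distance,
                 seed = as.integer(seed)), class = "screen_params")
}

#' Screen cell types by the prediction power of their enriched gene sets
#'
#' @param de_lists named list (cell type -> DE result data frame from
#'   [de_two_group()] / [find_cluster_markers()]); only up-regulated genes
#'   (`log_fc > 0`) are submitted.
#' @param collection a [geneset_collection()].
#' @param cohorts list of bulk [cohort()] objects (named or numbered).
#' @param params a [screen_params()].
#' @param universe enrichment universe; default: the `measured` attribute of
#'   each DE result (all genes measured in the single-cell data).
#' @return a `screen_report`: per (cell type, cohort) the enriched sets,
#'   per-set AUC / ROC p / FDR, `n_enriched`, `n_significant`, `pass`, plus
#'   `passing_by_cohort` and the cross-cohort `intersection`.
#' @export
screen_cell_types <- function(de_lists, collection, cohorts,
                              params = screen_params(), universe = NULL) {
  stopifnot(is.list(de_lists), length(de_lists) >= 1L,
            inherits(collection, "geneset_collection"),
            is.list(cohorts), length(cohorts) >= 1L)
  if (is.null(names(cohorts)))
    names(cohorts) <- sprintf("cohort_%d", seq_along(cohorts))
  cells <- names(de_lists)
  results <- list()
  for (ct_i in seq_along(cells)) {
    ct <- cells[ct_i]
    de <- de_lists[[ct]]
    uni <- universe %||% attr(de, "measured") %||% de$gene
    up <- de[de$log_fc > 0, , drop = FALSE]
    query <- top_n_by_abs_logfc(up, params$top_n)
    enriched <- if (length(query) == 0L) NULL else
      tryCatch(enrich_overrepresentation(query, collection, uni,
                                         q_max = params$q_max,
                                         top_k = if (params$apply_top_k)
                                           params$top_k else Inf),
               error = function(e) NULL)
    for (co_i in seq_along(cohorts)) {
      co <- names(cohorts)[co_i]
      if (is.null(enriched) || nrow(enriched) == 0L) {
        results[[paste(ct, co, sep = "||")]] <- list(
          cell_type = ct, cohort = co, sets = data.frame(),
          n_enriched = 0L, n_significant = 0L, pass = FALSE,
          reason = "no enriched sets")
        next
      }
      evals <- lapply(seq_len(nrow(enriched)), function(si) {
        sd_seed <- derive_seed(params$seed,
                               1000L * ct_i + 100L * co_i + si)
        vr <- evaluate_gene_set(cohorts[[co_i]],
                                collection$sets[[enriched$set[si]]],
                                n_splits = params$n_splits,
                                train_fraction = params$train_fraction,
                                seed = sd_seed, distance = params$distance)
        c(auc = vr$auc, roc_p = vr$roc_p)
      })
      tab <- data.frame(set = enriched$set,
                        auc = vapply(evals, `[[`, numeric(1), "auc"),
                        roc_p = vapply(evals, `[[`, numeric(1), "roc_p"),
                        stringsAsFactors = FALSE)
      tab$roc_fdr <- stats::p.adjust(tab$roc_p, "BH")
      n_sig <- sum(tab$roc_fdr < params$fdr_alpha)
      results[[paste(ct, co, sep = "||")]] <- list(
        cell_type = ct, cohort = co, sets = tab,
        n_enriched = nrow(tab), n_significant = n_sig,
        pass = n_sig / nrow(tab) >= 0.5, reason = NULL)
    }
  }
  passing <- lapply(names(cohorts), function(co) {
    sort(vapply(Filter(function(r) r$cohort == co && r$pass, results),
                `[[`, character(1), "cell_type"))
  })
  names(passing) <- names(cohorts)
  structure(list(results = results, passing_by_cohort = passing,
                 intersection = sort(Reduce(intersect, passing)),
                 params = unclass(params)),
            class = "screen_report")
}

#' @export
print.screen_report <- function(x, ...) {
  cat("<screen_report>\n")
  for (r in x$results)
    cat(sprintf("  %-10s %-10s enriched %2d significant %2d -> %s%s\n",
                r$cell_type, r$cohort, r$n_enriched, r$n_significant,
                if (r$pass) "PASS" else "fail",
                if (!is.null(r$reason)) paste0(" (", r$reason, ")") else ""))
  cat(sprintf("  intersection: %s\n",
              if (length(x$intersection)) paste(x$intersection, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Compare prediction power across gene-set collection categories
#'
#' Descriptive only: per category, the median and IQR of enriched-set AUCs on
#' one cohort.  No decision rule is attached.
#'
#' @param de_lists as in [screen_cell_types()].
#' @param collections named list (category -> [geneset_collection()]).
#' @param cohort one bulk [cohort()].
#' @param params a [screen_params()].
#' @return data frame `category`, `n_sets`, `median_auc`, `iqr_auc`.
#' @export
compare_collections <- function(de_lists, collections, cohort,
                                params = screen_params()) {
  stopifnot(length(collections) >= 2L)
  rows <- lapply(names(collections), function(cat) {
    rep_ <- screen_cell_types(de_lists, collections[[cat]], list(one = cohort),
                              params = params)
    aucs <- unlist(lapply(rep_$results, function(r)
      if (nrow(r$sets)) r$sets$auc else numeric(0)), use.names = FALSE)
    data.frame(category = cat, n_sets = length(aucs),
               median_auc = if (length(aucs)) stats::median(aucs) else NA_real_,
               iqr_auc = if (length(aucs)) stats::IQR(aucs) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
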