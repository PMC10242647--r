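## Over-representation analysis of gene lists against GMT collections, and
## preranked enrichment for ordered gene lists.

#' Hypergeometric over-representation analysis
#'
#' One-sided upper-tail hypergeometric p per set (set membership intersected
#' with the universe); BH adjustment within each collection category (the
#' q-value reported per category mirrors per-collection reporting).  Returns
#' sets with `q < q_max`, at most `top_k`, sorted by q then p.
#'
#' @param query gene ids to test; ids outside the universe are dropped with a
#'   warning.
#' @param collection a [geneset_collection()].
#' @param universe gene ids forming the background (unique).
#' @param q_max FDR cut-off. Default 0.05.
#' @param top_k maximum number of sets returned. Default 10 (the enrichment
#'   tool's display default); use `Inf` to disable truncation.
#' @return data frame `set`, `category`, `overlap`, `set_size`, `query_size`,
#'   `universe_size`, `p`, `q`, with attribute `all_sets` holding the
#'   untruncated table.
#' @export
enrich_overrepresentation <- function(query, collection, universe,
                                      q_max = 0.05, top_k = 10L) {
  stopifnot(inherits(collection, "geneset_collection"))
  universe <- as.character(universe)
  if (anyDuplicated(universe)) stop_field("universe", "must be unique")
  query <- as.character(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(sprintf("%d query gene(s) outside the universe dropped", length(outside)),
            call. = FALSE)
    query <- intersect(query, universe)
  }
  query <- unique(query)
  if (length(query) == 0L)
    stop("empty query after universe filtering", call. = FALSE)
  N <- length(universe); k <- length(query)
  rows <- lapply(names(collection$sets), function(nm) {
    members <- intersect(collection$sets[[nm]], universe)
    m <- length(members)
    if (m == 0L) return(NULL)
    x <- length(intersect(members, query))
    p <- stats::phyper(x - 1L, m, N - m, k, lower.tail = FALSE)
    data.frame(set = nm, category = unname(collection$categories[[nm]]),
               overlap = x, set_size = m, query_size = k, universe_size = N,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) stop("no set has members in the universe", call. = FALSE)
  res$q <- NA_real_
  for (cat in unique(res$category)) {
    sel <- res$category == cat
    res$q[sel] <- stats::p.adjust(res$p[sel], "BH")
  }
  res <- res[order(res$q, res$p, res$set), , drop = FALSE]
  rownames(res) <- NULL
  keep <- res[res$q < q_max, , drop = FALSE]
  if (is.finite(top_k)) keep <- utils::head(keep, top_k)
  rownames(keep) <- NULL
  attr(keep, "all_sets") <- res
  keep
}

## weighted KS running-sum enrichment score over a ranking
## w: |score| weights in ranking order; inset: logical membership
es_running <- function(w, inset) {
  n <- length(w)
  k <- sum(inset)
  hit_w <- w * inset
  denom <- sum(hit_w)
  phit <- if (denom > 0) cumsum(hit_w) / denom else cumsum(inset) / k
  pmiss <- cumsum(!inset) / (n - k)
  v <- phit - pmiss
  v[which.max(abs(v))]
}

#' Preranked gene-set enrichment (weighted KS, gene-permutation null)
#'
#' Computes the weighted Kolmogorov-Smirnov running-sum enrichment score
#' (weight = |score|, exponent 1) per set, a gene-label permutation p-value
#' (`n_perm` seeded draws, sign-aware with +1 correction), a normalized ES
#' (observed ES over the mean |permuted ES| of the same sign), and BH q within
#' each collection category.  Sets with fewer than 2 members in the ranked
#' universe, or spanning the entire list, are skipped with a warning.
#'
#' @param ranked named numeric vector of ranking scores (e.g. log fold
#'   changes), sorted in decreasing order; names are unique gene ids.
#' @param collection a [geneset_collection()].
#' @param n_perm number of permutations (>= 100).
#' @param seed integer seed for the permutation stream.
#' @return data frame `set`, `category`, `size`, `es`, `nes`, `p`, `q`.
#' @export
gsea_preranked <- function(ranked, collection, n_perm = 1000L, seed = 1L) {
  stopifnot(inherits(collection, "geneset_collection"))
  if (!is_count(n_perm) || n_perm < 100L) stop_field("n_perm", "must be >= 100")
  genes <- names(ranked)
  if (is.null(genes) || anyDuplicated(genes))
    stop_field("ranked", "must be a named vector with unique gene ids")
  if (!all(is.finite(ranked))) stop_field("ranked", "scores must be finite")
  if (is.unsorted(rev(ranked))) ranked <- sort(ranked, decreasing = TRUE)
  genes <- names(ranked)
  n <- length(ranked)
  w <- abs(ranked)
  rows <- withr::with_seed(as.integer(seed), {
    lapply(names(collection$sets), function(nm) {
      inset <- genes %in% collection$sets[[nm]]
      k <- sum(inset)
      if (k < 2L || k >= n) {
        warning(sprintf("set '%s' skipped (%d member(s) in ranked universe)",
                        nm, k), call. = FALSE)
        return(NULL)
      }
      es <- es_running(w, inset)
      perm <- vapply(seq_len(n_perm), function(i) {
        pos <- sample.int(n, k)
        ins <- logical(n); ins[pos] <- TRUE
        es_running(w, ins)
      }, numeric(1))
      same <- perm[sign(perm) == sign(es) | perm == 0]
      p <- (1 + sum(abs(perm) >= abs(es) & sign(perm) == sign(es))) / (1 + n_perm)
      nes <- if (length(same) && mean(abs(same)) > 0) es / mean(abs(same)) else NA_real_
      data.frame(set = nm, category = unname(collection$categories[[nm]]),
                 size = k, es = es, nes = nes, p = p, stringsAsFactors = FALSE)
    })
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(set = character(0), category = character(0),
                      size = integer(0), es = numeric(0), nes = numeric(0),
                      p = numeric(0), q = numeric(0), stringsAsFactors = FALSE))
  res$q <- NA_real_
  for (cat in unique(res$category)) {
    sel <- res$category == cat
    res$q[sel] <- stats::p.adjust(res$p[sel], "BH")
  }
  rownames(res) <- NULL
  res
}
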