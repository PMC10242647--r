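## Synthetic cohorts with planted structure.  The generator states one world:
## a shared gene universe gene_00001..gene_N; cluster k's markers occupy the
## k-th disjoint block of `n_markers_per_cluster` genes; the bulk
## discriminative panel is the first `panel_size` genes, i.e. it lies inside
## the first cluster's marker block.  The first cluster is therefore the
## signal-bearing subcluster (the immune-activated B-cell analogue) in
## end-to-end runs.

#' Specification of the synthetic world
#'
#' Defaults mirror the scale at which the pipeline is exercised end to end:
#' 2,000 genes; five immune subclusters of 200 cells (three B-cell
#' subclusters, one NK, one monocyte); 50 planted markers per cluster at a
#' log2 shift of 2; bulk cohorts of 40 + 40 samples with a 13-gene panel
#' shifted by 2 standard deviations; 3 planted-enrichment sets among 30 null
#' sets of 25 genes.
#'
#' @param n_genes number of genes in the shared universe.
#' @param clusters data frame with columns `cell_type` and `subcluster`; one
#'   row per cluster.  The first row is the signal-bearing subcluster.
#' @param n_cells_per_cluster cells simulated per cluster.
#' @param n_markers_per_cluster planted marker genes per cluster.
#' @param marker_log2_shift log2 fold-change of planted markers in their
#'   cluster versus all others.
#' @param n_bulk_samples_per_class bulk samples per class (balanced design).
#' @param panel_size number of planted discriminative bulk genes.
#' @param panel_effect mean shift of panel genes in the positive class, in
#'   units of each gene's log-scale standard deviation.
#' @param baseline_model `"lognormal"` (continuous, array-like) or
#'   `"negative_binomial"` (integer counts, 10x-like) for the cell matrix.
#' @param baseline_params hyperparameters of the baseline: for lognormal,
#'   `mu_mean`, `mu_sd` (per-gene log2 mean prior) and `sigma_min`,
#'   `sigma_max` (per-gene log2 sd, uniform); for negative binomial,
#'   `nb_mean_meanlog`, `nb_mean_sdlog` (per-gene mean, lognormal prior) and
#'   `nb_size` (dispersion).  For bulk cohorts `bulk_mu_mean`, `bulk_mu_sd`.
#' @param n_true_sets,n_null_sets,set_size gene-set planting parameters.
#' @param n_donors_per_condition donors per condition; cells inherit their
#'   donor's condition (`"disease"`/`"normal"`).
#' @param seed master seed; child seeds for each sub-simulation are derived
#'   by fixed offsets.
#' @return a validated `synthetic_spec`.
#' @export
synthetic_spec <- function(n_genes = 2000L,
                           clusters = data.frame(
                             cell_type = c("B", "B", "B", "NK", "Mono"),
                             subcluster = c("B_C4", "B_C1", "B_C2", "NK_C1", "Mono_C1"),
                             stringsAsFactors = FALSE),
                           n_cells_per_cluster = 200L,
                           n_markers_per_cluster = 50L,
                           marker_log2_shift = 2,
                           n_bulk_samples_per_class = 40L,
                           panel_size = 13L,
                           panel_effect = 2,
                           baseline_model = c("lognormal", "negative_binomial"),
                           baseline_params = list(),
                           n_true_sets = 3L,
                           n_null_sets = 30L,
                           set_size = 25L,
                           n_donors_per_condition = 4L,
                           seed = 1L) {
  baseline_model <- match.arg(baseline_model)
  defaults <- list(mu_mean = 2, mu_sd = 1, sigma_min = 0.5, sigma_max = 1.5,
                   nb_mean_meanlog = 0, nb_mean_sdlog = 1, nb_size = 2,
                   bulk_mu_mean = 8, bulk_mu_sd = 2)
  unknown <- setdiff(names(baseline_params), names(defaults))
  if (length(unknown))
    stop_field("baseline_params", paste0("unknown parameter(s): ",
               paste(unknown, collapse = ", ")))
  baseline_params <- utils::modifyList(defaults, baseline_params)
  spec <- structure(list(
    n_genes = as.integer(n_genes), clusters = clusters,
    n_cells_per_cluster = as.integer(n_cells_per_cluster),
    n_markers_per_cluster = as.integer(n_markers_per_cluster),
    marker_log2_shift = marker_log2_shift,
    n_bulk_samples_per_class = as.integer(n_bulk_samples_per_class),
    panel_size = as.integer(panel_size), panel_effect = panel_effect,
    baseline_model = baseline_model, baseline_params = baseline_params,
    n_true_sets = as.integer(n_true_sets), n_null_sets = as.integer(n_null_sets),
    set_size = as.integer(set_size),
    n_donors_per_condition = as.integer(n_donors_per_condition),
    seed = as.integer(seed)), class = "synthetic_spec")
  validate_spec(spec)
  spec
}

validate_spec <- function(spec) {
  for (f in c("n_genes", "n_cells_per_cluster", "n_markers_per_cluster",
              "n_bulk_samples_per_class", "panel_size", "set_size",
              "n_donors_per_condition"))
    if (!is_count(spec[[f]])) stop_field(f, "must be a positive integer")
  for (f in c("n_true_sets", "n_null_sets"))
    if (!(is.numeric(spec[[f]]) && spec[[f]] >= 0 && spec[[f]] == floor(spec[[f]])))
      stop_field(f, "must be a non-negative integer")
  if (!is.data.frame(spec$clusters) ||
      !all(c("cell_type", "subcluster") %in% names(spec$clusters)) ||
      nrow(spec$clusters) < 1L)
    stop_field("clusters", "must be a data frame with cell_type and subcluster")
  if (anyDuplicated(spec$clusters$subcluster))
    stop_field("clusters", "subcluster labels must be unique")
  if (spec$panel_size > spec$n_genes)
    stop_field("panel_size", "exceeds n_genes")
  if (spec$n_markers_per_cluster * nrow(spec$clusters) > spec$n_genes)
    stop_field("n_markers_per_cluster", "marker blocks exceed n_genes")
  if (!is.numeric(spec$marker_log2_shift) || !is.finite(spec$marker_log2_shift))
    stop_field("marker_log2_shift", "must be finite")
  if (!is.numeric(spec$panel_effect) || !is.finite(spec$panel_effect))
    stop_field("panel_effect", "must be finite")
  invisible(spec)
}

gene_universe <- function(spec) sprintf("gene_%05d", seq_len(spec$n_genes))

#' Planted ground truth implied by a spec
#'
#' @param spec a [synthetic_spec()].
#' @return a `ground_truth` list: `marker_map` (subcluster -> planted marker
#'   ids), `panel` (planted discriminative bulk genes), `true_sets` (names of
#'   planted enriched sets), `signal_subcluster`, `signal_cell_type`.
#' @export
ground_truth <- function(spec) {
  genes <- gene_universe(spec)
  m <- spec$n_markers_per_cluster
  k <- nrow(spec$clusters)
  marker_map <- stats::setNames(lapply(seq_len(k), function(i)
    genes[((i - 1L) * m + 1L):(i * m)]), spec$clusters$subcluster)
  panel <- genes[seq_len(min(spec$panel_size, m))]
  if (spec$panel_size > m) {
    tail_pool <- genes[(m * k + 1L):spec$n_genes]
    panel <- c(panel, tail_pool[seq_len(spec$panel_size - m)])
  }
  structure(list(marker_map = marker_map, panel = panel,
                 true_sets = if (spec$n_true_sets > 0)
                   sprintf("TRUE_SET_%02d", seq_len(spec$n_true_sets))
                 else character(0),
                 signal_subcluster = spec$clusters$subcluster[1L],
                 signal_cell_type = spec$clusters$cell_type[1L]),
            class = "ground_truth")
}

#' Simulate a single-cell-like cohort with planted cluster markers
#'
#' Baseline expression is log-normal on the log2 scale (per-gene mean and sd
#' drawn from the spec's hyperpriors) or negative-binomial counts.  Each
#' cluster's planted markers receive an additive `marker_log2_shift` on the
#' log scale (multiplicative on the raw scale) in that cluster's cells.
#' Disease/normal condition is assigned at donor level; cells inherit it.
#'
#' @param spec a [synthetic_spec()].
#' @return list with `cohort` (a [cohort()]: counts-layer matrix + cell
#'   metadata `id`, `cell_type`, `subcluster`, `condition`, `donor`) and
#'   `truth` (a [ground_truth()]).
#' @export
simulate_cell_cohort <- function(spec) {
  validate_spec(spec)
  truth <- ground_truth(spec)
  genes <- gene_universe(spec)
  k <- nrow(spec$clusters); npc <- spec$n_cells_per_cluster
  n_cells <- k * npc
  bp <- spec$baseline_params

  cluster_of <- rep(seq_len(k), each = npc)
  donors_dis <- sprintf("donor_D%02d", seq_len(spec$n_donors_per_condition))
  donors_nor <- sprintf("donor_N%02d", seq_len(spec$n_donors_per_condition))
  all_donors <- c(rbind(donors_dis, donors_nor))  # alternate conditions
  donor <- all_donors[((seq_len(npc) - 1L) %% length(all_donors)) + 1L]
  donor <- rep(donor, times = k)
  condition <- ifelse(grepl("_D", donor, fixed = TRUE), "disease", "normal")

  ## log2 shift matrix: markers of cluster i up in cluster i's cells
  shift <- matrix(0, nrow = spec$n_genes, ncol = n_cells)
  rownames(shift) <- genes
  for (i in seq_len(k))
    shift[truth$marker_map[[i]], cluster_of == i] <- spec$marker_log2_shift

  vals <- withr::with_seed(derive_seed(spec$seed, 11L), {
    if (spec$baseline_model == "lognormal") {
      mu <- stats::rnorm(spec$n_genes, bp$mu_mean, bp$mu_sd)
      sg <- stats::runif(spec$n_genes, bp$sigma_min, bp$sigma_max)
      z <- matrix(stats::rnorm(spec$n_genes * n_cells), nrow = spec$n_genes)
      2^(mu + shift + sg * z)
    } else {
      mu <- stats::rlnorm(spec$n_genes, bp$nb_mean_meanlog, bp$nb_mean_sdlog)
      lam <- mu * 2^shift
      matrix(stats::rnbinom(spec$n_genes * n_cells, mu = lam, size = bp$nb_size),
             nrow = spec$n_genes)
    }
  })
  ids <- sprintf("cell_%05d", seq_len(n_cells))
  dimnames(vals) <- list(genes, ids)
  meta <- data.frame(id = ids,
                     cell_type = spec$clusters$cell_type[cluster_of],
                     subcluster = spec$clusters$subcluster[cluster_of],
                     condition = condition, donor = donor,
                     stringsAsFactors = FALSE)
  list(cohort = cohort(expr_matrix(vals, "counts"), meta), truth = truth)
}

#' Simulate a two-class bulk cohort with a planted discriminative panel
#'
#' Values are array-like log2-scale intensities (layer `"lognorm"`): per gene,
#' `mu_g + sigma_g * z`, with panel genes in the positive class shifted by
#' `panel_effect * sigma_g`.  Labels are balanced.
#'
#' @param spec a [synthetic_spec()].
#' @param cohort_id integer distinguishing independent cohorts generated from
#'   the same spec (enters the derived seed); cohort 1 and cohort 2 stand in
#'   for the two MI screening cohorts, higher ids for refinement/held-out data.
#' @return list with `cohort` (a [cohort()]: lognorm-layer matrix + metadata
#'   `id`, `class_label`) and `truth`.
#' @export
simulate_bulk_cohort <- function(spec, cohort_id = 1L) {
  validate_spec(spec)
  if (!is_count(cohort_id)) stop_field("cohort_id", "must be a positive integer")
  truth <- ground_truth(spec)
  genes <- gene_universe(spec)
  n_per <- spec$n_bulk_samples_per_class
  n <- 2L * n_per
  bp <- spec$baseline_params
  positive <- rep(c(TRUE, FALSE), each = n_per)

  vals <- withr::with_seed(derive_seed(spec$seed, 20000L + as.integer(cohort_id)), {
    mu <- stats::rnorm(spec$n_genes, bp$bulk_mu_mean, bp$bulk_mu_sd)
    sg <- stats::runif(spec$n_genes, bp$sigma_min, bp$sigma_max)
    z <- matrix(stats::rnorm(spec$n_genes * n), nrow = spec$n_genes)
    shift <- matrix(0, spec$n_genes, n, dimnames = list(genes, NULL))
    shift[truth$panel, positive] <- spec$panel_effect
    mu + sg * (z + shift)
  })
  ids <- sprintf("sample_c%d_%03d", cohort_id, seq_len(n))
  dimnames(vals) <- list(genes, ids)
  meta <- data.frame(id = ids,
                     class_label = ifelse(positive, "positive", "negative"),
                     stringsAsFactors = FALSE)
  list(cohort = cohort(expr_matrix(vals, "lognorm"), meta), truth = truth)
}

#' Simulate a gene-set collection with planted "true" sets
#'
#' True sets draw at least 80% of their members from planted genes (the bulk
#' panel for the first set, then each cluster's marker block in turn) and the
#' remainder from non-planted genes; null sets are drawn uniformly from
#' non-planted genes.  All member ids exist in the cohort gene universe.
#'
#' @param spec a [synthetic_spec()].
#' @param truth the [ground_truth()] generated from the same spec.
#' @return a [geneset_collection()] (category `"GOBP"`).
#' @export
simulate_geneset_collection <- function(spec, truth) {
  validate_spec(spec)
  stopifnot(inherits(truth, "ground_truth"))
  genes <- gene_universe(spec)
  planted <- unique(c(truth$panel, unlist(truth$marker_map, use.names = FALSE)))
  free <- setdiff(genes, planted)
  if (spec$set_size > length(free))
    stop_field("set_size", sprintf("only %d non-planted genes available",
                                   length(free)))
  sources <- c(list(truth$panel), truth$marker_map)
  withr::with_seed(derive_seed(spec$seed, 31L), {
    sets <- list()
    for (i in seq_len(spec$n_true_sets)) {
      src <- sources[[((i - 1L) %% length(sources)) + 1L]]
      need <- ceiling(0.8 * spec$set_size)
      if (length(src) >= need) {
        core <- sample(src, need)
        fill <- sample(free, spec$set_size - need)
      } else {  # shrink the set so the planted fraction stays >= 80%
        core <- src
        fill_n <- max(0L, floor(length(src) / 0.8) - length(src))
        fill <- if (fill_n > 0) sample(free, fill_n) else character(0)
      }
      sets[[sprintf("TRUE_SET_%02d", i)]] <- sort(unique(c(core, fill)))
    }
    for (i in seq_len(spec$n_null_sets))
      sets[[sprintf("NULL_SET_%02d", i)]] <- sort(sample(free, spec$set_size))
    geneset_collection(sets, "GOBP")
  })
}
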