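## End-to-end orchestration: simulate -> normalize/markers -> screen ->
## GSVA subcluster attribution -> candidate pool -> cyclic refinement ->
## final validation on a held-out cohort.  Stage outputs are files so any
## stage can be re-run standalone; the manifest is fully deterministic
## (timings go to a separate timings.tsv, outside the byte-identity contract).

pipeline_defaults <- function() list(
  synthetic = list(),
  de = list(min_pct = 0.1, logfc_threshold = 0.25, alpha = 0.05),
  enrich = list(top_n = 500L, q_max = 0.05, top_k = 10L, apply_top_k = TRUE),
  gsea = list(n_perm = 1000L),
  gsva = list(kcdf = "auto", stat = "max_diff"),
  classify = list(n_splits = 200L, train_fraction = 2 / 3,
                  distance = "euclidean"),
  refine = list(stop_size = 3L, selection_rule = "smallest_max",
                subset_sample = 0L),   # 0 = evaluate all leave-one-out subsets
  seed = 1L,
  out_dir = NULL,
  write_matrices = TRUE)

merge_checked <- function(defaults, user, path) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key: %s", paste(paste0(path, unknown),
                                                 collapse = ", ")), call. = FALSE)
  utils::modifyList(defaults, user)
}

#' Validate and normalize a pipeline configuration
#'
#' Fills every default (paper-stated values where they exist: `min_pct` 0.1,
#' `logfc_threshold` 0.25, `alpha`/`q_max` 0.05, `top_n` 500, `top_k` 10,
#' `stop_size` 3), rejects unknown keys by name, and range-checks values.
#' Idempotent: `validate_config(validate_config(x))` equals
#' `validate_config(x)`.
#'
#' @param config a (possibly partial) configuration list.
#' @return the normalized configuration.
#' @export
validate_config <- function(config = list()) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stop(sprintf("unknown config key: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  cfg <- defaults
  for (k in c("de", "enrich", "gsea", "gsva", "classify", "refine"))
    if (!is.null(config[[k]]))
      cfg[[k]] <- merge_checked(defaults[[k]], config[[k]], paste0(k, "$"))
  if (!is.null(config$synthetic)) {
    allowed <- setdiff(names(formals(synthetic_spec)), "seed")
    unknown <- setdiff(names(config$synthetic), allowed)
    if (length(unknown))
      stop(sprintf("unknown config key: %s",
                   paste(paste0("synthetic$", unknown), collapse = ", ")),
           call. = FALSE)
    syn <- config$synthetic
    if (!is.null(syn$clusters) && !is.data.frame(syn$clusters))
      syn$clusters <- as.data.frame(syn$clusters, stringsAsFactors = FALSE)
    cfg$synthetic <- syn
  }
  for (k in c("seed", "out_dir", "write_matrices"))
    if (!is.null(config[[k]])) cfg[[k]] <- config[[k]]
  with(cfg, {
    if (!is_fraction(de$min_pct, open = FALSE)) stop_field("de$min_pct", "must be in [0,1]")
    if (de$logfc_threshold < 0) stop_field("de$logfc_threshold", "must be >= 0")
    if (!is_fraction(de$alpha)) stop_field("de$alpha", "must be in (0,1)")
    if (!is_fraction(enrich$q_max)) stop_field("enrich$q_max", "must be in (0,1)")
    if (!is_count(enrich$top_n)) stop_field("enrich$top_n", "must be a positive integer")
    if (!is_count(enrich$top_k)) stop_field("enrich$top_k", "must be a positive integer")
    if (!is_count(gsea$n_perm) || gsea$n_perm < 100) stop_field("gsea$n_perm", "must be >= 100")
    if (!is_count(classify$n_splits)) stop_field("classify$n_splits", "must be a positive integer")
    if (!is_fraction(classify$train_fraction)) stop_field("classify$train_fraction", "must be in (0,1)")
    if (!is_count(refine$stop_size)) stop_field("refine$stop_size", "must be a positive integer")
    if (!is.numeric(refine$subset_sample) || refine$subset_sample < 0)
      stop_field("refine$subset_sample", "must be 0 (all subsets) or a positive integer")
    if (!is.numeric(seed) || length(seed) != 1L) stop_field("seed", "must be one integer")
  })
  cfg$seed <- as.integer(cfg$seed)
  cfg$de$min_pct <- as.numeric(cfg$de$min_pct)
  cfg$enrich$top_n <- as.integer(cfg$enrich$top_n)
  cfg$enrich$top_k <- as.integer(cfg$enrich$top_k)
  cfg$gsea$n_perm <- as.integer(cfg$gsea$n_perm)
  cfg$classify$n_splits <- as.integer(cfg$classify$n_splits)
  cfg$refine$stop_size <- as.integer(cfg$refine$stop_size)
  cfg
}

#' Read a pipeline configuration from YAML or JSON
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return the raw configuration list (run [validate_config()] on it).
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path)) jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

write_de_tsv <- function(de, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(paste(c("gene", "log_fc", "pct_1", "pct_2", "p", "p_adj"),
                   collapse = "\t"), con)
  if (nrow(de))
    writeLines(paste(de$gene,
                     format(de$log_fc, digits = 15, trim = TRUE, scientific = FALSE),
                     format(de$pct_1, digits = 15, trim = TRUE, scientific = FALSE),
                     format(de$pct_2, digits = 15, trim = TRUE, scientific = FALSE),
                     format(de$p, digits = 15, trim = TRUE),
                     format(de$p_adj, digits = 15, trim = TRUE),
                     sep = "\t"), con)
  invisible(path)
}

#' Run the full signature-discovery pipeline on synthetic data
#'
#' Executes simulate -> log-normalize -> per-subcluster markers and
#' per-cell-type DE lists -> over-representation + classifier screening on
#' two bulk cohorts -> GSVA attribution of the screened sets to a subcluster
#' -> candidate pool from sets with ROC FDR < 0.05 on the refinement cohort
#' -> cyclic leave-one-out refinement -> validation of the selected
#' signature on the (in-sample) refinement cohort and on an independent
#' held-out cohort generated with a fresh seed, plus a ground-truth
#' concordance report.
#'
#' @param config a configuration list (see [validate_config()]); must carry
#'   `out_dir`.
#' @return the run manifest (`run_manifest`), invisibly; all stage outputs
#'   are files under `out_dir`.
#' @export
run_full_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  if (is.null(cfg$out_dir)) stop_field("out_dir", "must be set")
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)
  timings <- list()
  outputs <- character(0)
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed (completed: %s): %s", name,
                   paste(names(timings), collapse = ", "),
                   conditionMessage(e)), call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    res
  }
  register <- function(path) { outputs <<- c(outputs, path); path }

  ## --- simulate ----------------------------------------------------------
  sim <- stage("simulate", {
    spec <- do.call(synthetic_spec, c(cfg$synthetic, list(seed = cfg$seed)))
    cell <- simulate_cell_cohort(spec)
    bulk <- lapply(1:4, function(i) simulate_bulk_cohort(spec, i))
    coll <- simulate_geneset_collection(spec, cell$truth)
    write_report(cell$truth, register(out("ground_truth.json")))
    write_gmt(coll, register(out("gene_sets.gmt")))
    write_metadata(cell$cohort$metadata, register(out("cell_metadata.tsv")))
    for (i in 1:4)
      write_metadata(bulk[[i]]$cohort$metadata,
                     register(out(sprintf("bulk%d_metadata.tsv", i))))
    if (isTRUE(cfg$write_matrices)) {
      write_matrix(cell$cohort$matrix, register(out("cell_counts.tsv")))
      for (i in 1:4)
        write_matrix(bulk[[i]]$cohort$matrix,
                     register(out(sprintf("bulk%d_matrix.tsv", i))))
    }
    list(spec = spec, cell = cell, bulk = bulk, coll = coll)
  })
  truth <- sim$cell$truth
  dep <- de_params(cfg$de$min_pct, cfg$de$logfc_threshold, cfg$de$alpha, "up")

  ## --- markers & per-cell-type DE lists ---------------------------------
  mk <- stage("markers", {
    logn <- lognormalize(sim$cell$cohort$matrix)
    meta <- sim$cell$cohort$metadata
    subcl <- find_cluster_markers(logn, meta$subcluster, dep)
    celltype <- find_cluster_markers(logn, meta$cell_type, dep)
    for (nm in names(subcl))
      write_de_tsv(subcl[[nm]], register(out(sprintf("markers_%s.tsv", nm))))
    for (nm in names(celltype))
      write_de_tsv(celltype[[nm]], register(out(sprintf("de_celltype_%s.tsv", nm))))
    list(logn = logn, subcl = subcl, celltype = celltype)
  })

  ## --- screening ---------------------------------------------------------
  scr <- stage("screen", {
    sp <- screen_params(top_n = cfg$enrich$top_n, q_max = cfg$enrich$q_max,
                        top_k = cfg$enrich$top_k,
                        apply_top_k = cfg$enrich$apply_top_k,
                        n_splits = cfg$classify$n_splits,
                        train_fraction = cfg$classify$train_fraction,
                        distance = cfg$classify$distance,
                        seed = derive_seed(cfg$seed, 3L))
    rep_ <- screen_cell_types(mk$celltype, sim$coll,
                              list(cohort_1 = sim$bulk[[1]]$cohort,
                                   cohort_2 = sim$bulk[[2]]$cohort), sp)
    write_report(rep_, register(out("screen_report.json")))
    rep_
  })

  ## --- subcluster attribution via single-sample scores -------------------
  attrib <- stage("attribution", {
    picked <- scr$intersection
    if (length(picked) == 0L) return(list(note = "no cell type passed screening"))
    ct <- picked[1L]
    sets1 <- scr$results[[paste(ct, "cohort_1", sep = "||")]]$sets
    sig_sets <- sets1$set[sets1$roc_fdr < 0.05]
    if (length(sig_sets) == 0L) sig_sets <- sets1$set
    meta <- sim$cell$cohort$metadata
    cells <- meta$id[meta$cell_type == ct]
    sub <- mk$logn[, cells]
    sc <- gsva_score(sub, geneset_collection(sim$coll$sets[sig_sets],
                                             sim$coll$categories[sig_sets]),
                     kcdf_mode = cfg$gsva$kcdf, stat_mode = cfg$gsva$stat)
    subcl <- meta$subcluster[match(colnames(sc), meta$id)]
    mean_by <- vapply(unique(subcl), function(s)
      mean(sc[, subcl == s, drop = FALSE]), numeric(1))
    attributed <- names(mean_by)[which.max(mean_by)]
    cmp <- if (sum(subcl != attributed) >= 2L)
      score_group_compare(sc, which(subcl == attributed),
                          which(subcl != attributed))
    else NULL  # single-subcluster cell type: nothing to compare against
    res <- list(cell_type = ct, attributed_subcluster = attributed,
                mean_score_by_subcluster = as.list(mean_by),
                score_compare = cmp)
    write_report(res, register(out("attribution.json")))
    res
  })

  ## --- candidate pool on the refinement cohort ---------------------------
  pool <- stage("pool", {
    picked <- if (!is.null(attrib$cell_type)) attrib$cell_type
              else names(mk$celltype)[1L]
    sets1 <- scr$results[[paste(picked, "cohort_1", sep = "||")]]$sets
    if (is.null(sets1) || nrow(sets1) == 0L)
      stop("no enriched sets available for pool construction", call. = FALSE)
    evals <- vapply(seq_len(nrow(sets1)), function(si) {
      evaluate_gene_set(sim$bulk[[3]]$cohort, sim$coll$sets[[sets1$set[si]]],
                        n_splits = cfg$classify$n_splits,
                        train_fraction = cfg$classify$train_fraction,
                        seed = derive_seed(cfg$seed, 5000L + si),
                        distance = cfg$classify$distance)$roc_p
    }, numeric(1))
    qual <- data.frame(set = sets1$set, q = stats::p.adjust(evals, "BH"),
                       stringsAsFactors = FALSE)
    pool <- build_candidate_pool(qual, sim$coll, alpha = 0.05)
    writeLines(pool, register(out("candidate_pool.txt")))
    pool
  })

  ## --- refinement ---------------------------------------------------------
  tr <- stage("refine", {
    tr <- refine_signature(pool, sim$bulk[[3]]$cohort,
                           n_splits = cfg$classify$n_splits,
                           train_fraction = cfg$classify$train_fraction,
                           distance = cfg$classify$distance,
                           stop_size = cfg$refine$stop_size,
                           seed = derive_seed(cfg$seed, 6L),
                           selection_rule = cfg$refine$selection_rule,
                           subset_sample = if (cfg$refine$subset_sample > 0)
                             cfg$refine$subset_sample else Inf)
    write_report(tr, register(out("refinement_trace.json")))
    plot_auc_by_size(tr, path = register(out("auc_by_size.tsv")))
    writeLines(tr$selected_signature, register(out("signature.txt")))
    tr
  })

  ## --- final validation ---------------------------------------------------
  val <- stage("validate", {
    insample <- multiple_random_validation(sim$bulk[[3]]$cohort,
                                           tr$selected_signature,
                                           cfg$classify$n_splits,
                                           cfg$classify$train_fraction,
                                           derive_seed(cfg$seed, 7L),
                                           cfg$classify$distance)
    heldout <- multiple_random_validation(sim$bulk[[4]]$cohort,
                                          tr$selected_signature,
                                          cfg$classify$n_splits,
                                          cfg$classify$train_fraction,
                                          derive_seed(cfg$seed, 8L),
                                          cfg$classify$distance)
    write_report(insample, register(out("validation_insample.json")))
    write_report(heldout, register(out("validation_heldout.json")))
    list(insample = insample, heldout = heldout)
  })

  ## --- ground-truth concordance ------------------------------------------
  conc <- stage("concordance", {
    marker_recovery <- vapply(names(truth$marker_map), function(cl) {
      found <- mk$subcl[[cl]]$gene
      length(intersect(found, truth$marker_map[[cl]])) /
        length(truth$marker_map[[cl]])
    }, numeric(1))
    res <- list(
      marker_recovery_by_cluster = as.list(marker_recovery),
      screen_intersection = scr$intersection,
      screen_correct = identical(scr$intersection, truth$signal_cell_type),
      attributed_subcluster = attrib$attributed_subcluster %||% NA,
      attribution_correct = identical(attrib$attributed_subcluster,
                                      truth$signal_subcluster),
      signature_size = length(tr$selected_signature),
      panel_recovered = length(intersect(tr$selected_signature, truth$panel)),
      panel_size = length(truth$panel),
      heldout_auc = val$heldout$auc,
      insample_auc = val$insample$auc)
    write_report(res, register(out("concordance.json")))
    res
  })

  ## --- manifest (deterministic) + timings (not) ---------------------------
  checksums <- stats::setNames(lapply(outputs, file_checksum), basename(outputs))
  manifest <- structure(list(
    schema_version = report_schema_version,
    config = cfg[setdiff(names(cfg), "out_dir")],
    seed = cfg$seed,
    seed_ledger = list(screen = derive_seed(cfg$seed, 3L),
                       refine = derive_seed(cfg$seed, 6L),
                       validate_insample = derive_seed(cfg$seed, 7L),
                       validate_heldout = derive_seed(cfg$seed, 8L)),
    outputs = basename(outputs),
    checksums = checksums,
    concordance = conc), class = "run_manifest")
  write_report(manifest, out("manifest.json"))
  tcon <- file(out("timings.tsv"), "wb")
  writeLines(c("stage\tseconds",
               sprintf("%s\t%.3f", names(timings), unlist(timings))), tcon)
  close(tcon)
  invisible(manifest)
}
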