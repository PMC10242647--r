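## Readers/writers for the plain-text formats the pipeline touches.
## All parsers reject malformed input with a file position; nothing is coerced.

#' Read an expression matrix from TSV or MatrixMarket
#'
#' TSV dialect: tab-separated, no quoting, first row = column ids, first
#' column = gene ids.  MTX: a MatrixMarket file with `genes.txt` and
#' `barcodes.txt` sidecars (one id per line) next to it.
#'
#' @param path file path (`.tsv` or `.mtx`).
#' @param format `"tsv"` or `"mtx"`.
#' @param layer layer tag to validate against (`"counts"` or `"lognorm"`).
#' @return an [expr_matrix()].
#' @export
read_matrix <- function(path, format = c("tsv", "mtx"), layer = "counts") {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  if (format == "tsv") {
    lines <- readLines(path)
    if (length(lines) < 2L) stop(sprintf("%s: need a header and >= 1 gene row", path),
                                 call. = FALSE)
    fields <- strsplit(lines, "\t", fixed = TRUE)
    header <- fields[[1L]]
    ncol_exp <- length(header)
    body <- fields[-1L]
    bad <- which(lengths(body) != ncol_exp)
    if (length(bad))
      stop(sprintf("%s: ragged row at line %d (%d fields, expected %d)",
                   path, bad[1L] + 1L, lengths(body)[bad[1L]], ncol_exp), call. = FALSE)
    genes <- vapply(body, `[[`, character(1), 1L)
    vals <- suppressWarnings(
      matrix(as.numeric(unlist(lapply(body, `[`, -1L), use.names = FALSE)),
             nrow = length(body), byrow = TRUE))
    if (anyNA(vals))
      stop(sprintf("%s: non-numeric value in matrix body", path), call. = FALSE)
    ## header may or may not carry a corner label; detect by field count
    cols <- if (ncol_exp == ncol(vals) + 1L) header[-1L] else header
    if (length(cols) != ncol(vals))
      stop(sprintf("%s: header has %d ids for %d value columns", path,
                   length(cols), ncol(vals)), call. = FALSE)
    dimnames(vals) <- list(genes, cols)
    expr_matrix(vals, layer)
  } else {
    dir <- dirname(path)
    gf <- file.path(dir, "genes.txt"); bf <- file.path(dir, "barcodes.txt")
    for (f in c(gf, bf)) if (!file.exists(f))
      stop(sprintf("missing MTX sidecar: %s", f), call. = FALSE)
    m <- as.matrix(Matrix::readMM(path))
    genes <- readLines(gf); cols <- readLines(bf)
    if (nrow(m) != length(genes) || ncol(m) != length(cols))
      stop(sprintf("%s: dimensions %dx%d do not match sidecars (%d genes, %d columns)",
                   path, nrow(m), ncol(m), length(genes), length(cols)), call. = FALSE)
    dimnames(m) <- list(genes, cols)
    expr_matrix(m, layer)
  }
}

#' Write an expression matrix to TSV or MatrixMarket
#'
#' @param m an [expr_matrix()].
#' @param path destination file.
#' @param format `"tsv"` or `"mtx"` (MTX writes `genes.txt`/`barcodes.txt`
#'   sidecars next to `path`).
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path, format = c("tsv", "mtx")) {
  format <- match.arg(format)
  stopifnot(inherits(m, "expr_matrix"))
  if (format == "tsv") {
    con <- file(path, "wb")  # binary mode: byte-stable newlines across platforms
    on.exit(close(con))
    writeLines(paste(c("gene_id", colnames(m)), collapse = "\t"), con)
    body <- apply(unclass(m), 1L, function(r)
      paste(format(r, digits = 15, trim = TRUE, scientific = FALSE), collapse = "\t"))
    writeLines(paste(rownames(m), body, sep = "\t"), con)
  } else {
    Matrix::writeMM(Matrix::Matrix(unclass(m), sparse = TRUE), path)
    writeLines(rownames(m), file.path(dirname(path), "genes.txt"))
    writeLines(colnames(m), file.path(dirname(path), "barcodes.txt"))
  }
  invisible(path)
}

#' Read a GMT gene-set file
#'
#' One set per line: name, description, then >= 1 tab-separated member id.
#' The description field carries the category label when written by
#' [write_gmt()].
#'
#' @param path GMT file path.
#' @return a [geneset_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop(sprintf("%s: line %d has %d fields; need name, description and >= 1 member",
                 path, short[1L], lengths(fields)[short[1L]]), call. = FALSE)
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop(sprintf("%s: duplicate set name '%s'", path, nm[duplicated(nm)][1L]),
         call. = FALSE)
  sets <- stats::setNames(lapply(fields, `[`, -(1:2)), nm)
  cats <- vapply(fields, `[[`, character(1), 2L)
  cats[!nzchar(cats)] <- "custom"
  geneset_collection(sets, cats)
}

#' Write a gene-set collection as GMT
#' @param collection a [geneset_collection()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "geneset_collection"))
  lines <- vapply(names(collection$sets), function(nm)
    paste(c(nm, collection$categories[[nm]], collection$sets[[nm]]), collapse = "\t"),
    character(1))
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read column metadata from TSV
#' @param path TSV with an `id` column (plus `class_label` for bulk,
#'   `cell_type`/`subcluster`/`condition`/`donor` for cells).
#' @return a data frame.
#' @export
read_metadata <- function(path) {
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  if (is.null(df$id)) stop(sprintf("%s: metadata must have an `id` column", path),
                           call. = FALSE)
  df
}

#' Write column metadata as TSV
#' @param metadata data frame with an `id` column.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(paste(colnames(metadata), collapse = "\t"), con)
  writeLines(do.call(paste, c(lapply(metadata, as.character), sep = "\t")), con)
  invisible(path)
}

report_schema_version <- "1.0"

## Strips environments/functions and rounds nothing: reports must be
## byte-stable for identical inputs.
as_report_payload <- function(object) {
  if (inherits(object, "validation_result"))
    return(object[c("auc", "auc_ci", "roc_p", "sens", "spec", "sens_ci", "spec_ci",
                    "threshold", "n_splits", "train_fraction", "seed", "scores",
                    "roc_points")])
  if (inherits(object, "refinement_trace"))
    return(list(auc_by_size = object$auc_by_size,
                selected_signature = object$selected_signature,
                selection_rule_applied = object$selection_rule_applied,
                seed = object$seed,
                cycles = lapply(object$cycles, function(cy)
                  cy[c("cycle_index", "input_size", "max_auc", "genelist_maxAUC",
                       "left_out")])))
  if (inherits(object, "screen_report") || inherits(object, "run_manifest") ||
      inherits(object, "ground_truth"))
    return(unclass(object))
  if (is.list(object)) return(object)
  stop_field("object", "not a reportable pipeline result")
}

#' Write a pipeline result object as a versioned JSON report
#'
#' The report embeds a schema version, the object class and the seed (when the
#' object carries one); identical inputs give byte-identical files.
#'
#' @param object a pipeline result (validation result, refinement trace,
#'   screen report, run manifest, ground truth, or a plain list).
#' @param path destination `.json` file.
#' @return `path`, invisibly.
#' @export
write_report <- function(object, path) {
  if (!dir.exists(dirname(path)))
    stop(sprintf("cannot write report: no such directory '%s'", dirname(path)),
         call. = FALSE)
  payload <- as_report_payload(object)
  rep <- list(schema_version = report_schema_version,
              object_class = class(object)[1L],
              seed = payload$seed %||% NULL,
              results = payload)
  json <- jsonlite::toJSON(rep, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                           null = "null", na = "null", dataframe = "columns")
  con <- file(path, "wb"); on.exit(close(con))
  writeLines(json, con)
  invisible(path)
}

#' Read a JSON report written by [write_report()]
#' @param path report path.
#' @return the parsed report list.
#' @export
read_report <- function(path) jsonlite::read_json(path, simplifyVector = TRUE)

#' Checksum of a file's bytes (provenance)
#' @param path file path.
#' @return an md5 hex string.
#' @export
file_checksum <- function(path) digest::digest(path, algo = "md5", file = TRUE)
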