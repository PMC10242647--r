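## Core containers.  The pipeline deliberately uses light S3 wrappers around
## base matrices / data frames: every object round-trips through plain-text
## formats (TSV / MTX / GMT / JSON) and stays diff-able.

#' Expression matrix (genes x columns) with a layer tag
#'
#' A numeric matrix with unique, non-empty gene row names and column ids, plus
#' a `layer` attribute: `"counts"` for raw (non-negative) data or `"lognorm"`
#' for library-size log-normalized / array-scale data.
#'
#' @param values numeric matrix, genes in rows, samples or cells in columns.
#' @param layer `"counts"` or `"lognorm"`.
#' @param validate run the invariant checks (duplicate ids, finiteness,
#'   negative counts).
#' @return an `expr_matrix`.
#' @export
expr_matrix <- function(values, layer = c("counts", "lognorm"), validate = TRUE) {
  layer <- match.arg(layer)
  if (!is.matrix(values) || !is.numeric(values))
    stop_field("values", "must be a numeric matrix")
  if (validate) {
    rn <- rownames(values); cn <- colnames(values)
    if (is.null(rn) || is.null(cn))
      stop_field("values", "must carry gene row names and column ids")
    if (anyDuplicated(rn))
      stop_field("gene_ids", paste0("duplicate gene ids: ",
                 paste(unique(rn[duplicated(rn)]), collapse = ", ")))
    if (anyDuplicated(cn))
      stop_field("column_ids", paste0("duplicate column ids: ",
                 paste(unique(cn[duplicated(cn)]), collapse = ", ")))
    if (!all(is.finite(values)))
      stop_field("values", "all values must be finite")
    if (layer == "counts" && any(values < 0))
      stop_field("values", "counts layer must be non-negative")
  }
  structure(values, layer = layer, class = c("expr_matrix", class(values)))
}

#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod("[", drop = drop)
  if (is.matrix(out)) out <- expr_matrix(out, em_layer(x), validate = FALSE)
  out
}

#' Layer tag of an expression matrix
#' @param x an `expr_matrix`.
#' @return `"counts"` or `"lognorm"`.
#' @export
em_layer <- function(x) attr(x, "layer") %||% "counts"

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("<expr_matrix> %d genes x %d columns, layer = %s\n",
              nrow(x), ncol(x), em_layer(x)))
  invisible(x)
}

#' Named gene-set collection with category labels
#'
#' @param sets named list of character vectors (member gene ids).
#' @param categories character vector of category labels (GOBP/KEGG/... style),
#'   one per set; recycled if length 1.
#' @return a `geneset_collection`.
#' @export
geneset_collection <- function(sets, categories = "custom") {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == ""))
    stop_field("sets", "must be a named list of gene id vectors")
  if (anyDuplicated(names(sets)))
    stop_field("sets", paste0("duplicate set names: ",
               paste(unique(names(sets)[duplicated(names(sets))]), collapse = ", ")))
  if (any(lengths(sets) == 0L))
    stop_field("sets", "every set must be non-empty")
  sets <- lapply(sets, as.character)
  if (length(categories) == 1L) categories <- rep(categories, length(sets))
  if (length(categories) != length(sets))
    stop_field("categories", "must have one label per set")
  structure(list(sets = sets, categories = stats::setNames(categories, names(sets))),
            class = "geneset_collection")
}

#' @export
print.geneset_collection <- function(x, ...) {
  cat(sprintf("<geneset_collection> %d sets (%s); sizes %d-%d\n",
              length(x$sets), paste(unique(x$categories), collapse = ", "),
              min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' @export
length.geneset_collection <- function(x) length(x$sets)

#' Restrict a collection to one category
#' @param collection a `geneset_collection`.
#' @param category category label to keep.
#' @return a `geneset_collection` with only that category's sets.
#' @export
collection_subset <- function(collection, category) {
  keep <- collection$categories == category
  if (!any(keep)) stop_field("category", sprintf("no sets in category '%s'", category))
  geneset_collection(collection$sets[keep], collection$categories[keep])
}

#' Bundle an expression matrix with per-column metadata
#'
#' @param matrix an `expr_matrix`.
#' @param metadata data frame with an `id` column matching the matrix columns;
#'   bulk cohorts carry `class_label` (`"positive"`/`"negative"`), cell cohorts
#'   carry `cell_type`, `subcluster`, `condition`, `donor`.
#' @return a `cohort` list with elements `matrix` and `metadata`.
#' @export
cohort <- function(matrix, metadata) {
  if (!inherits(matrix, "expr_matrix")) stop_field("matrix", "must be an expr_matrix")
  if (!is.data.frame(metadata) || is.null(metadata$id))
    stop_field("metadata", "must be a data frame with an `id` column")
  if (!identical(as.character(metadata$id), colnames(matrix)))
    stop_field("metadata", "ids must match matrix columns in order")
  if (!is.null(metadata$class_label) &&
      !all(metadata$class_label %in% c("positive", "negative")))
    stop_field("class_label", "must be 'positive' or 'negative'")
  structure(list(matrix = matrix, metadata = metadata), class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  kind <- if (!is.null(x$metadata$class_label)) "bulk" else "cell"
  cat(sprintf("<cohort:%s> %d genes x %d columns\n", kind,
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}
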