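## Nearest-centroid classification with multiple random validation: pooled
## continuous prediction scores across stratified random splits, one ROC/AUC
## on the pooled scores, a Welch-t ROC p-value, and Wilson intervals for
## sensitivity/specificity at the max-Youden threshold.

#' Wilson score confidence interval
#'
#' @param k number of successes (0 <= k <= n).
#' @param n number of trials (> 0).
#' @param level confidence level. Default 0.95.
#' @return numeric `c(lo, hi)`.
#' @export
wilson_ci <- function(k, n, level = 0.95) {
  if (!is.numeric(n) || length(n) != 1L || n <= 0) stop_field("n", "must be > 0")
  if (!is.numeric(k) || k < 0 || k > n) stop_field("k", "must be in [0, n]")
  z <- stats::qnorm(1 - (1 - level) / 2)
  p <- k / n
  denom <- n + z^2
  center <- (k + z^2 / 2) / denom
  half <- z * sqrt(k * (n - k) / n + z^2 / 4) / denom
  c(lo = center - half, hi = center + half)
}

#' Mann-Whitney AUC of a score vector (half-credit ties)
#'
#' @param scores numeric prediction scores (higher = positive class).
#' @param positive logical, TRUE for positive-class observations.
#' @return the AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n2 <- sum(!positive)
  if (n1 == 0L || n2 == 0L) stop_field("positive", "both classes required")
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' ROC points from pooled scores
#'
#' Sweeps thresholds over the distinct score values in decreasing order,
#' grouping ties, so the trapezoidal area equals the Mann-Whitney AUC with
#' half-credit ties.  Points start at (0,0) and end at (1,1), monotone
#' non-decreasing in both coordinates.
#'
#' @inheritParams auc_mann_whitney
#' @return data frame `threshold`, `fpr`, `tpr` (first row threshold `Inf`).
#' @export
roc_points <- function(scores, positive) {
  positive <- as.logical(positive)
  n1 <- sum(positive); n2 <- sum(!positive)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- positive[ord]
  grp <- cumsum(!duplicated(s))
  tp <- cumsum(y); fp <- cumsum(!y)
  last <- !duplicated(grp, fromLast = TRUE)   # last index of each tie group
  data.frame(threshold = c(Inf, s[last]),
             fpr = c(0, fp[last] / n2),
             tpr = c(0, tp[last] / n1))
}

trapezoid_auc <- function(fpr, tpr) sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)

#' Fit a two-class nearest-centroid model
#'
#' @param train a bulk [cohort()] (metadata carries `class_label`).
#' @param features gene ids to use; all must be measured.
#' @param distance `"euclidean"` (default) or `"correlation"` (1 - Pearson).
#' @return a `centroid_model` with per-class mean expression per feature.
#' @export
fit_centroid <- function(train, features, distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  stopifnot(inherits(train, "cohort"))
  labels <- train$metadata$class_label
  if (is.null(labels)) stop_field("train", "cohort has no class labels")
  if (length(unique(labels)) != 2L)
    stop("training set must contain both classes", call. = FALSE)
  missing <- setdiff(features, rownames(train$matrix))
  if (length(missing))
    stop(sprintf("feature gene(s) not measured: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  X <- unclass(train$matrix)[features, , drop = FALSE]
  pos <- rowMeans(X[, labels == "positive", drop = FALSE])
  neg <- rowMeans(X[, labels == "negative", drop = FALSE])
  structure(list(features = features, positive = pos, negative = neg,
                 distance = distance), class = "centroid_model")
}

centroid_dist <- function(x, centroid, distance) {
  if (distance == "euclidean") sqrt(sum((x - centroid)^2))
  else {
    if (stats::sd(x) == 0 || stats::sd(centroid) == 0) return(1)
    1 - stats::cor(x, centroid)
  }
}

#' Continuous nearest-centroid prediction score
#'
#' `score = d(x, negative centroid) - d(x, positive centroid)`: positive
#' scores mean the sample sits closer to the positive class.
#'
#' @param model a [fit_centroid()] model.
#' @param x named numeric vector covering all model features.
#' @return a real score.
#' @export
predict_score <- function(model, x) {
  stopifnot(inherits(model, "centroid_model"))
  if (!all(model$features %in% names(x)))
    stop_field("x", "must cover all model features")
  v <- x[model$features]
  if (!all(is.finite(v))) stop_field("x", "non-finite input")
  centroid_dist(v, model$negative, model$distance) -
    centroid_dist(v, model$positive, model$distance)
}

## stratified train/test partitions; per-class train count is
## round(f * n_c) clamped to [1, n_c - 1] so both folds see both classes
draw_splits <- function(labels, n_splits, train_fraction, seed, max_retry = 100L) {
  classes <- unique(labels)
  idx_by <- lapply(classes, function(cl) which(labels == cl))
  n_tr <- vapply(idx_by, function(ix)
    max(1L, min(length(ix) - 1L,
                as.integer(round(train_fraction * length(ix))))), integer(1))
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_splits), function(i) {
      for (try in seq_len(max_retry)) {
        train <- sort(unlist(lapply(seq_along(idx_by), function(ci)
          sample(idx_by[[ci]], n_tr[ci])), use.names = FALSE))
        if (length(unique(labels[train])) == 2L &&
            length(unique(labels[-train])) == 2L)
          return(list(train = train, test = sort(setdiff(seq_along(labels), train))))
      }
      stop("could not draw a split with both classes in both folds", call. = FALSE)
    })
  })
}

## core of multiple_random_validation given pre-drawn splits; returns pooled
## held-out scores (one row per held-out occurrence)
mrv_pool_scores <- function(cohort_obj, features, splits, distance) {
  X <- unclass(cohort_obj$matrix)
  labels <- cohort_obj$metadata$class_label
  out <- lapply(splits, function(sp) {
    tr <- cohort_obj
    tr$matrix <- cohort_obj$matrix[, sp$train, drop = FALSE]
    tr$metadata <- cohort_obj$metadata[sp$train, , drop = FALSE]
    model <- fit_centroid(tr, features, distance)
    sc <- vapply(sp$test, function(j) predict_score(model, X[, j]), numeric(1))
    data.frame(index = sp$test, id = colnames(X)[sp$test],
               label = labels[sp$test], score = sc, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

## aggregate occurrence-level held-out scores to one pooled score per sample
## (the mean over the splits in which the sample was held out)
aggregate_per_sample <- function(occ) {
  agg <- rowsum(occ$score, occ$id, reorder = FALSE)
  cnt <- rowsum(rep(1L, nrow(occ)), occ$id, reorder = FALSE)
  ids <- rownames(agg)
  data.frame(id = ids, label = occ$label[match(ids, occ$id)],
             score = as.numeric(agg) / as.numeric(cnt),
             n_heldout = as.integer(cnt), stringsAsFactors = FALSE)
}

## summarize per-sample pooled scores into a validation_result
summarize_validation <- function(occ, n_splits, train_fraction, seed, features) {
  pooled <- aggregate_per_sample(occ)
  positive <- pooled$label == "positive"
  auc <- auc_mann_whitney(pooled$score, positive)
  roc <- roc_points(pooled$score, positive)
  n1 <- sum(positive); n2 <- sum(!positive)
  ## Hanley-McNeil binomial SE for the AUC CI
  q1 <- auc / (2 - auc); q2 <- 2 * auc^2 / (1 + auc)
  se <- sqrt((auc * (1 - auc) + (n1 - 1) * (q1 - auc^2) +
              (n2 - 1) * (q2 - auc^2)) / (n1 * n2))
  auc_ci <- c(lo = max(0, auc - 1.96 * se), hi = min(1, auc + 1.96 * se))
  roc_p <- tryCatch(
    stats::t.test(pooled$score[positive], pooled$score[!positive])$p.value,
    error = function(e) 1)  # constant scores: no evidence
  youden <- roc$tpr - roc$fpr
  best <- which.max(youden)
  thr <- roc$threshold[best]
  sens_k <- sum(pooled$score[positive] >= thr)
  spec_k <- sum(pooled$score[!positive] < thr)
  structure(list(
    scores = pooled,
    roc_points = roc, auc = auc, auc_ci = auc_ci, roc_p = roc_p,
    sens = sens_k / n1, spec = spec_k / n2,
    sens_ci = wilson_ci(sens_k, n1), spec_ci = wilson_ci(spec_k, n2),
    threshold = thr, n_splits = n_splits, train_fraction = train_fraction,
    seed = seed, features = features), class = "validation_result")
}

#' @export
print.validation_result <- function(x, ...) {
  cat(sprintf(paste0("<validation_result> AUC = %.3f (95%% CI %.3f-%.3f), ",
                     "ROC p = %.3g; sens = %.3f, spec = %.3f; %d splits\n"),
              x$auc, x$auc_ci[1], x$auc_ci[2], x$roc_p, x$sens, x$spec, x$n_splits))
  invisible(x)
}

#' Multiple random validation of a nearest-centroid classifier
#'
#' Repeats stratified random train/test partitions, fits the centroid model
#' on each training fold, scores the held-out samples, pools each sample's
#' held-out scores into one continuous prediction score (the mean over the
#' splits in which it was held out, with the count recorded), and computes a
#' single ROC/AUC over the per-sample pooled scores (Mann-Whitney ties
#' handling), a Welch's t-test ROC p-value, and sensitivity/specificity with
#' Wilson 95% intervals at the max-Youden threshold.  Samples never held out
#' (possible at very small `n_splits`) are excluded from the summary.
#'
#' @param cohort a bulk [cohort()] with both classes (each >= 2 samples).
#' @param features gene ids used by the classifier.
#' @param n_splits number of random splits. Default 200.
#' @param train_fraction training fraction per class. Default 2/3.
#' @param seed integer seed for the split stream.
#' @param distance `"euclidean"` or `"correlation"`.
#' @return a `validation_result`.
#' @export
multiple_random_validation <- function(cohort, features, n_splits = 200L,
                                       train_fraction = 2 / 3, seed = 1L,
                                       distance = c("euclidean", "correlation")) {
  distance <- match.arg(distance)
  stopifnot(inherits(cohort, "cohort"))
  if (!is_count(n_splits)) stop_field("n_splits", "must be a positive integer")
  if (!is_fraction(train_fraction)) stop_field("train_fraction", "must be in (0,1)")
  labels <- cohort$metadata$class_label
  if (min(table(labels)) < 2L || length(unique(labels)) != 2L)
    stop("both classes need >= 2 samples", call. = FALSE)
  splits <- draw_splits(labels, n_splits, train_fraction, seed)
  pooled <- mrv_pool_scores(cohort, features, splits, distance)
  summarize_validation(pooled, n_splits, train_fraction, seed, features)
}

#' Evaluate the prediction power of one gene set
#'
#' Runs [multiple_random_validation()] restricted to the set members measured
#' in the cohort; membership loss is recorded in the result's
#' `features_dropped` attribute.
#'
#' @param cohort a bulk [cohort()].
#' @param set_members gene ids of the set.
#' @param n_splits,train_fraction,seed,distance passed through.
#' @return a `validation_result`.
#' @export
evaluate_gene_set <- function(cohort, set_members, n_splits = 200L,
                              train_fraction = 2 / 3, seed = 1L,
                              distance = "euclidean") {
  measured <- intersect(set_members, rownames(cohort$matrix))
  if (length(measured) == 0L)
    stop("no set member is measured in the cohort", call. = FALSE)
  res <- multiple_random_validation(cohort, measured, n_splits, train_fraction,
                                    seed, distance)
  attr(res, "features_dropped") <- setdiff(set_members, measured)
  res
}
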