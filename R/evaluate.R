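#' Classification metrics from a confusion matrix
#'
#' Positive class is `improved`. Accuracy, sensitivity (recall on improved),
#' specificity (recall on unimproved) and F1, all in percent. A ratio whose
#' denominator is zero (e.g. specificity in a fold with no unimproved
#' samples) is returned as `NA` and excluded from fold averaging downstream.
#'
#' @param tp,fp,tn,fn Non-negative confusion counts; total > 0.
#' @return One-row tibble: `acc`, `sens`, `spec`, `f1` (percent).
#' @export
confusion_metrics <- function(tp, fp, tn, fn) {
  stopifnot(tp >= 0, fp >= 0, tn >= 0, fn >= 0)
  total <- tp + fp + tn + fn
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  tibble::tibble(
    acc = ratio(tp + tn, total),
    sens = ratio(tp, tp + fn),
    spec = ratio(tn, tn + fp),
    f1 = ratio(2 * tp, 2 * tp + fp + fn)
  )
}

split_metrics <- function(truth, pred) {
  truth <- factor(truth, levels = c("improved", "unimproved"))
  pred <- factor(pred, levels = c("improved", "unimproved"))
  confusion_metrics(
    tp = sum(truth == "improved" & pred == "improved"),
    fp = sum(truth == "unimproved" & pred == "improved"),
    tn = sum(truth == "unimproved" & pred == "unimproved"),
    fn = sum(truth == "improved" & pred == "unimproved")
  )
}

new_eval <- function(protocol, spec, per_split, seed) {
  agg <- dplyr::summarise(per_split, dplyr::across(
    c("acc", "sens", "spec", "f1"), ~ mean(.x, na.rm = TRUE)))
  structure(list(protocol = protocol, spec = spec, per_split = per_split,
                 aggregate = agg, seed = seed),
            class = "mfc_eval")
}

#' @export
print.mfc_eval <- function(x, ...) {
  cat(sprintf("<mfc_eval> protocol=%s family=%s (%d splits, seed %d)\n",
              x$protocol, x$spec$family, nrow(x$per_split), x$seed))
  print(round(x$aggregate, 2))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-split metrics of an evaluation
#'
#' @param x An `mfc_eval` object.
#' @param ... Unused.
#' @return Tibble with one row per fold or repetition.
#' @method tidy mfc_eval
#' @export
tidy.mfc_eval <- function(x, ...) x$per_split

#' One-row summary of an evaluation
#'
#' @param x An `mfc_eval` object.
#' @param ... Unused.
#' @return One-row tibble: protocol, family, mean `acc`, `sens`, `spec`,
#'   `f1` (percent, averaged over splits with undefined ratios excluded),
#'   and seed.
#' @method glance mfc_eval
#' @export
glance.mfc_eval <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(protocol = x$protocol, family = x$spec$family),
    x$aggregate,
    tibble::tibble(seed = x$seed)
  )
}

check_xy <- function(features, labels) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(labels), ncol(features) >= 1)
  labels <- factor(labels, levels = c("improved", "unimproved"))
  if (anyNA(labels)) stop("labels must be improved/unimproved", call. = FALSE)
  if (length(unique(labels)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  list(x = features, y = labels)
}

#' Stratified k-fold cross-validated evaluation
#'
#' Folds preserve the class distribution as evenly as possible (see
#' [stratified_folds()]); the model is fit on k-1 folds and tested on the
#' held-out fold; metrics are the arithmetic mean of the per-fold values,
#' with per-fold undefined ratios (zero denominators) excluded.
#'
#' @param features Numeric feature data frame (rows = patients).
#' @param labels Binary outcome (`improved`/`unimproved`).
#' @param model A [model_spec()].
#' @param k Number of folds (default 5).
#' @param seed Integer seed (fold assignment and stochastic fitters).
#' @return An `mfc_eval` object.
#' @export
stratified_cv_eval <- function(features, labels, model = model_spec("svm"),
                               k = 5L, seed = 1L) {
  d <- check_xy(features, labels)
  fold <- stratified_folds(d$y, k = k, seed = seed)
  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- fold != f
    set.seed(seed + f)
    fit <- fit_model(model, d$x[tr, , drop = FALSE], d$y[tr])
    pred <- predict_model(fit, d$x[!tr, , drop = FALSE])
    dplyr::mutate(split_metrics(d$y[!tr], pred), split = f, .before = 1)
  })
  new_eval("stratified_cv", model, per_fold, seed)
}

#' Repeated random undersampling evaluation
#'
#' Each repetition draws `per_class` samples from each class for training
#' and tests on all remaining samples; metrics are averaged over
#' repetitions. Balances the training set without synthetic samples.
#'
#' @inheritParams stratified_cv_eval
#' @param per_class Training samples drawn per class (default 3).
#' @param reps Number of repetitions (default 200).
#' @return An `mfc_eval` object.
#' @export
undersample_eval <- function(features, labels, model = model_spec("svm"),
                             per_class = 3L, reps = 200L, seed = 1L) {
  d <- check_xy(features, labels)
  counts <- table(d$y)
  if (per_class >= min(counts)) {
    stop("per_class must be smaller than the minority class", call. = FALSE)
  }
  per_rep <- purrr::map_dfr(seq_len(reps), function(r) {
    set.seed(seed + r)
    tr_idx <- unlist(lapply(levels(d$y), function(cl) {
      sample(which(d$y == cl), per_class)
    }))
    fit <- fit_model(model, d$x[tr_idx, , drop = FALSE], d$y[tr_idx])
    te <- setdiff(seq_along(d$y), tr_idx)
    pred <- predict_model(fit, d$x[te, , drop = FALSE])
    dplyr::mutate(split_metrics(d$y[te], pred), split = r, .before = 1)
  })
  new_eval("undersample", model, per_rep, seed)
}

#' SMOTE minority oversampling
#'
#' Synthetic minority samples are uniform convex combinations of a minority
#' sample and one of its `k_neighbors` nearest minority neighbours
#' (Euclidean), so every synthetic point lies on a segment between two true
#' minority points. Enough points are generated to balance the classes.
#'
#' @param features Numeric feature data frame.
#' @param labels Binary labels; the rarer class is oversampled.
#' @param k_neighbors Number of nearest minority neighbours (default 2).
#' @param seed Integer seed.
#' @return List with the augmented `features` and `labels` (originals
#'   first), and `synthetic`, the generated rows alone.
#' @export
smote_balance <- function(features, labels, k_neighbors = 2L, seed = 1L) {
  x <- as.matrix(features)
  labels <- factor(labels)
  counts <- table(droplevels(labels))
  if (length(counts) < 2) {
    stop("both classes must be present for SMOTE", call. = FALSE)
  }
  minority <- names(counts)[which.min(counts)]
  n_new <- max(counts) - min(counts)
  min_idx <- which(labels == minority)
  if (length(min_idx) <= k_neighbors) {
    stop("minority count must exceed k_neighbors", call. = FALSE)
  }
  if (n_new == 0) {
    return(list(features = as.data.frame(features), labels = labels,
                synthetic = features[0, , drop = FALSE]))
  }
  xm <- x[min_idx, , drop = FALSE]
  dm <- as.matrix(stats::dist(xm))
  diag(dm) <- Inf
  set.seed(seed)
  parents <- sample(seq_along(min_idx), n_new, replace = TRUE)
  synth <- t(vapply(parents, function(i) {
    nbrs <- order(dm[i, ])[seq_len(k_neighbors)]
    j <- nbrs[sample.int(k_neighbors, 1)]
    u <- stats::runif(1)
    xm[i, ] + u * (xm[j, ] - xm[i, ])
  }, numeric(ncol(x))))
  synth <- as.data.frame(synth)
  names(synth) <- colnames(features)
  list(
    features = rbind(as.data.frame(features), synth),
    labels = factor(c(as.character(labels), rep(minority, n_new)),
                    levels = levels(labels)),
    synthetic = synth
  )
}

#' Stratified CV with SMOTE-oversampled training folds
#'
#' Identical to [stratified_cv_eval()] except that SMOTE (with `k_neighbors`
#' minority neighbours) is applied inside each training fold only; test
#' folds are never touched, so no synthetic sample leaks into evaluation.
#'
#' @inheritParams stratified_cv_eval
#' @param k_neighbors SMOTE neighbour count (default 2).
#' @param k Number of folds (default 5).
#' @return An `mfc_eval` object.
#' @export
smote_cv_eval <- function(features, labels, model = model_spec("svm"),
                          k_neighbors = 2L, k = 5L, seed = 1L) {
  d <- check_xy(features, labels)
  fold <- stratified_folds(d$y, k = k, seed = seed)
  per_fold <- purrr::map_dfr(seq_len(k), function(f) {
    tr <- fold != f
    bal <- smote_balance(d$x[tr, , drop = FALSE], d$y[tr],
                         k_neighbors = k_neighbors, seed = seed + f)
    set.seed(seed + f)
    fit <- fit_model(model, bal$features, bal$labels)
    pred <- predict_model(fit, d$x[!tr, , drop = FALSE])
    dplyr::mutate(split_metrics(d$y[!tr], pred), split = f, .before = 1)
  })
  new_eval("smote_cv", model, per_fold, seed)
}

#' Mann-Whitney U test between outcome groups for one session
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test of a per-patient metric
#' between the improved and unimproved groups. Exact for untied samples at
#' these group sizes; with ties, the tie-corrected normal approximation is
#' used.
#'
#' @param values Numeric per-patient values for one session.
#' @param labels Binary group labels, both groups non-empty.
#' @return Two-sided p-value.
#' @export
session_group_test <- function(values, labels) {
  labels <- factor(labels, levels = c("improved", "unimproved"))
  a <- values[labels == "improved"]
  b <- values[labels == "unimproved"]
  if (length(a) == 0 || length(b) == 0) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  if (length(unique(c(a, b))) == 1) return(1)  # no rank information at all
  has_ties <- anyDuplicated(c(a, b)) > 0
  res <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = "two.sided",
                       exact = !has_ties, correct = has_ties)
  )
  unname(res$p.value)
}
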