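# Equal-frequency discretization into (at most) `bins` levels, rank-based so
# the result is invariant to strictly monotone transforms of the feature.
# Ties share a bin; a constant vector collapses to one bin.
discretize_ef <- function(x, bins = 3L) {
  r <- rank(x, ties.method = "average")
  ceiling(bins * r / length(r))
}

# Mutual information (bits) between two discrete vectors.
mutual_information <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  mi <- 0
  for (i in seq_along(pa)) {
    for (j in seq_along(pb)) {
      p <- tab[i, j]
      if (p > 0) mi <- mi + p * log2(p / (pa[i] * pb[j]))
    }
  }
  mi
}

#' mRMR feature ranking
#'
#' Greedy forward minimum-redundancy maximum-relevance ranking: the first
#' feature maximizes mutual information with the label; each subsequent pick
#' maximizes relevance minus (MID, default) or divided by (MIQ) the mean
#' mutual information with the already-ranked features. Mutual information is
#' estimated after equal-frequency 3-bin discretization of each feature
#' (rank-based, so the ranking is invariant to monotone transforms).
#'
#' @param features Data frame of numeric feature columns (>= 2 features,
#'   >= 4 samples).
#' @param labels Binary factor/vector, both classes present.
#' @param scheme `"MID"` (difference, default) or `"MIQ"` (quotient).
#' @param bins Discretization bins (default 3).
#' @return Tibble in rank order: `rank`, `feature`, `relevance`,
#'   `redundancy`, `score`.
#' @export
mrmr_rank <- function(features, labels, scheme = c("MID", "MIQ"), bins = 3L) {
  scheme <- match.arg(scheme)
  features <- as.data.frame(features)
  stopifnot(ncol(features) >= 2, nrow(features) >= 4)
  labels <- as.factor(labels)
  if (length(unique(labels)) < 2) stop("labels are constant", call. = FALSE)
  if (nrow(features) < bins) stop("fewer samples than bins", call. = FALSE)

  disc <- lapply(features, discretize_ef, bins = bins)
  rel <- vapply(disc, mutual_information, numeric(1), b = labels)
  nms <- names(features)

  ranked <- character(0)
  rows <- list()
  remaining <- nms
  while (length(remaining) > 0) {
    if (length(ranked) == 0) {
      red <- stats::setNames(rep(0, length(remaining)), remaining)
      score <- rel[remaining]
    } else {
      red <- vapply(remaining, function(f) {
        mean(vapply(ranked, function(g) {
          mutual_information(disc[[f]], disc[[g]])
        }, numeric(1)))
      }, numeric(1))
      score <- if (scheme == "MID") rel[remaining] - red
               else rel[remaining] / (red + 1e-12)
    }
    # an uninformative constant feature carries no information at all:
    # always ranked after every varying feature
    constant <- vapply(remaining, function(f) {
      length(unique(disc[[f]])) == 1
    }, logical(1))
    score[constant] <- -Inf
    # scores rounded before ordering so mathematically tied candidates are
    # resolved by relevance then name, not by floating-point noise
    ord <- order(-round(score, 10), -round(rel[remaining], 10), remaining)
    pick <- remaining[ord[1]]
    rows[[length(rows) + 1L]] <- tibble::tibble(
      feature = pick, relevance = unname(rel[pick]),
      redundancy = unname(red[pick]), score = unname(score[pick])
    )
    ranked <- c(ranked, pick)
    remaining <- setdiff(remaining, pick)
  }
  out <- dplyr::bind_rows(rows)
  dplyr::mutate(out, rank = dplyr::row_number(), .before = 1)
}

#' Stratified fold assignment
#'
#' Splits samples into `k` folds preserving the class distribution as evenly
#' as possible: per-class counts differ by at most one across folds, and
#' class remainders are dealt to the folds with the smallest running size so
#' total fold sizes stay balanced (11/4 over 5 folds gives per-fold class
#' counts (3,0), (2,1), (2,1), (2,1), (2,1)).
#'
#' @param labels Factor/vector of class labels.
#' @param k Number of folds (2 <= k <= number of samples).
#' @param seed Integer seed shuffling the within-class order.
#' @return Integer vector of fold ids (1..k), one per sample.
#' @export
stratified_folds <- function(labels, k = 5L, seed = 1L) {
  labels <- as.factor(labels)
  n <- length(labels)
  if (k < 2 || k > n) stop("k must be in [2, n]", call. = FALSE)
  fold <- integer(n)
  fold_sizes <- integer(k)
  set.seed(seed)
  # larger classes first so their remainders are placed before the smaller
  # class fills the gaps
  classes <- names(sort(table(labels), decreasing = TRUE))
  for (cl in classes) {
    idx <- sample(which(labels == cl))
    base <- length(idx) %/% k
    rem <- length(idx) %% k
    counts <- rep(base, k)
    if (rem > 0) {
      extra <- order(fold_sizes, seq_len(k))[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    pos <- 1L
    for (f in seq_len(k)) {
      if (counts[f] > 0) {
        fold[idx[pos:(pos + counts[f] - 1L)]] <- f
        pos <- pos + counts[f]
      }
      fold_sizes[f] <- fold_sizes[f] + counts[f]
    }
  }
  fold
}

#' Fold-wise mRMR rankings
#'
#' Ranks features by mRMR once per stratified fold, each time on the
#' training portion (all samples except that fold) so every ranking sees both
#' classes at the full n - n/k sample size; the per-fold half of the
#' rank-then-vote selection.
#'
#' @param features Numeric feature data frame.
#' @param labels Binary labels.
#' @param k Number of folds (5 and 3 are the protocol values).
#' @param seed Fold-assignment seed.
#' @param scheme mRMR scheme, see [mrmr_rank()].
#' @return Tibble of rankings with a `fold_id` column.
#' @export
mrmr_rank_folds <- function(features, labels, k = 5L, seed = 1L,
                            scheme = "MID") {
  fold <- stratified_folds(labels, k = k, seed = seed)
  purrr::map_dfr(seq_len(k), function(f) {
    idx <- which(fold != f)
    if (length(unique(labels[idx])) < 2 || length(idx) < 4) return(NULL)
    dplyr::mutate(mrmr_rank(features[idx, , drop = FALSE], labels[idx],
                            scheme = scheme),
                  fold_id = f, .before = 1)
  })
}

#' Majority-vote feature selection across fold rankings
#'
#' A feature is a candidate when it appears in the top-`k` of a strict
#' majority of folds. Candidates are ordered by vote count, then mean rank,
#' then name; at most `k` are selected.
#'
#' @param rankings Tibble of fold rankings (from [mrmr_rank_folds()]), with
#'   columns `fold_id`, `feature`, `rank`.
#' @param k Top-k size (default 4).
#' @return Tibble: `feature`, `votes`, `mean_rank`, `selected`.
#' @export
vote_select <- function(rankings, k = 4L) {
  stopifnot(nrow(rankings) > 0)
  feats_by_fold <- split(rankings$feature, rankings$fold_id)
  sets <- lapply(feats_by_fold, sort)
  if (length(unique(sets)) != 1) {
    stop("inconsistent feature sets across folds", call. = FALSE)
  }
  n_folds <- length(feats_by_fold)
  n_feat <- length(sets[[1]])
  if (k < 1 || k > n_feat) stop("k must be in [1, n_features]", call. = FALSE)
  tally <- rankings |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(votes = sum(.data$rank <= k),
                     mean_rank = mean(.data$rank), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$votes), .data$mean_rank, .data$feature)
  majority <- tally$votes > n_folds / 2
  selected <- majority & (cumsum(majority) <= k)
  dplyr::mutate(tally, selected = selected)
}
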