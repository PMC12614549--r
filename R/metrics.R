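#' @useDynLib mfcadhere, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang .data
NULL

check_pair <- function(x, y) {
  if (length(x) != length(y)) {
    stop(sprintf("length mismatch: %d vs %d", length(x), length(y)),
         call. = FALSE)
  }
  if (length(x) < 1) stop("empty series", call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y))) {
    stop("non-finite values", call. = FALSE)
  }
}

as_metric_vector <- function(x) {
  if (inherits(x, "processed_series")) x$values else as.numeric(x)
}

#' Normalized Euclidean distance
#'
#' Root-mean-square difference `sqrt(mean((X - Y)^2))`: bounded by 1 when
#' both inputs live in \[0, 1\], attaining it on the all-ones/all-zeros pair.
#' The alternative form `sqrt(sum((X - Y)^2)) / n` is available for
#' sensitivity analyses.
#'
#' @param x,y Equal-length numeric vectors (or `processed_series`).
#' @param form `"rms"` (default) or `"sum_over_n"`.
#' @return Scalar distance >= 0.
#' @export
euclidean_norm <- function(x, y, form = c("rms", "sum_over_n")) {
  form <- match.arg(form)
  x <- as_metric_vector(x); y <- as_metric_vector(y)
  check_pair(x, y)
  if (form == "rms") sqrt(mean((x - y)^2)) else sqrt(sum((x - y)^2)) / length(x)
}

#' Normalized Manhattan distance
#'
#' Mean absolute difference `mean(|X - Y|)`; in \[0, 1\] for \[0, 1\] inputs.
#'
#' @inheritParams euclidean_norm
#' @return Scalar distance >= 0.
#' @export
manhattan_norm <- function(x, y) {
  x <- as_metric_vector(x); y <- as_metric_vector(y)
  check_pair(x, y)
  mean(abs(x - y))
}

#' Normalized dynamic time warping distance
#'
#' Cumulative alignment cost `D(n, n)` of the recurrence
#' `D(i,j) = d(X_i, Y_j) + min(D(i-1,j), D(i,j-1), D(i-1,j-1))` with local
#' cost `|X_i - Y_j|` (or squared), divided by the common padded length `n`.
#'
#' @inheritParams euclidean_norm
#' @param local_cost `"abs"` (default) or `"sq"`.
#' @return Scalar distance >= 0; 0 iff a zero-cost warping exists.
#' @export
dtw_norm <- function(x, y, local_cost = c("abs", "sq")) {
  local_cost <- match.arg(local_cost)
  x <- as_metric_vector(x); y <- as_metric_vector(y)
  check_pair(x, y)
  dtw_cost(x, y, squared = (local_cost == "sq")) / length(x)
}

#' Lagged normalized cross-correlation
#'
#' Pearson correlation of `X[1..(n-k)]` with `Y[(1+k)..n]` — the correlation
#' of X with Y advanced by `k` strides.
#'
#' @param x,y Equal-length numeric vectors.
#' @param k Lag, `0 <= k <= n - 2`.
#' @return Correlation in \[-1, 1\].
#' @export
xcr_lag <- function(x, y, k) {
  n <- length(x)
  stopifnot(k >= 0, k <= n - 2)
  xs <- x[seq_len(n - k)]
  ys <- y[seq(1 + k, n)]
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0) {
    stop("zero variance on lagged support", call. = FALSE)
  }
  stats::cor(xs, ys)
}

#' Cross-correlation distance
#'
#' Dissimilarity combining the immediate and delayed correlation structure:
#' `XCRD = (1 - XCR(0)^2) / sum_k (1 - XCR(k)^2)` over lags `k = 1..max_lag`.
#' Perfect zero-lag (anti)correlation gives 0; a series decorrelated from the
#' reference at lag 0 but still correlated at positive lags scores high.
#' One-sided in the lag, hence not symmetric in (x, y).
#'
#' @inheritParams euclidean_norm
#' @param max_lag Maximum lag (default 20); must be < series length.
#' @return Scalar distance >= 0.
#' @export
xcrd <- function(x, y, max_lag = 20L) {
  x <- as_metric_vector(x); y <- as_metric_vector(y)
  check_pair(x, y)
  n <- length(x)
  if (max_lag < 1 || max_lag >= n - 1) {
    stop("max_lag must satisfy 1 <= max_lag <= n - 2", call. = FALSE)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  r0 <- xcr_lag(x, y, 0)
  denom <- sum(vapply(seq_len(max_lag),
                      function(k) 1 - xcr_lag(x, y, k)^2, numeric(1)))
  if (denom == 0) {
    stop("all lagged correlations are +/-1; XCRD undefined", call. = FALSE)
  }
  (1 - r0^2) / denom
}

#' Pearson correlation coefficient
#'
#' @inheritParams euclidean_norm
#' @return Correlation in \[-1, 1\].
#' @export
corrcoef <- function(x, y) {
  x <- as_metric_vector(x); y <- as_metric_vector(y)
  check_pair(x, y)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero-variance input", call. = FALSE)
  }
  stats::cor(x, y)
}

#' Cosine similarity
#'
#' @inheritParams euclidean_norm
#' @return `sum(XY) / (||X|| ||Y||)`, in \[-1, 1\].
#' @export
cosine_sim <- function(x, y) {
  x <- as_metric_vector(x); y <- as_metric_vector(y)
  check_pair(x, y)
  nx <- sqrt(sum(x^2)); ny <- sqrt(sum(y^2))
  if (nx == 0 || ny == 0) stop("zero-norm input", call. = FALSE)
  # clamp rounding spill so downstream [-1,1] contracts hold exactly
  max(-1, min(1, sum(x * y) / (nx * ny)))
}

#' Six-metric similarity profile of one baseline/session pair
#'
#' Both raw series are amplitude-normalized then zero-padded to the common
#' length; all six metrics are computed on the padded vectors (pad zeros
#' included), matching the preprocessing order of the analysis.
#'
#' @param baseline,session Raw MFC series (mm).
#' @param config An [mfc_config()].
#' @return One-row tibble: `ed`, `md`, `dtw`, `xcrd`, `cc`, `cs`.
#' @export
similarity_profile <- function(baseline, session, config = mfc_config()) {
  b <- process_series(baseline, config)$values
  s <- process_series(session, config)$values
  tibble::tibble(
    ed = euclidean_norm(b, s, form = config$ed_form),
    md = manhattan_norm(b, s),
    dtw = dtw_norm(b, s, local_cost = config$dtw_local_cost),
    xcrd = xcrd(b, s, max_lag = config$max_lag),
    cc = corrcoef(b, s),
    cs = cosine_sim(b, s)
  )
}

#' Baseline-vs-session similarity profiles for a cohort
#'
#' The classifier features: for each patient and each requested training
#' session, the six metrics between the patient's baseline and that session.
#' Sessions lost to data collection are skipped.
#'
#' @param cohort An `mfc_cohort`.
#' @param sessions Training sessions to profile (default `"train_2"`, the
#'   prediction setting: outcome from the second training session).
#' @param config An [mfc_config()].
#' @return Tibble: `patient_id`, `session`, `ed`, `md`, `dtw`, `xcrd`,
#'   `cc`, `cs`, `label`.
#' @export
similarity_profiles <- function(cohort, sessions = "train_2",
                                config = mfc_config()) {
  stopifnot(inherits(cohort, "mfc_cohort"))
  stopifnot(all(sessions %in% training_sessions()))
  labels <- cohort_labels(cohort)
  rows <- purrr::map_dfr(labels$patient_id, function(p) {
    base <- cohort_series(cohort, p, "baseline")
    purrr::map_dfr(sessions, function(s) {
      ser <- cohort_series(cohort, p, s)
      if (is.null(ser)) return(NULL)
      dplyr::bind_cols(
        tibble::tibble(patient_id = p, session = s),
        similarity_profile(base, ser, config)
      )
    })
  })
  dplyr::left_join(rows, labels, by = "patient_id")
}
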