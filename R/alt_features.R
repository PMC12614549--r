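# Daubechies-6 (12-tap, 6 vanishing moments) orthonormal analysis filters,
# standard published values.
DB6_LO <- c(-0.0010773010853084796, 0.004777257510945511,
            0.0005538422011614961, -0.03158203931748603,
            0.027522865530305727, 0.09750160558732304,
            -0.12976686756726194, -0.22626469396543983,
            0.31525035170919763, 0.7511339080210954,
            0.49462389039845306, 0.11154074335010947)
DB6_HI <- rev(DB6_LO) * rep_len(c(1, -1), length(DB6_LO))

#' Descriptive statistics of an MFC series
#'
#' @param values Raw MFC series (mm), length >= 2.
#' @return One-row tibble: `mean`, `median`, `sd`, `q1`, `q3`, `iqr` (mm).
#'   Quartiles use linear interpolation (type 7); SD has denominator n - 1.
#' @export
stat_features <- function(values) {
  if (length(values) < 2) stop("series must have length >= 2", call. = FALSE)
  q <- stats::quantile(values, c(0.25, 0.75), names = FALSE, type = 7)
  tibble::tibble(
    mean = mean(values), median = stats::median(values),
    sd = stats::sd(values), q1 = q[1], q3 = q[2], iqr = q[2] - q[1]
  )
}

#' Percentage-index (PI) series
#'
#' Percent change between successive MFC values relative to the previous one:
#' `PI_i = 100 (v_{i+1} - v_i) / v_i`. Defined on the raw millimetre series
#' (percent change of a normalized series is ill-defined at 0), which must be
#' strictly positive.
#'
#' @param values Raw MFC series (mm), all > 0.
#' @return Numeric vector of length `length(values) - 1`, in percent.
#' @export
pi_series <- function(values) {
  if (any(values <= 0)) {
    stop("PI requires strictly positive MFC values", call. = FALSE)
  }
  n <- length(values)
  if (n < 2) stop("series must have length >= 2", call. = FALSE)
  100 * diff(values) / values[-n]
}

#' Tone and entropy of a PI series
#'
#' Tone is the mean percentage change (positive: the series tends upward).
#' Entropy is the Shannon entropy (bits) of the PI distribution over a
#' fixed-width histogram (default 1 percentage point per bin, empty bins
#' excluded): 0 when every change falls in one bin, 1 bit for an even split
#' over two bins.
#'
#' @param pi_values PI series from [pi_series()].
#' @param bin_width Histogram bin width in percentage points (default 1).
#' @return One-row tibble: `tone` (%), `entropy` (bits).
#' @export
tone_entropy <- function(pi_values, bin_width = 1) {
  if (length(pi_values) < 1) stop("empty PI series", call. = FALSE)
  stopifnot(bin_width > 0)
  bins <- floor(pi_values / bin_width)
  p <- table(bins) / length(bins)
  tibble::tibble(tone = mean(pi_values), entropy = -sum(p * log2(p)))
}

# One periodized analysis step: circular convolution with the analysis pair,
# downsample by 2. Odd-length inputs are wrapped to even length first.
dwt_step <- function(x) {
  n <- length(x)
  if (n %% 2 == 1) {
    x <- c(x, x[1])
    n <- n + 1
  }
  L <- length(DB6_LO)
  idx <- outer(seq(2, n, by = 2), seq_len(L) - 1L, `-`) %% n + 1L
  xm <- matrix(x[idx], nrow = n / 2)
  list(approx = as.numeric(xm %*% rev(DB6_LO)),
       detail = as.numeric(xm %*% rev(DB6_HI)))
}

#' Wavelet multiscale variance features
#'
#' Periodized Daubechies-6 decomposition over 8 levels; per level the log2 of
#' the mean squared detail coefficient (energy about zero, so the deepest
#' levels with one or two coefficients stay defined), plus the least-squares
#' slope of that profile across levels. White noise gives a near-flat
#' profile; long-range-correlated series a sloped one.
#'
#' @param values Processed (normalized, padded) series, typically length 200.
#' @param levels Number of decomposition levels (default 8).
#' @return One-row tibble: `level_log_var_1..levels` and
#'   `multiscale_exponent`.
#' @export
wavelet_variance_features <- function(values, levels = 8L) {
  values <- as_metric_vector(values)
  if (all(values == 0)) stop("zero series: wavelet variances undefined",
                             call. = FALSE)
  stopifnot(levels >= 1)
  logvar <- numeric(levels)
  approx <- values
  for (lev in seq_len(levels)) {
    st <- dwt_step(approx)
    e <- mean(st$detail^2)
    if (e == 0) stop("zero detail energy at level ", lev, call. = FALSE)
    logvar[lev] <- log2(e)
    approx <- st$approx
  }
  slope <- unname(stats::coef(stats::lm(logvar ~ seq_len(levels)))[2])
  out <- tibble::as_tibble(as.list(stats::setNames(
    logvar, paste0("level_log_var_", seq_len(levels)))))
  out$multiscale_exponent <- slope
  out
}

#' Similarity between baseline and session feature vectors
#'
#' Reuses the series metrics on derived feature vectors (wavelet or
#' statistical/tone-entropy), as in the comparison of feature spaces: CC, CS
#' and XCRD between the baseline's and the session's feature vector. For
#' short vectors XCRD uses `max_lag = length - 2` capped at the configured
#' maximum.
#'
#' @param f_base,f_train Equal-length numeric feature vectors (length >= 3
#'   for `cc`/`xcrd`).
#' @param metrics Subset of `c("cc", "cs", "xcrd")`.
#' @param max_lag Optional cap on the XCRD lag.
#' @return One-row tibble with the requested metrics.
#' @export
feature_space_similarity <- function(f_base, f_train,
                                     metrics = c("cc", "cs", "xcrd"),
                                     max_lag = 20L) {
  metrics <- match.arg(metrics, several.ok = TRUE)
  check_pair(f_base, f_train)
  out <- list()
  if ("cc" %in% metrics) out$cc <- corrcoef(f_base, f_train)
  if ("cs" %in% metrics) out$cs <- cosine_sim(f_base, f_train)
  if ("xcrd" %in% metrics) {
    lag <- min(max_lag, length(f_base) - 2L)
    out$xcrd <- xcrd(f_base, f_train, max_lag = lag)
  }
  tibble::as_tibble(out)
}

#' Alternative feature-space profiles for a cohort
#'
#' For each patient, computes the baseline and session feature vectors in the
#' requested space and their CC/CS/XCRD similarity, giving the comparison
#' feature sets evaluated against the raw-series profiles.
#'
#' @param cohort An `mfc_cohort`.
#' @param space `"wavelet"` (8-level Daubechies-6 log-variances + slope) or
#'   `"stat_te"` (mean, median, SD, quartiles, IQR, tone, entropy).
#' @param sessions Training sessions (default `"train_2"`).
#' @param config An [mfc_config()].
#' @return Tibble: `patient_id`, `session`, `cc`, `cs`, `xcrd`, `label`.
#' @export
alt_feature_profiles <- function(cohort, space = c("wavelet", "stat_te"),
                                 sessions = "train_2",
                                 config = mfc_config()) {
  space <- match.arg(space)
  stopifnot(inherits(cohort, "mfc_cohort"))
  labels <- cohort_labels(cohort)
  fvec <- function(values) {
    if (space == "wavelet") {
      unlist(wavelet_variance_features(process_series(values, config)),
             use.names = FALSE)
    } else {
      c(unlist(stat_features(values), use.names = FALSE),
        unlist(tone_entropy(pi_series(values),
                            bin_width = config$entropy_bin_width),
               use.names = FALSE))
    }
  }
  rows <- purrr::map_dfr(labels$patient_id, function(p) {
    fb <- fvec(cohort_series(cohort, p, "baseline"))
    purrr::map_dfr(sessions, function(s) {
      ser <- cohort_series(cohort, p, s)
      if (is.null(ser)) return(NULL)
      dplyr::bind_cols(tibble::tibble(patient_id = p, session = s),
                       feature_space_similarity(fb, fvec(ser),
                                                max_lag = config$max_lag))
    })
  })
  dplyr::left_join(rows, labels, by = "patient_id")
}
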