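#' Analysis configuration
#'
#' Bundles the preprocessing and metric options shared across the pipeline.
#'
#' @param pad_length Fixed length every series is brought to before metric
#'   computation (default 200 strides).
#' @param normalization Amplitude normalization: `"minmax"` rescales each
#'   series to \[0, 1\] (default); `"zscore"` centres and scales instead.
#' @param truncate_policy What to do with series longer than `pad_length`:
#'   `"head"` keeps the first `pad_length` strides (default), `"error"` stops.
#' @param max_lag Maximum lag of the cross-correlation distance (default 20).
#' @param dtw_local_cost Local cost of the DTW recurrence: `"abs"` (default)
#'   or `"sq"`.
#' @param ed_form Normalized Euclidean distance form: `"rms"`
#'   sqrt(sum(d^2)/n) (default; attains 1 on the extremal \[0,1\] pair) or
#'   `"sum_over_n"` sqrt(sum(d^2))/n.
#' @param raam_measures Dissimilarity measures entering GPS_MFC (default
#'   cosine-similarity distance and cross-correlation distance).
#' @param entropy_bin_width Histogram bin width (percentage points) for the
#'   entropy of the percentage-index series (default 1).
#' @return A list of class `mfc_config`.
#' @export
mfc_config <- function(pad_length = 200L,
                       normalization = c("minmax", "zscore"),
                       truncate_policy = c("head", "error"),
                       max_lag = 20L,
                       dtw_local_cost = c("abs", "sq"),
                       ed_form = c("rms", "sum_over_n"),
                       raam_measures = c("one_minus_cs", "xcrd"),
                       entropy_bin_width = 1) {
  stopifnot(pad_length >= 1, max_lag >= 1, entropy_bin_width > 0)
  cfg <- list(
    pad_length = as.integer(pad_length),
    normalization = match.arg(normalization),
    truncate_policy = match.arg(truncate_policy),
    max_lag = as.integer(max_lag),
    dtw_local_cost = match.arg(dtw_local_cost),
    ed_form = match.arg(ed_form),
    raam_measures = raam_measures,
    entropy_bin_width = entropy_bin_width
  )
  class(cfg) <- "mfc_config"
  cfg
}

#' Amplitude-normalize a stride series
#'
#' Min-max rescaling to \[0, 1\]: `(v - min) / (max - min)`. A constant
#' series maps to all 0.5 by convention (its location carries no shape
#' information after normalization). The `zscore` alternative centres to mean
#' 0, SD 1.
#'
#' @param values Numeric stride series (length >= 2, finite).
#' @param method `"minmax"` (default) or `"zscore"`.
#' @return Unitless numeric vector of the same length.
#' @export
amplitude_normalize <- function(values, method = c("minmax", "zscore")) {
  method <- match.arg(method)
  if (length(values) < 2) stop("series must have length >= 2", call. = FALSE)
  if (any(!is.finite(values))) stop("non-finite values in series",
                                    call. = FALSE)
  if (method == "minmax") {
    rng <- range(values)
    if (rng[1] == rng[2]) return(rep(0.5, length(values)))
    (values - rng[1]) / (rng[2] - rng[1])
  } else {
    s <- stats::sd(values)
    if (s == 0) return(rep(0, length(values)))
    (values - mean(values)) / s
  }
}

#' Zero-pad (or truncate) a normalized series to fixed length
#'
#' Shorter series get trailing zeros; longer series are truncated to their
#' first `L` strides (early-session behaviour is kept). The original stride
#' count is recorded so downstream code can tell real entries from padding.
#'
#' @param values Numeric vector (already amplitude-normalized).
#' @param L Target length (default 200).
#' @param truncate_policy `"head"` or `"error"` for over-long input.
#' @return A list with `values` (length `L`), `orig_length`, and `L`,
#'   of class `processed_series`.
#' @export
zero_pad <- function(values, L = 200L, truncate_policy = c("head", "error")) {
  truncate_policy <- match.arg(truncate_policy)
  if (L < 1) stop("L must be >= 1", call. = FALSE)
  n <- length(values)
  if (n < 1) stop("empty series", call. = FALSE)
  if (n > L) {
    if (truncate_policy == "error") {
      stop(sprintf("series length %d exceeds pad length %d", n, L),
           call. = FALSE)
    }
    values <- values[seq_len(L)]
    n <- L
  }
  out <- c(values, rep(0, L - n))
  structure(list(values = out, orig_length = n, L = as.integer(L)),
            class = "processed_series")
}

#' Normalize and pad a raw MFC series
#'
#' @param values Raw MFC series (mm).
#' @param config An [mfc_config()].
#' @return A `processed_series` (see [zero_pad()]).
#' @export
process_series <- function(values, config = mfc_config()) {
  zero_pad(amplitude_normalize(values, config$normalization),
           L = config$pad_length, truncate_policy = config$truncate_policy)
}

#' Biofeedback target range from a baseline series
#'
#' The display band the patient is asked to lift the swing foot into:
#' centred at baseline mean + SD, half a baseline SD to either side, i.e.
#' lower = mean + 0.5 SD, upper = mean + 1.5 SD. Sample SD (denominator
#' n - 1).
#'
#' @param baseline Raw baseline MFC series (mm), length >= 2.
#' @return Tibble with one row: `lower`, `center`, `upper` (mm).
#' @export
target_range <- function(baseline) {
  if (length(baseline) < 2) stop("baseline must have length >= 2",
                                 call. = FALSE)
  m <- mean(baseline)
  s <- stats::sd(baseline)
  if (s == 0) stop("baseline SD is zero; target range undefined",
                   call. = FALSE)
  tibble::tibble(lower = m + 0.5 * s, center = m + s, upper = m + 1.5 * s)
}
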