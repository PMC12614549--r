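#' Synthetic cohort configuration
#'
#' Generative parameters for the fixture cohort: per-patient baseline AR(1)
#' stride series and 10 training sessions whose deviation-from-baseline is
#' governed by a per-session adherence level in \[0, 1\]. Adherence 0
#' reproduces the baseline process (sharing its standardized deviation
#' pattern stride-for-stride); adherence 1 centres the series on the
#' biofeedback target (baseline mean + SD), shrinks its SD by `sd_shrink`,
#' and fully decorrelates it from the baseline pattern.
#'
#' Defaults mirror the study conditions: 11 improved / 4 unimproved
#' patients, 200 strides per session, and data loss at a 5% session rate.
#'
#' @param n_improved,n_unimproved Class sizes (default 11 / 4).
#' @param strides Strides per session (default 200).
#' @param baseline_mean,baseline_sd Baseline MFC mean and SD in mm
#'   (default 20, 4).
#' @param ar_coef Lag-1 autocorrelation of the stride series (default 0.3).
#' @param adherence_improved Length-10 adherence schedule for improved
#'   patients (default linear ramp 0.3 to 0.9).
#' @param adherence_unimproved Range of the uniform per-session adherence of
#'   unimproved patients (default \[0, 0.15\]).
#' @param sd_shrink Fractional SD reduction at full adherence (default 0.5).
#' @param missing_rate Probability a training session is lost (default 0.05).
#' @param patient_jitter Relative SD of per-patient jitter on baseline mean
#'   and SD (default 0.1).
#' @param shape_jitter Half-width of the log-uniform exponent of the
#'   per-session amplitude-shape warp (default 0.5; 0 disables). Each
#'   session's marginal distribution is warped by a random monotone power
#'   map, emulating the day-to-day amplitude-distribution differences that
#'   motivate amplitude normalization: min-max rescaling removes linear
#'   amplitude effects but not shape changes, so pointwise distances (ED,
#'   MD) pick up adherence-independent variation while rank/alignment
#'   metrics (CC, CS, XCRD) are barely affected — as observed on real gait
#'   series.
#' @param seed Integer seed; the generator is fully deterministic given
#'   (config, seed).
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_improved = 11L, n_unimproved = 4L,
                             strides = 200L,
                             baseline_mean = 20, baseline_sd = 4,
                             ar_coef = 0.3,
                             adherence_improved = seq(0.3, 0.9,
                                                      length.out = 10),
                             adherence_unimproved = c(0, 0.15),
                             sd_shrink = 0.5, missing_rate = 0.05,
                             patient_jitter = 0.1, shape_jitter = 0.5,
                             seed = 1L) {
  stopifnot(n_improved >= 0, n_unimproved >= 0, strides >= 2,
            baseline_sd > 0, ar_coef >= 0, ar_coef < 1,
            length(adherence_improved) == 10,
            all(adherence_improved >= 0 & adherence_improved <= 1),
            length(adherence_unimproved) == 2,
            all(adherence_unimproved >= 0 & adherence_unimproved <= 1),
            sd_shrink >= 0, sd_shrink <= 1,
            missing_rate >= 0, missing_rate < 1, shape_jitter >= 0)
  structure(as.list(environment()), class = "synthetic_config")
}

# Monotone power warp of the series' amplitude distribution: values are
# mapped through ((v - min) / range)^gamma with gamma log-uniform around 1.
# Rank order (hence correlation structure) is preserved; the marginal shape
# is not. Draws one gamma from the current RNG stream.
shape_warp <- function(v, jitter) {
  if (jitter == 0) return(v)
  g <- exp(stats::runif(1, -jitter, jitter))
  r <- range(v)
  if (r[1] == r[2]) return(v)
  r[1] + (r[2] - r[1]) * ((v - r[1]) / (r[2] - r[1]))^g
}

# Stationary AR(1) deviations with unit marginal SD.
ar1_unit <- function(n, phi) {
  innov_sd <- sqrt(1 - phi^2)
  z <- numeric(n)
  z[1] <- stats::rnorm(1)
  for (t in 2:n) z[t] <- phi * z[t - 1] + innov_sd * stats::rnorm(1)
  z
}

#' Simulate one baseline MFC series
#'
#' AR(1) about the baseline mean, innovation variance scaled so the
#' stationary SD equals `baseline_sd`; values floored at 0.5 mm (clearance
#' heights are positive). Uses the current RNG state: seed management
#' belongs to the caller (see [simulate_cohort()]).
#'
#' @param config A [synthetic_config()].
#' @param mu,sigma Optional per-patient overrides of mean/SD (mm).
#' @return List: `values` (mm) and `z`, the standardized deviation series
#'   that training sessions of the same patient partially share.
#' @export
simulate_baseline <- function(config, mu = config$baseline_mean,
                              sigma = config$baseline_sd) {
  z <- ar1_unit(config$strides, config$ar_coef)
  v <- shape_warp(pmax(mu + sigma * z, 0.5), config$shape_jitter)
  list(values = v, z = z)
}

#' Simulate one training-session MFC series
#'
#' Adherence `alpha` moves the session mean toward the biofeedback target
#' centre (baseline mean + SD), shrinks the SD by `sd_shrink * alpha`, and
#' decorrelates the stride pattern from the baseline: the session's
#' standardized deviations are `(1 - alpha) * z_base` blended with
#' independent AR(1) innovations at weight `sqrt(1 - (1 - alpha)^2)`, so the
#' expected correlation with the baseline pattern is `1 - alpha`. A
#' non-adherent session therefore stays baseline-like while a fully adherent
#' one is an independent series around the target.
#'
#' @param baseline A baseline as returned by [simulate_baseline()].
#' @param alpha Adherence in \[0, 1\].
#' @param config A [synthetic_config()].
#' @param mu,sigma The patient's baseline mean/SD (mm).
#' @return Numeric MFC series (mm).
#' @export
simulate_session <- function(baseline, alpha, config,
                             mu = config$baseline_mean,
                             sigma = config$baseline_sd) {
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]", call. = FALSE)
  rho <- 1 - alpha
  z_new <- ar1_unit(config$strides, config$ar_coef)
  z <- rho * baseline$z + sqrt(1 - rho^2) * z_new
  mu_a <- mu + alpha * sigma          # target centre is mu + sigma
  sigma_a <- sigma * (1 - config$sd_shrink * alpha)
  shape_warp(pmax(mu_a + sigma_a * z, 0.5), config$shape_jitter)
}

#' Simulate a labelled synthetic cohort
#'
#' Generates `n_improved + n_unimproved` patients, each with a baseline and
#' 10 training sessions. Improved patients follow the adherence ramp;
#' unimproved patients draw a low adherence level per session from the
#' configured uniform range. Per-patient baseline mean and SD are jittered.
#' Training sessions (never baselines) are then dropped independently at
#' `missing_rate`.
#'
#' @param config A [synthetic_config()].
#' @return An `mfc_cohort` tibble.
#' @export
simulate_cohort <- function(config = synthetic_config()) {
  n <- config$n_improved + config$n_unimproved
  if (n < 2) stop("need at least 2 patients", call. = FALSE)
  set.seed(config$seed)
  labels <- c(rep("improved", config$n_improved),
              rep("unimproved", config$n_unimproved))
  ids <- sprintf("P%02d", seq_len(n))
  rows <- purrr::map_dfr(seq_len(n), function(i) {
    mu <- config$baseline_mean *
      (1 + config$patient_jitter * stats::rnorm(1))
    sigma <- config$baseline_sd *
      max(1 + config$patient_jitter * stats::rnorm(1), 0.2)
    base <- simulate_baseline(config, mu, sigma)
    alphas <- if (labels[i] == "improved") config$adherence_improved else {
      stats::runif(10, config$adherence_unimproved[1],
                   config$adherence_unimproved[2])
    }
    series <- c(
      list(baseline = base$values),
      stats::setNames(
        lapply(alphas, simulate_session, baseline = base, config = config,
               mu = mu, sigma = sigma),
        training_sessions())
    )
    purrr::imap_dfr(series, function(v, s) {
      tibble::tibble(patient_id = ids[i], session = s,
                     stride_index = seq_along(v) - 1L, mfc_mm = v,
                     label = labels[i])
    })
  })
  cohort <- as_mfc_cohort(rows)
  inject_missing(cohort, config$missing_rate, seed = config$seed + 1L)
}

#' Drop training sessions at random (data loss)
#'
#' Each training session is independently removed with probability `rate`;
#' baselines are never removed (the analysis is undefined without them).
#'
#' @param cohort An `mfc_cohort`.
#' @param rate Loss probability in \[0, 1).
#' @param seed Integer seed.
#' @return The cohort minus the lost sessions.
#' @export
inject_missing <- function(cohort, rate, seed = 1L) {
  stopifnot(inherits(cohort, "mfc_cohort"))
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)", call. = FALSE)
  if (rate == 0) return(cohort)
  sessions <- dplyr::distinct(tibble::as_tibble(cohort), .data$patient_id,
                              .data$session)
  sessions <- sessions[sessions$session != "baseline", ]
  set.seed(seed)
  drop <- sessions[stats::runif(nrow(sessions)) < rate, ]
  if (nrow(drop) == 0) return(cohort)
  keep <- !(paste(cohort$patient_id, cohort$session) %in%
              paste(drop$patient_id, drop$session))
  out <- cohort[keep, ]
  class(out) <- unique(c("mfc_cohort", class(out)))
  out
}
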