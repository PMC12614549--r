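raam_measure_names <- function() {
  c("ed", "md", "dtw", "xcrd", "one_minus_cc", "one_minus_cs")
}

#' Convert a similarity value to a distance
#'
#' The mixing rule for GPS_MFC: when any distance measure is in the set,
#' similarities (CC, CS) enter as `1 - value`. CC and CS live in \[-1, 1\],
#' so the result lies in \[0, 2\]; values above 1 (negative correlation) are
#' kept, not clamped.
#'
#' @param value Similarity in \[-1, 1\].
#' @param kind `"cc"` or `"cs"` (informational).
#' @return `1 - value`.
#' @export
similarity_to_distance <- function(value, kind = c("cc", "cs")) {
  kind <- match.arg(kind)
  if (any(value < -1 | value > 1)) {
    stop(kind, " must lie in [-1, 1]", call. = FALSE)
  }
  1 - value
}

#' MFC Variation Score (MVS)
#'
#' One baseline-referenced dissimilarity of a processed session series:
#' the named measure applied to (session, baseline reference). Similarities
#' are converted via `1 - value` so every measure reads as a distance
#' (0 = identical to baseline).
#'
#' @param session Processed session vector (normalized, padded).
#' @param reference Processed baseline vector of the same patient.
#' @param measure One of `"ed"`, `"md"`, `"dtw"`, `"xcrd"`,
#'   `"one_minus_cc"`, `"one_minus_cs"`.
#' @param config An [mfc_config()] (metric options).
#' @return Scalar dissimilarity.
#' @export
mvs <- function(session, reference, measure, config = mfc_config()) {
  measure <- match.arg(measure, raam_measure_names())
  s <- as_metric_vector(session)
  r <- as_metric_vector(reference)
  switch(measure,
    ed = euclidean_norm(s, r, form = config$ed_form),
    md = manhattan_norm(s, r),
    dtw = dtw_norm(s, r, local_cost = config$dtw_local_cost),
    xcrd = xcrd(s, r, max_lag = config$max_lag),
    one_minus_cc = similarity_to_distance(corrcoef(s, r), "cc"),
    one_minus_cs = similarity_to_distance(cosine_sim(s, r), "cs")
  )
}

#' GPS_MFC of one session
#'
#' Root-mean-square of the MFC Variation Scores over the chosen dissimilarity
#' measures: `sqrt(mean(MVS_m^2))`. Zero iff the session equals its baseline
#' under every chosen measure; monotone non-decreasing in each |MVS|.
#'
#' @inheritParams mvs
#' @param measures Character vector of measures (default from `config`,
#'   normally `one_minus_cs` and `xcrd`).
#' @return Scalar GPS_MFC >= 0.
#' @export
gps_mfc <- function(session, reference, measures = NULL,
                    config = mfc_config()) {
  if (is.null(measures)) measures <- config$raam_measures
  if (length(measures) < 1) stop("empty measure list", call. = FALSE)
  v <- vapply(measures, function(m) mvs(session, reference, m, config),
              numeric(1))
  sqrt(mean(v^2))
}

#' Per-patient GPS_MFC trajectories over the training sessions
#'
#' For each patient and each of the 10 training sessions, the GPS_MFC of
#' that session against the patient's processed baseline. Sessions lost to
#' data collection get `available = FALSE` and `gps = NA`.
#'
#' @param cohort An `mfc_cohort`.
#' @param measures Dissimilarity measures (default from `config`).
#' @param config An [mfc_config()].
#' @return Tibble of class `gps_trajectory`: `patient_id`, `session`,
#'   `session_no` (1..10), `gps`, `available`, `label`.
#' @export
gps_trajectories <- function(cohort, measures = NULL,
                             config = mfc_config()) {
  stopifnot(inherits(cohort, "mfc_cohort"))
  if (is.null(measures)) measures <- config$raam_measures
  labels <- cohort_labels(cohort)
  out <- purrr::map_dfr(labels$patient_id, function(p) {
    ref <- process_series(cohort_series(cohort, p, "baseline"), config)
    purrr::map_dfr(seq_len(10), function(i) {
      s <- cohort_series(cohort, p, paste0("train_", i))
      gps <- if (is.null(s)) NA_real_ else {
        gps_mfc(process_series(s, config), ref, measures, config)
      }
      tibble::tibble(patient_id = p, session = paste0("train_", i),
                     session_no = i, gps = gps, available = !is.null(s))
    })
  })
  out <- dplyr::left_join(out, labels, by = "patient_id")
  class(out) <- c("gps_trajectory", class(out))
  out
}

#' Session-to-session GPS_MFC variation
#'
#' The 9 inter-session differences `gps[i + 1] - gps[i]` per patient. With
#' dissimilarity measures, positive values signal improved adherence (the
#' session moved further from baseline). Intervals touching a lost session
#' are reported as 0 with `zeroed_by_missing = TRUE`, so plots carry the
#' zero convention while statistics can exclude those intervals.
#'
#' @param trajectories A `gps_trajectory` tibble ([gps_trajectories()]).
#' @return Tibble: `patient_id`, `interval` (1..9), `delta`,
#'   `zeroed_by_missing`, `label`.
#' @export
delta_gps <- function(trajectories) {
  stopifnot(inherits(trajectories, "gps_trajectory") ||
              all(c("patient_id", "session_no", "gps", "available") %in%
                    names(trajectories)))
  trajectories |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$session_no)
      if (nrow(df) != 10) stop("trajectory must cover 10 sessions",
                               call. = FALSE)
      ok <- df$available[-1] & df$available[-10]
      delta <- ifelse(ok, df$gps[-1] - df$gps[-10], 0)
      out <- tibble::tibble(interval = 1:9, delta = delta,
                            zeroed_by_missing = !ok)
      if ("label" %in% names(df)) out$label <- df$label[seq_len(9)]
      out
    }) |>
    dplyr::ungroup()
}

#' Mean GPS_MFC over available sessions
#'
#' @param trajectories A `gps_trajectory` tibble.
#' @return Tibble: `patient_id`, `mean_gps` (mean over available sessions
#'   only), `n_available`, `label`.
#' @export
mean_gps <- function(trajectories) {
  trajectories |>
    dplyr::group_by(.data$patient_id, .data$label) |>
    dplyr::summarise(
      mean_gps = {
        g <- .data$gps[.data$available]
        if (length(g) == 0) stop("no available sessions", call. = FALSE)
        mean(g)
      },
      n_available = sum(.data$available), .groups = "drop"
    ) |>
    dplyr::select("patient_id", "mean_gps", "n_available", "label")
}

#' Correlation of early GPS_MFC with the full-course mean
#'
#' Pearson correlation across patients between the GPS_MFC of the second
#' training session and the mean GPS_MFC over all available sessions — how
#' well early adherence anticipates whole-course adherence.
#'
#' @param trajectories A `gps_trajectory` tibble.
#' @param session_no Early session to correlate (default 2).
#' @return List: `r` (Pearson correlation), `n` (patients with that session
#'   available).
#' @export
cohort_gps_correlation <- function(trajectories, session_no = 2L) {
  m <- mean_gps(trajectories)
  s <- trajectories[trajectories$session_no == session_no &
                      trajectories$available, c("patient_id", "gps")]
  joined <- dplyr::inner_join(m, s, by = "patient_id")
  if (nrow(joined) < 3) stop("need >= 3 patients", call. = FALSE)
  list(r = corrcoef(joined$gps, joined$mean_gps), n = nrow(joined))
}
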