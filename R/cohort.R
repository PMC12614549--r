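#' Session labels of the training protocol
#'
#' The protocol fixes one baseline walking session followed by ten biofeedback
#' training sessions. Session labels form a closed set; anything else in an
#' input file is an error rather than silently kept.
#'
#' @return Character vector `c("baseline", "train_1", ..., "train_10")`.
#' @export
mfc_sessions <- function() {
  c("baseline", paste0("train_", 1:10))
}

training_sessions <- function() paste0("train_", 1:10)

#' Build an MFC cohort from a long stride table
#'
#' An MFC cohort is a long (tidy) tibble with one row per stride:
#' `patient_id`, `session`, `stride_index`, `mfc_mm` (minimum foot clearance
#' in millimetres) and a per-patient binary outcome `label`
#' (`improved`/`unimproved`). Sessions that were lost to technical failure are
#' simply absent; a baseline series is mandatory for every patient because it
#' is the reference all downstream metrics use.
#'
#' @param data Data frame with columns `patient_id`, `session`,
#'   `stride_index`, `mfc_mm`, `label`.
#' @return A tibble of class `mfc_cohort`, sorted by patient, session,
#'   stride index.
#' @export
as_mfc_cohort <- function(data) {
  required <- c("patient_id", "session", "stride_index", "mfc_mm", "label")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop("cohort table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  data <- tibble::as_tibble(data[required])

  bad_session <- setdiff(unique(as.character(data$session)), mfc_sessions())
  if (length(bad_session) > 0) {
    stop("unknown session label(s): ", paste(bad_session, collapse = ", "),
         "; expected baseline, train_1..train_10", call. = FALSE)
  }
  if (!is.numeric(data$mfc_mm) || anyNA(data$mfc_mm) ||
      any(!is.finite(data$mfc_mm))) {
    stop("non-numeric or non-finite mfc_mm values", call. = FALSE)
  }
  bad_label <- setdiff(unique(as.character(data$label)),
                       c("improved", "unimproved"))
  if (length(bad_label) > 0) {
    stop("labels must be improved/unimproved; found: ",
         paste(bad_label, collapse = ", "), call. = FALSE)
  }

  data <- dplyr::mutate(
    data,
    patient_id = as.character(.data$patient_id),
    session = factor(as.character(.data$session), levels = mfc_sessions()),
    stride_index = as.integer(.data$stride_index),
    label = factor(as.character(.data$label),
                   levels = c("improved", "unimproved"))
  )

  dup <- dplyr::count(data, .data$patient_id, .data$session,
                      .data$stride_index)
  if (any(dup$n > 1)) {
    d <- dup[dup$n > 1, ][1, ]
    stop(sprintf("duplicate (patient, session, stride_index): (%s, %s, %d)",
                 d$patient_id, as.character(d$session), d$stride_index),
         call. = FALSE)
  }

  lab <- dplyr::distinct(data, .data$patient_id, .data$label)
  conflicted <- lab$patient_id[duplicated(lab$patient_id)]
  if (length(conflicted) > 0) {
    stop("conflicting labels for patient(s): ",
         paste(unique(conflicted), collapse = ", "), call. = FALSE)
  }

  no_baseline <- setdiff(
    unique(data$patient_id),
    unique(data$patient_id[data$session == "baseline"])
  )
  if (length(no_baseline) > 0) {
    stop("missing baseline for patient(s): ",
         paste(no_baseline, collapse = ", "), call. = FALSE)
  }

  n_strides <- dplyr::count(data, .data$patient_id, .data$session)
  if (any(n_strides$n < 2)) {
    s <- n_strides[n_strides$n < 2, ][1, ]
    stop(sprintf("series (%s, %s) has fewer than 2 strides",
                 s$patient_id, as.character(s$session)), call. = FALSE)
  }

  data <- dplyr::arrange(data, .data$patient_id, .data$session,
                         .data$stride_index)
  class(data) <- c("mfc_cohort", class(data))
  data
}

#' Read an MFC cohort from CSV
#'
#' @param path Path to a CSV with header
#'   `patient_id,session,stride_index,mfc_mm,label`.
#' @return An `mfc_cohort` tibble (see [as_mfc_cohort()]).
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           patient_id = readr::col_character(),
                           session = readr::col_character(),
                           stride_index = readr::col_integer(),
                           mfc_mm = readr::col_double(),
                           label = readr::col_character()
                         ))
  if (any(dim(readr::problems(raw)) > 0) && nrow(readr::problems(raw)) > 0) {
    stop("malformed cohort CSV (non-numeric mfc_mm or stride_index?): ",
         path, call. = FALSE)
  }
  as_mfc_cohort(raw)
}

#' Write an MFC cohort to CSV
#'
#' @param cohort An `mfc_cohort` tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(inherits(cohort, "mfc_cohort"))
  out <- dplyr::mutate(cohort,
                       session = as.character(.data$session),
                       label = as.character(.data$label))
  readr::write_csv(out, path)
  invisible(path)
}

#' Write a results table to CSV
#'
#' Generic writer for the tabular outputs of the pipeline (feature profiles,
#' evaluation rows, GPS trajectories). Floats are serialized with full
#' precision (readr default, >= 6 significant digits).
#'
#' @param table Data frame of results sharing one header.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results <- function(table, path) {
  stopifnot(is.data.frame(table))
  out <- dplyr::mutate(table, dplyr::across(dplyr::where(is.factor),
                                            as.character))
  readr::write_csv(out, path)
  invisible(path)
}

#' Extract one stride series from a cohort
#'
#' @param cohort An `mfc_cohort`.
#' @param patient Patient identifier.
#' @param session Session label.
#' @return Numeric vector of MFC heights (mm) in stride order, or `NULL` if
#'   the session is absent (data loss).
#' @export
cohort_series <- function(cohort, patient, session) {
  rows <- cohort[cohort$patient_id == patient &
                   as.character(cohort$session) == session, ]
  if (nrow(rows) == 0) return(NULL)
  rows$mfc_mm[order(rows$stride_index)]
}

#' Per-patient outcome labels
#'
#' @param cohort An `mfc_cohort`.
#' @return Tibble with one row per patient: `patient_id`, `label`.
#' @export
cohort_labels <- function(cohort) {
  dplyr::distinct(tibble::as_tibble(cohort), .data$patient_id, .data$label)
}
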