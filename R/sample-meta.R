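TIMEPOINTS <- c("T1", "T2", "TS")
RCB_LEVELS <- c("RCB0", "RCB_I", "RCB_II", "RCB_III", "undetermined")

#' Map residual cancer burden class to the response grouping
#'
#' The two-group coding used throughout outcome analyses: RCB 0/I denotes
#' response (no or minimal residual tumor), RCB II/III nonresponse (moderate
#' to extensive residual disease). Undetermined RCB maps to `NA`.
#'
#' @param rcb Character or factor of RCB classes. Accepted spellings per
#'   class: `"RCB0"`/`"0"`, `"RCB_I"`/`"I"`, `"RCB_II"`/`"II"`,
#'   `"RCB_III"`/`"III"`, `"undetermined"` (or `NA`).
#' @return Factor with levels `responder`, `nonresponder` (and `NA`).
#' @examples
#' rcb_to_group(c("0", "I", "II", "III", "undetermined"))
#' @export
rcb_to_group <- function(rcb) {
  std <- normalize_rcb(rcb)
  out <- dplyr::case_match(
    std,
    c("RCB0", "RCB_I") ~ "responder",
    c("RCB_II", "RCB_III") ~ "nonresponder",
    .default = NA_character_
  )
  factor(out, levels = c("responder", "nonresponder"))
}

normalize_rcb <- function(rcb) {
  x <- toupper(trimws(as.character(rcb)))
  std <- dplyr::case_match(
    x,
    c("RCB0", "RCB_0", "0") ~ "RCB0",
    c("RCB_I", "RCBI", "I", "1") ~ "RCB_I",
    c("RCB_II", "RCBII", "II", "2") ~ "RCB_II",
    c("RCB_III", "RCBIII", "III", "3") ~ "RCB_III",
    c("UNDETERMINED", "NA", "") ~ "undetermined",
    .default = NA_character_
  )
  std[is.na(x)] <- "undetermined"
  bad <- unique(x[is.na(std)])
  if (length(bad) > 0) {
    abort(sprintf("Unknown RCB value(s): %s", paste(bad, collapse = ", ")))
  }
  factor(std, levels = RCB_LEVELS)
}

#' Construct the per-sample annotation sheet
#'
#' One row per array: which patient, which biopsy time point (T1 pretreatment,
#' T2 24-96 h after the first chemotherapy dose, TS at surgery), which print
#' batch, plus the clinical annotations the outcome analyses need. The
#' response grouping `rcb_group` is always (re)derived from `rcb`.
#'
#' @param x Data frame with columns `sample_id`, `patient_id`, `timepoint`,
#'   `batch`; optional `rcb`, `hr_status`, `rfs_time` (months), `rfs_event`
#'   (0 censored / 1 recurrence).
#' @return A tibble of class `serial_meta`.
#' @export
sample_meta <- function(x) {
  x <- as_tibble(x)
  req <- c("sample_id", "patient_id", "timepoint", "batch")
  miss <- setdiff(req, names(x))
  if (length(miss) > 0) {
    abort(sprintf("Sample sheet lacks required column(s): %s", paste(miss, collapse = ", ")))
  }
  x$sample_id <- as.character(x$sample_id)
  x$patient_id <- as.character(x$patient_id)
  check_no_duplicates(x$sample_id, "sample ids")
  tp <- as.character(x$timepoint)
  bad_tp <- unique(tp[!tp %in% TIMEPOINTS])
  if (length(bad_tp) > 0) {
    abort(sprintf("Unknown timepoint(s): %s (must be one of %s)",
                  paste(bad_tp, collapse = ", "), paste(TIMEPOINTS, collapse = ", ")))
  }
  x$timepoint <- factor(tp, levels = TIMEPOINTS)
  key <- paste(x$patient_id, tp)
  check_no_duplicates(key, "(patient_id, timepoint) pairs")
  x$batch <- factor(as.character(x$batch))

  if (!"rcb" %in% names(x)) x$rcb <- NA_character_
  x$rcb <- normalize_rcb(x$rcb)
  x$rcb_group <- rcb_to_group(x$rcb)

  if ("hr_status" %in% names(x)) {
    hr <- tolower(as.character(x$hr_status))
    ok <- hr %in% c("positive", "negative") | is.na(hr)
    if (!all(ok)) abort("hr_status must be 'positive', 'negative' or NA.")
    x$hr_status <- factor(hr, levels = c("negative", "positive"))
  } else {
    x$hr_status <- factor(NA_character_, levels = c("negative", "positive"))
  }

  has_time <- "rfs_time" %in% names(x)
  has_event <- "rfs_event" %in% names(x)
  if (has_event && !has_time) abort("rfs_event present without rfs_time.")
  if (!has_time) x$rfs_time <- NA_real_
  if (!has_event) x$rfs_event <- NA_integer_
  x$rfs_time <- as.numeric(x$rfs_time)
  x$rfs_event <- as.integer(x$rfs_event)
  if (any(!is.na(x$rfs_event) & !x$rfs_event %in% c(0L, 1L))) {
    abort("rfs_event must be 0 (censored) or 1 (recurrence).")
  }
  if (any(!is.na(x$rfs_time) & x$rfs_time < 0)) abort("rfs_time must be nonnegative.")
  if (any(!is.na(x$rfs_event) & x$rfs_event == 1L &
          (is.na(x$rfs_time) | x$rfs_time <= 0))) {
    abort("rfs_event = 1 requires rfs_time > 0.")
  }
  x <- dplyr::relocate(x, "sample_id", "patient_id", "timepoint", "batch",
                       "rcb", "rcb_group", "hr_status", "rfs_time", "rfs_event")
  structure(x, class = c("serial_meta", class(tibble())))
}

#' Read / write the sample sheet as TSV
#'
#' @param path File path.
#' @return `read_sample_meta()` returns a `serial_meta` tibble;
#'   `write_sample_meta()` returns `x` invisibly.
#' @export
read_sample_meta <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                         na = c("NA", ""), progress = FALSE, name_repair = "minimal")
  sample_meta(raw)
}

#' @rdname read_sample_meta
#' @param x Sample sheet to write.
#' @export
write_sample_meta <- function(x, path) {
  readr::write_tsv(as_tibble(x), path, na = "NA", quote = "none", progress = FALSE)
  invisible(x)
}

# meta rows for samples present in an expression table, in column order
meta_for_expr <- function(expr, meta) {
  ids <- names(expr)[-1]
  missing_ids <- setdiff(ids, meta$sample_id)
  if (length(missing_ids) > 0) {
    abort(sprintf("Samples absent from sample sheet: %s",
                  paste(head(missing_ids, 5), collapse = ", ")))
  }
  meta[match(ids, meta$sample_id), , drop = FALSE]
}
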