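#' Read and write trial data as CSV tables
#'
#' A trial is stored as two UTF-8 CSV tables with header rows and '.'
#' decimals: a long-format longitudinal table `longitudinal.csv` with columns
#' `subject_id, subgroup, arm, time_years, biomarker`, and a survival table
#' `survival.csv` with columns
#' `subject_id, subgroup, arm, recruit_years, time_years, event`.
#' `read_trial_csv()` returns a `trial_snapshot` ready for fitting (observed
#' times are taken as given; no further administrative censoring is applied).
#'
#' @param snapshot a `trial_snapshot` to write.
#' @param dir directory holding / receiving `longitudinal.csv` and
#'   `survival.csv`.
#' @param analysis_index analysis label to attach on read.
#' @return `read_trial_csv()` returns a `trial_snapshot`; `write_trial_csv()`
#'   returns `dir` invisibly.
#' @export
write_trial_csv <- function(snapshot, dir) {
  stopifnot(inherits(snapshot, "trial_snapshot"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  su <- snapshot$subjects
  surv <- tibble::tibble(
    subject_id = su$subject_id, subgroup = su$subgroup, arm = su$arm,
    recruit_years = su$recruit_years, time_years = su$time_years,
    event = su$event)
  me <- snapshot$measurements
  key <- match(me$subject_id, su$subject_id)
  long <- tibble::tibble(
    subject_id = me$subject_id, subgroup = su$subgroup[key],
    arm = su$arm[key], time_years = me$time_years, biomarker = me$biomarker)
  readr::write_csv(long, file.path(dir, "longitudinal.csv"))
  readr::write_csv(surv, file.path(dir, "survival.csv"))
  invisible(dir)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(dir, analysis_index = 1L) {
  long <- readr::read_csv(file.path(dir, "longitudinal.csv"),
                          show_col_types = FALSE)
  surv <- readr::read_csv(file.path(dir, "survival.csv"),
                          show_col_types = FALSE)
  need_l <- c("subject_id", "subgroup", "arm", "time_years", "biomarker")
  need_s <- c("subject_id", "subgroup", "arm", "recruit_years", "time_years",
              "event")
  if (!all(need_l %in% names(long))) {
    stop("longitudinal.csv must have columns ", paste(need_l, collapse = ", "),
         call. = FALSE)
  }
  if (!all(need_s %in% names(surv))) {
    stop("survival.csv must have columns ", paste(need_s, collapse = ", "),
         call. = FALSE)
  }
  surv <- dplyr::arrange(surv, .data$subject_id)
  su <- tibble::tibble(
    subject_id = surv$subject_id, subgroup = as.integer(surv$subgroup),
    arm = as.integer(surv$arm), recruit_years = surv$recruit_years,
    b0 = NA_real_, b1 = NA_real_,
    latent_event_years = NA_real_, ltfu_years = NA_real_,
    time_years = surv$time_years, event = as.integer(surv$event))
  me <- tibble::tibble(subject_id = long$subject_id,
                       time_years = long$time_years,
                       biomarker = long$biomarker)
  keep <- me$time_years <= su$time_years[match(me$subject_id, su$subject_id)] + 1e-12
  if (!all(keep)) {
    warning(sum(!keep), " measurement(s) post-date the observed time and were dropped",
            call. = FALSE)
    me <- me[keep, ]
  }
  structure(list(subjects = su, measurements = me,
                 analysis = as.integer(analysis_index),
                 calendar_time = max(su$recruit_years + su$time_years),
                 tau = max(su$time_years), params = NULL),
            class = "trial_snapshot")
}
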