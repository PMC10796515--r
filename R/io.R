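#' Read patient GTV records and dose schedules from CSV
#'
#' The patient file must have columns `patient_id`, `time_days`, `gtv_cm3`
#' (optionally `necrosis_cm3`); the schedule file `patient_id`,
#' `dose_time_days` and optionally `dose_gy` (metadata only -- all fractions
#' are assumed biologically equivalent by the model). Volumes are normalised
#' to fold change of each patient's first scan; the raw initial volume in
#' cm^3 is retained as metadata.
#'
#' @param path Path to the patient CSV.
#' @param schedule_path Optional path to the schedule CSV, joined by
#'   `patient_id`.
#' @return A named list of [observation_set()] objects.
#' @export
read_patients <- function(path, schedule_path = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "time_days", "gtv_cm3")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("patient file is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  sched <- NULL
  if (!is.null(schedule_path)) {
    sched <- utils::read.csv(schedule_path, stringsAsFactors = FALSE)
    if (!all(c("patient_id", "dose_time_days") %in% names(sched)))
      stop("schedule file needs columns patient_id, dose_time_days",
           call. = FALSE)
  }
  out <- list()
  for (id in unique(df$patient_id)) {
    rows <- df[df$patient_id == id, , drop = FALSE]
    if (is.unsorted(rows$time_days))
      stop("times not sorted for patient ", id, " (row ",
           rownames(rows)[which(diff(rows$time_days) < 0)[1] + 1], ")",
           call. = FALSE)
    if (any(rows$gtv_cm3 <= 0))
      stop("nonpositive GTV for patient ", id, " (row ",
           rownames(rows)[which(rows$gtv_cm3 <= 0)[1]], ")", call. = FALSE)
    v0 <- rows$gtv_cm3[1]
    n_obs <- NULL
    if ("necrosis_cm3" %in% names(rows) && any(!is.na(rows$necrosis_cm3)))
      n_obs <- rows$necrosis_cm3 / v0
    dt <- if (!is.null(sched))
      sort(sched$dose_time_days[sched$patient_id == id]) else numeric(0)
    out[[as.character(id)]] <- observation_set(
      rows$time_days, rows$gtv_cm3 / v0, dt, n_obs,
      patient_id = as.character(id), initial_cm3 = v0)
  }
  out
}

#' Write a cohort (real or synthetic) to the CSV schema
#'
#' Writes `patients.csv` and `schedules.csv` in the schema read by
#' [read_patients()], plus -- for synthetic cohorts -- `manifest.json`
#' recording seeds, noise parameters and each patient's true parameters and
#' class.
#'
#' @param cohort A named list of [observation_set()] or
#'   `rt_synth_patient` objects.
#' @param dir Output directory (created if needed).
#' @param initial_cm3 Initial volume used to de-normalise fold changes when
#'   the record has no stored raw volume (default 1: volumes written in
#'   fold-change units).
#' @param seed Optional cohort-level seed recorded in the manifest.
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir, initial_cm3 = 1, seed = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pat <- list(); sch <- list(); man <- list()
  for (id in names(cohort)) {
    x <- cohort[[id]]
    obs <- if (inherits(x, "rt_synth_patient")) x$obs else x
    v0 <- if (is.finite(obs$initial_cm3)) obs$initial_cm3 else initial_cm3
    pat[[id]] <- data.frame(patient_id = id, time_days = obs$times,
                            gtv_cm3 = obs$v_obs * v0)
    if (!is.null(obs$n_obs))
      pat[[id]]$necrosis_cm3 <- obs$n_obs * v0
    if (length(obs$dose_times))
      sch[[id]] <- data.frame(patient_id = id,
                              dose_time_days = obs$dose_times,
                              dose_gy = 2)
    if (inherits(x, "rt_synth_patient"))
      man[[id]] <- list(seed = x$seed, theta = as.list(x$theta),
                        class = as.character(x$class),
                        alpha1 = x$noise$alpha1, alpha2 = x$noise$alpha2)
  }
  utils::write.csv(do.call(rbind, pat), file.path(dir, "patients.csv"),
                   row.names = FALSE)
  if (length(sch))
    utils::write.csv(do.call(rbind, sch), file.path(dir, "schedules.csv"),
                     row.names = FALSE)
  if (length(man))
    jsonlite::write_json(list(cohort_seed = seed, patients = man),
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
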