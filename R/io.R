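#' Read and write cohort CSV files
#'
#' The cohort CSV dialect is long format with a header and columns
#' `patient_id`, `state` (`+1` relapse / `-1` remission), `start_week`
#' (0-based) and `duration_weeks` (integer `>= 1`); each patient's
#' episodes are contiguous, alternating rows. `read_cohort_csv()` and
#' `write_cohort_csv()` are exact inverses.
#'
#' @param path file path.
#' @param require_onset enforce that every course starts with a relapse.
#' @return `read_cohort_csv()`: a named list of [patient_course()] objects.
#'   `write_cohort_csv()`: the path, invisibly.
#' @examples
#' coh <- list(patient_course("p1", c(1, -1, -1, 1)))
#' f <- tempfile(fileext = ".csv")
#' write_cohort_csv(coh, f)
#' identical(read_cohort_csv(f)$p1$series, coh[[1]]$series)
#' @export
read_cohort_csv <- function(path, require_onset = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- tryCatch(read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(patient_id = "character")),
                 error = function(e) stop("cannot parse '", path, "': ",
                                          conditionMessage(e)))
  need <- c("patient_id", "state", "start_week", "duration_weeks")
  if (nrow(df) == 0L) stop("empty cohort file: ", path)
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols))
    stop("missing column(s) in '", path, "': ",
         paste(missing_cols, collapse = ", "))
  bad <- which(!df$state %in% c(1, -1))
  if (length(bad))
    stop(sprintf("unknown state code '%s' at data line %d of '%s' (expected +1 or -1)",
                 df$state[bad[1]], bad[1] + 1L, path))
  bad <- which(!is.finite(df$duration_weeks) | df$duration_weeks < 1 |
                 df$duration_weeks != floor(df$duration_weeks))
  if (length(bad))
    stop(sprintf("invalid duration_weeks at data line %d of '%s' (integer >= 1 required)",
                 bad[1] + 1L, path))
  ids <- rle(df$patient_id)$values
  if (anyDuplicated(ids))
    stop("duplicate patient_id '", ids[duplicated(ids)][1],
         "': each patient's episodes must form one contiguous block")
  cohort <- lapply(split(df, factor(df$patient_id, levels = ids)),
                   function(block) {
    ep <- data.frame(
      state = ifelse(block$state == 1, "relapse", "remission"),
      start_week = block$start_week,
      duration_weeks = as.integer(block$duration_weeks))
    series_from_episodes(ep, patient_id = block$patient_id[1],
                         require_onset = require_onset)
  })
  cohort[ids]
}

#' @rdname read_cohort_csv
#' @param cohort list of [patient_course()] objects.
#' @export
write_cohort_csv <- function(cohort, path) {
  if (inherits(cohort, "patient_course")) cohort <- list(cohort)
  stopifnot(length(cohort) > 0,
            all(vapply(cohort, inherits, logical(1), "patient_course")))
  rows <- lapply(cohort, function(p) {
    ep <- episodes_from_series(p)
    data.frame(patient_id = p$patient_id,
               state = ifelse(ep$state == "relapse", 1L, -1L),
               start_week = ep$start_week,
               duration_weeks = ep$duration_weeks)
  })
  write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialise a cohort report to JSON
#'
#' Writes the per-patient inferences, pooled statistics, histograms and
#' provenance of an [analyze_cohort()] report as pretty-printed JSON.
#'
#' @param report a `"cohort_report"`.
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "cohort_report"))
  stripped <- unclass(report)
  stripped$patients <- lapply(report$patients, unclass)
  stripped$pooled <- unclass(report$pooled)
  jsonlite::write_json(stripped, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
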