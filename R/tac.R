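#' Time-activity curve
#'
#' A time-ordered series of activity measurements for one subject and one
#' compartment (blood, a named organ, tumor, or the whole body). The value
#' unit is one of:
#' \describe{
#'   \item{`pid_per_g`}{percent of injected dose per gram of tissue (%ID/g)}
#'   \item{`pid_per_ml`}{percent of injected dose per mL (%ID/mL), the blood
#'     concentration form}
#'   \item{`pid`}{percent of injected dose in the whole compartment (%ID)}
#'   \item{`fia`}{fraction of injected activity (= %ID/100)}
#'   \item{`fia_per_ml`}{fraction of injected activity per mL}
#' }
#'
#' @param time numeric vector of sampling times in hours, strictly increasing,
#'   all `>= 0`.
#' @param value numeric vector of measurements, same length as `time`.
#'   Negative values are tolerated (background subtraction of faint regions
#'   can undershoot) but raise a classed warning.
#' @param unit one of `"pid_per_g"`, `"pid_per_ml"`, `"pid"`, `"fia"`,
#'   `"fia_per_ml"`.
#' @param subject_id,compartment identifying labels.
#' @return an object of class `"tac"`.
#' @export
#' @examples
#' tac(c(0, 24, 48), c(35, 20, 12), "pid_per_g", "m1", "blood")
tac <- function(time, value, unit, subject_id = "s1", compartment = "blood") {
  unit <- match.arg(unit, c("pid_per_g", "pid_per_ml", "pid", "fia", "fia_per_ml"))
  time <- as.numeric(time)
  value <- as.numeric(value)
  if (length(time) != length(value)) {
    md_stop("time and value must have equal length", "mirdose_invalid_input")
  }
  if (length(time) == 0L || anyNA(time) || anyNA(value)) {
    md_stop("time/value must be non-empty and free of NA", "mirdose_invalid_input")
  }
  if (any(time < 0)) md_stop("times must be >= 0", "mirdose_invalid_input")
  if (any(diff(time) <= 0)) {
    md_stop("times must be strictly increasing", "mirdose_invalid_input")
  }
  if (any(value < 0)) {
    md_warn(sprintf("tac '%s/%s' contains %d negative value(s); retained un-clamped",
                    subject_id, compartment, sum(value < 0)),
            "mirdose_negative_value")
  }
  structure(
    list(subject_id = subject_id, compartment = compartment,
         unit = unit, time = time, value = value),
    class = "tac"
  )
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("<tac> %s / %s [%s], %d samples over %g-%g h\n",
              x$subject_id, x$compartment, x$unit, length(x$time),
              min(x$time), max(x$time)))
  invisible(x)
}

#' @export
as.data.frame.tac <- function(x, ...) {
  data.frame(subject_id = x$subject_id, compartment = x$compartment,
             unit = x$unit, time_h = x$time, value = x$value,
             stringsAsFactors = FALSE)
}

#' @export
length.tac <- function(x) length(x$time)

is_tac <- function(x) inherits(x, "tac")

# replace values, keeping metadata (no re-warning for unchanged negatives)
tac_update <- function(x, value, unit = x$unit) {
  x$value <- as.numeric(value)
  x$unit <- unit
  x
}

#' Write time-activity curves to CSV
#'
#' Columns: `subject_id, compartment, unit, time_h, value`.
#'
#' @param tacs a `tac` or list of `tac` objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tac <- function(tacs, path) {
  if (is_tac(tacs)) tacs <- list(tacs)
  df <- do.call(rbind, lapply(tacs, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read time-activity curves from CSV
#'
#' Inverse of [write_tac()]: one `tac` per (subject_id, compartment) pair.
#'
#' @param path CSV path with columns `subject_id, compartment, unit, time_h,
#'   value`.
#' @return named list of `tac` objects, names `subject_id.compartment`.
#' @export
read_tac <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "compartment", "unit", "time_h", "value")
  if (!all(need %in% names(df))) {
    md_stop(paste0("tac csv must have columns: ", paste(need, collapse = ", ")),
            "mirdose_invalid_input")
  }
  parts <- split(df, list(df$subject_id, df$compartment), drop = TRUE)
  lapply(parts, function(p) {
    p <- p[order(p$time_h), ]
    tac(p$time_h, p$value, unit = p$unit[1],
        subject_id = p$subject_id[1], compartment = p$compartment[1])
  })
}
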