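#' Counting standard for a gamma-counter study
#'
#' The counting standard is a diluted aliquot of the administered solution
#' counted alongside the tissue samples; it anchors sample counts to the
#' administered activity without requiring an absolute calibration of the
#' counter.
#'
#' @param counts counts per minute measured for the standard aliquot (> 0).
#' @param volume_counted volume of the aliquot actually counted, mL (> 0).
#' @param dilution_factor dilution applied to the administered solution before
#'   counting (>= 1).
#' @param administered_volume volume of solution injected into the subject,
#'   mL (> 0).
#' @return an object of class `"counting_standard"`.
#' @export
counting_standard <- function(counts, volume_counted, dilution_factor = 1,
                              administered_volume = volume_counted) {
  if (!is.finite(counts) || counts <= 0) {
    md_stop("standard counts must be > 0", "mirdose_invalid_input")
  }
  if (!is.finite(volume_counted) || volume_counted <= 0 ||
      !is.finite(administered_volume) || administered_volume <= 0) {
    md_stop("volumes must be > 0", "mirdose_invalid_input")
  }
  if (!is.finite(dilution_factor) || dilution_factor < 1) {
    md_stop("dilution factor must be >= 1", "mirdose_invalid_input")
  }
  structure(list(counts = counts, volume_counted = volume_counted,
                 dilution_factor = dilution_factor,
                 administered_volume = administered_volume),
            class = "counting_standard")
}

#' Administered activity from a counting standard
#'
#' Administered activity (cpm) = standard counts x dilution factor x
#' administered volume / counted volume.
#'
#' @param std a [counting_standard()].
#' @return administered activity in cpm.
#' @export
#' @examples
#' administered_activity(counting_standard(1000, 1, 100, 2)) # 200000
administered_activity <- function(std) {
  stopifnot(inherits(std, "counting_standard"))
  std$counts * std$dilution_factor * std$administered_volume / std$volume_counted
}

#' Percent injected dose per mL (or per gram)
#'
#' %ID/mL = (sample cpm / sample mL) / administered activity (cpm) x 100.
#' Exactly the same arithmetic yields %ID/g when `amount` is a mass in
#' grams; no tissue density is ever assumed.
#'
#' @param counts sample counts (cpm), vectorized; `>= 0`.
#' @param amount sample volume (mL) or mass (g), `> 0`, recycled against
#'   `counts`.
#' @param std the study's [counting_standard()].
#' @return %ID per mL (or per g), same length as `counts`.
#' @export
percent_id_per_ml <- function(counts, amount, std) {
  if (any(!is.finite(amount)) || any(amount <= 0)) {
    md_stop("sample amount must be > 0", "mirdose_invalid_input")
  }
  if (any(counts < 0)) md_stop("sample counts must be >= 0", "mirdose_invalid_input")
  aa <- administered_activity(std)
  if (!is.finite(aa) || aa <= 0) {
    md_stop("administered activity is not positive; counting standard invalid",
            "mirdose_invalid_standard")
  }
  (counts / amount) / aa * 100
}

#' Pooled background counts-per-pixel
#'
#' Pools counts and pixel areas over all matching background regions of a
#' view: CPP = sum(counts) / sum(pixels). Pooling (rather than averaging
#' per-region ratios) makes the estimate invariant to how the same pixels are
#' partitioned into regions.
#'
#' @param rois data frame of ROI records with columns `roi_label`, `count`,
#'   `size_px`, and optionally `view` and `time_h` used for filtering.
#' @param label background label to pool, e.g. `"background_corner"` or
#'   `"body_background"`.
#' @param view,time_h optional filters (exact match).
#' @return counts per pixel (scalar).
#' @export
background_cpp <- function(rois, label, view = NULL, time_h = NULL) {
  sel <- rois$roi_label == label
  if (!is.null(view)) sel <- sel & rois$view == view
  if (!is.null(time_h)) sel <- sel & rois$time_h == time_h
  sub <- rois[sel, , drop = FALSE]
  if (nrow(sub) == 0L) {
    md_stop(sprintf("no '%s' ROI found%s%s", label,
                    if (is.null(view)) "" else paste0(" in view ", view),
                    if (is.null(time_h)) "" else paste0(" at t=", time_h, " h")),
            "mirdose_missing_background")
  }
  if (any(sub$size_px <= 0)) md_stop("ROI size must be > 0 px", "mirdose_invalid_input")
  sum(sub$count) / sum(sub$size_px)
}

#' Background-subtracted ROI count
#'
#' net = raw ROI count - CPP x ROI size. The raw difference is returned:
#' negative nets (faint regions at late timepoints) are kept so that
#' whole-body-minus-organs arithmetic downstream stays unbiased, but they
#' trigger a classed warning.
#'
#' @param count raw ROI counts (vectorized).
#' @param size_px ROI size in pixels.
#' @param cpp background counts per pixel (`>= 0`).
#' @return net counts (may be negative).
#' @export
net_roi_count <- function(count, size_px, cpp) {
  if (any(cpp < 0)) md_stop("cpp must be >= 0", "mirdose_invalid_input")
  net <- count - cpp * size_px
  if (any(net < 0)) {
    md_warn(sprintf("%d ROI net count(s) are negative after background subtraction",
                    sum(net < 0)), "mirdose_negative_net")
  }
  net
}

.planar_bg_labels <- c("background_corner", "body_background", "calibration_source")
.plain_bg_users <- c("whole_body", "calibration_source")

#' Conjugate-view planar quantification
#'
#' Converts a two-view (anterior/posterior) planar ROI count table into %ID
#' time-activity curves per organ plus the whole body. Per view and
#' timepoint, corner-background CPP is subtracted from the whole-body and
#' calibration-source ROIs and body-background (muscle) CPP from organ ROIs;
#' anterior and posterior net counts are then combined by their arithmetic
#' mean (no geometric-mean attenuation correction is applied). The
#' administered count in image units is the averaged calibration-source net
#' divided by `std_ratio`, the calibration-source-to-administered activity
#' ratio measured on the gamma-counter.
#'
#' @param rois data frame in `planar_rois.csv` layout: `subject_id`,
#'   `time_h`, `view` (`"anterior"`/`"posterior"`), `roi_label`, `count`,
#'   `size_px`. Labels `background_corner`, `body_background`,
#'   `calibration_source` and `whole_body` are structural; every other label
#'   is treated as an organ.
#' @param std_ratio calibration-source activity / administered activity
#'   (dimensionless, > 0).
#' @return named list of `tac` objects (unit `"pid"`), one per organ plus
#'   `whole_body`.
#' @export
conjugate_percent_id <- function(rois, std_ratio) {
  if (!is.finite(std_ratio) || std_ratio <= 0) {
    md_stop("std_ratio must be > 0", "mirdose_invalid_input")
  }
  subject <- if ("subject_id" %in% names(rois)) as.character(rois$subject_id[1]) else "s1"
  times <- sort(unique(rois$time_h))
  labels <- setdiff(unique(rois$roi_label), c("background_corner", "body_background"))
  if (!"calibration_source" %in% labels) {
    md_stop("calibration_source ROI absent from study", "mirdose_missing_calibration")
  }
  per_tp <- lapply(times, function(tp) {
    nets <- sapply(c("anterior", "posterior"), function(vw) {
      sub <- rois[rois$time_h == tp & rois$view == vw, , drop = FALSE]
      if (nrow(sub) == 0L) {
        md_stop(sprintf("timepoint %g h is missing the %s view", tp, vw),
                "mirdose_incomplete_timepoint")
      }
      bg <- background_cpp(sub, "background_corner")
      body_bg <- background_cpp(sub, "body_background")
      vapply(labels, function(lb) {
        row <- sub[sub$roi_label == lb, , drop = FALSE]
        if (nrow(row) == 0L) return(NA_real_)
        cpp <- if (lb %in% .plain_bg_users) bg else body_bg
        sum(net_roi_count(row$count, row$size_px, cpp))
      }, numeric(1))
    })
    rowMeans(nets)   # arithmetic mean of anterior/posterior
  })
  avg <- do.call(rbind, per_tp)          # timepoints x labels
  cal <- avg[, "calibration_source"]
  if (anyNA(cal)) {
    md_stop(sprintf("calibration source missing at t = %s h",
                    paste(times[is.na(cal)], collapse = ", ")),
            "mirdose_missing_calibration")
  }
  administered <- cal / std_ratio        # image-domain administered count
  organs <- setdiff(labels, "calibration_source")
  out <- lapply(organs, function(lb) {
    pid <- avg[, lb] / administered * 100
    keep <- !is.na(pid)
    tac(times[keep], pid[keep], unit = "pid",
        subject_id = subject, compartment = lb)
  })
  names(out) <- organs
  out
}

#' Scale a blood %ID/mL curve by the subject's peak whole-blood content
#'
#' Scaled %ID/mL = %ID/mL / max %ID x 100, where max %ID = peak %ID/mL x
#' body weight (kg) x circulating blood volume (65 mL/kg for cynomolgus
#' monkey). This normalizes each subject's blood curve to its own peak
#' whole-blood activity so PK parameters are comparable across subjects.
#'
#' @param curve a `tac` with unit `"pid_per_ml"`.
#' @param body_weight_kg subject body weight, kg.
#' @param blood_ml_per_kg circulating blood volume per kg (default 65).
#' @return a `tac` of scaled values (unit kept as `"pid_per_ml"`).
#' @export
scaled_percent_id <- function(curve, body_weight_kg, blood_ml_per_kg = 65) {
  stopifnot(is_tac(curve))
  if (curve$unit != "pid_per_ml") {
    md_stop("scaled_percent_id requires a %ID/mL curve", "mirdose_invalid_input")
  }
  max_pid <- max(curve$value) * body_weight_kg * blood_ml_per_kg
  if (!is.finite(max_pid) || max_pid <= 0) {
    md_stop("curve peak is not positive; cannot scale", "mirdose_degenerate_curve")
  }
  tac_update(curve, curve$value / max_pid * 100)
}

#' Read gamma-counter sample records
#'
#' @param path CSV with columns `subject_id, compartment, time_h, counts_cpm,
#'   amount, amount_unit` (`amount_unit` in `mL`/`g`).
#' @return the validated data frame.
#' @export
read_gamma_counts <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "compartment", "time_h", "counts_cpm", "amount", "amount_unit")
  if (!all(need %in% names(df))) {
    md_stop(paste0("gamma counts csv must have columns: ",
                   paste(need, collapse = ", ")), "mirdose_invalid_input")
  }
  if (any(df$amount <= 0)) md_stop("amounts must be > 0", "mirdose_invalid_input")
  df
}

#' Read a counting-standard table
#'
#' @param path CSV with columns `subject_id, counts_cpm, volume_ml,
#'   dilution_factor, administered_volume_ml`.
#' @return named list of [counting_standard()] objects, one per subject.
#' @export
read_counting_standard <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "counts_cpm", "volume_ml", "dilution_factor",
            "administered_volume_ml")
  if (!all(need %in% names(df))) {
    md_stop(paste0("counting standard csv must have columns: ",
                   paste(need, collapse = ", ")), "mirdose_invalid_input")
  }
  out <- lapply(seq_len(nrow(df)), function(i) {
    counting_standard(df$counts_cpm[i], df$volume_ml[i], df$dilution_factor[i],
                      df$administered_volume_ml[i])
  })
  names(out) <- df$subject_id
  out
}

#' Gamma-counter records to %ID time-activity curves
#'
#' Applies [percent_id_per_ml()] to every sample; `amount_unit` decides
#' whether the curve unit is %ID/mL or %ID/g.
#'
#' @param counts data frame from [read_gamma_counts()].
#' @param standards named list from [read_counting_standard()].
#' @return named list of `tac` objects keyed `subject_id.compartment`.
#' @export
gamma_counts_to_tac <- function(counts, standards) {
  parts <- split(counts, list(counts$subject_id, counts$compartment), drop = TRUE)
  lapply(parts, function(p) {
    p <- p[order(p$time_h), ]
    std <- standards[[as.character(p$subject_id[1])]]
    if (is.null(std)) {
      md_stop(sprintf("no counting standard for subject '%s'", p$subject_id[1]),
              "mirdose_invalid_standard")
    }
    unit <- if (p$amount_unit[1] == "g") "pid_per_g" else "pid_per_ml"
    tac(p$time_h, percent_id_per_ml(p$counts_cpm, p$amount, std),
        unit = unit, subject_id = p$subject_id[1], compartment = p$compartment[1])
  })
}
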