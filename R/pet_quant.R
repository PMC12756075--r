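# PET outcome measures: SUV, late-window spleen-referenced SUVR-1, and
# aggregate (volume-weighted) binding.

#' Standardized uptake value
#'
#' `SUV = concentration [kBq/mL] * body weight [g] / injected dose [kBq]`,
#' i.e. tissue activity normalized by injected dose per unit body weight.
#'
#' @param conc_kbq_ml tissue activity concentration, kBq/mL.
#' @param injected_dose_mbq injected dose, MBq (> 0).
#' @param body_weight_kg body weight, kg (> 0).
#' @return unitless SUV.
#' @export
compute_suv <- function(conc_kbq_ml, injected_dose_mbq, body_weight_kg) {
  if (any(injected_dose_mbq <= 0)) stop_input("injected dose must be > 0 MBq")
  if (any(body_weight_kg <= 0)) stop_input("body weight must be > 0 kg")
  conc_kbq_ml * (body_weight_kg * 1000) / (injected_dose_mbq * 1000)
}

#' Duration-weighted mean activity over a time window
#'
#' Averages frame activities over frames fully contained in
#' `[window[1], window[2]]`, weighting by frame duration. Frames only
#' partially overlapping the window are excluded.
#'
#' @param frame_start,frame_end frame boundaries in minutes (non-overlapping,
#'   ordered).
#' @param activity activity concentration per frame (kBq/mL, >= 0).
#' @param window length-2 numeric, window start/end in minutes (default the
#'   late 180-240 min binding window).
#' @return duration-weighted mean activity, kBq/mL.
#' @export
window_mean <- function(frame_start, frame_end, activity, window = c(180, 240)) {
  if (length(frame_start) != length(frame_end) ||
      length(frame_start) != length(activity))
    stop_input("frame_start, frame_end and activity must have equal length")
  if (any(frame_end <= frame_start)) stop_input("frames must have positive duration")
  o <- order(frame_start)
  fs <- frame_start[o]; fe <- frame_end[o]; act <- activity[o]
  if (any(fs[-1] < fe[-length(fe)] - 1e-9)) stop_input("frames must not overlap")
  inside <- fs >= window[1] - 1e-9 & fe <= window[2] + 1e-9
  if (!any(inside))
    stop_input("no frame fully contained in window [%g, %g] min", window[1], window[2])
  w <- (fe - fs)[inside]
  sum(w * act[inside]) / sum(w)
}

#' Spleen-referenced SUVR-1
#'
#' Ratio of target-region SUV to reference-region (spleen) SUV minus one; the
#' spleen accounts for non-specific tracer uptake and the subtraction of 1
#' removes the non-specific component of the ratio. Because injected dose and
#' body weight cancel in the ratio, activity concentrations can be supplied
#' directly. Negative values (target below reference) are retained with a
#' warning since downstream regression consumes them.
#'
#' @param pancreas_suv target-region SUV (or activity concentration).
#' @param spleen_suv reference-region SUV (> 0).
#' @return unitless SUVR-1.
#' @export
compute_suvr_minus1 <- function(pancreas_suv, spleen_suv) {
  if (any(spleen_suv <= 0)) stop_input("reference (spleen) SUV must be > 0")
  out <- pancreas_suv / spleen_suv - 1
  if (any(out < 0))
    warning("negative SUVR-1 value(s): target uptake below the spleen reference",
            call. = FALSE)
  out
}

#' Aggregate binding: metric times pancreas volume
#'
#' Volume-weighted binding (`SUVR-1 x volume` or `BP_ND x volume`) accounts
#' for organ volume loss and is reflective of total (aggregate) beta-cell
#' mass rather than density.
#'
#' @param metric unitless binding metric (SUVR-1 or BP_ND).
#' @param volume_ml region volume in mL (> 0).
#' @return metric times volume, unitless * mL.
#' @export
aggregate_binding <- function(metric, volume_ml) {
  if (any(volume_ml <= 0)) stop_input("volume must be > 0 mL")
  metric * volume_ml
}

#' SUVR-1 per subject and region from a time-activity table
#'
#' @param tac `data.frame` with columns `subject`, `region`,
#'   `frame_start_min`, `frame_end_min`, `activity_kbq_ml`; one region must be
#'   the reference.
#' @param window late binding window in minutes.
#' @param reference reference region name (default `"spleen"`).
#' @return `data.frame` with `subject`, `region`, `suvr_minus1` for every
#'   non-reference region.
#' @export
suvr_table <- function(tac, window = c(180, 240), reference = "spleen") {
  need <- c("subject", "region", "frame_start_min", "frame_end_min", "activity_kbq_ml")
  if (!all(need %in% names(tac)))
    stop_input("tac table must have columns %s", paste(need, collapse = ", "))
  out <- list()
  for (s in unique(tac$subject)) {
    d <- tac[tac$subject == s, ]
    if (!reference %in% d$region)
      stop_input("subject %s: reference region '%s' missing", s, reference)
    ref <- d[d$region == reference, ]
    ref_mean <- window_mean(ref$frame_start_min, ref$frame_end_min,
                            ref$activity_kbq_ml, window)
    for (r in setdiff(unique(d$region), reference)) {
      tr <- d[d$region == r, ]
      tr_mean <- window_mean(tr$frame_start_min, tr$frame_end_min,
                             tr$activity_kbq_ml, window)
      out[[paste(s, r)]] <- data.frame(
        subject = s, region = r,
        suvr_minus1 = compute_suvr_minus1(tr_mean, ref_mean),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
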