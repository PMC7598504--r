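#' Relative Supercoiling Units (RSU)
#'
#' Apparent linking numbers vary from gel to gel, so supercoiling is reported
#' on a relative scale anchored by two reference lanes run on every gel:
#' `ref0` (defined as 0 RSU) and `ref1` (defined as 1 RSU). A lane's RSU is
#' the linear interpolation/extrapolation of its weighted mean Lk between the
#' two reference weighted means:
#' `(weighted_lk - ref0_lk) / (ref1_lk - ref0_lk)`. With references 0.5 Lk
#' apart, one full linking number of offset converts to 2 RSU. The scale is
#' invariant under any common affine transform of the three inputs, which is
#' what makes cross-gel comparison legitimate; it deliberately says nothing
#' about the sign of supercoiling.
#'
#' @param weighted_lk Weighted mean Lk of the lane (vectorized).
#' @param ref0_lk Weighted mean Lk of the 0-RSU reference lane.
#' @param ref1_lk Weighted mean Lk of the 1-RSU reference lane.
#' @return RSU value(s).
#' @examples
#' rsu(3.0, ref0_lk = 2.0, ref1_lk = 2.5)  # 2
#' @export
rsu <- function(weighted_lk, ref0_lk, ref1_lk) {
  if (!is_num1(ref0_lk) || !is_num1(ref1_lk)) {
    stop_tq("topoquant_invalid_parameter", "reference weighted Lk values must be finite numbers")
  }
  if (abs(ref1_lk - ref0_lk) <= 1e-9) {
    stop_tq("topoquant_degenerate_reference_error",
            "reference lanes are not separated (|ref1 - ref0| <= 1e-9)")
  }
  (weighted_lk - ref0_lk) / (ref1_lk - ref0_lk)
}

#' DNA gyrase activity as delta-Lk per hour
#'
#' Activity is the signed increase in weighted mean apparent Lk per hour
#' relative to the starting topoisomer distribution; relaxation gives
#' negative values.
#'
#' @param initial_wlk Weighted mean Lk of the starting distribution.
#' @param final_wlk Weighted mean Lk after incubation.
#' @param hours Incubation time in hours, `> 0`.
#' @return Activity in delta-Lk per hour.
#' @export
gyrase_activity <- function(initial_wlk, final_wlk, hours) {
  if (!is_num1(hours) || hours <= 0) {
    stop_tq("topoquant_invalid_duration_error", "hours must be > 0")
  }
  (final_wlk - initial_wlk) / hours
}

#' Percent variation of activity against a baseline
#'
#' Enzyme activities are reported as percent variation against the
#' no-polyamine baseline (which is 0% by construction):
#' `100 * (activity - baseline) / baseline`.
#'
#' @param activity Activity of the condition (vectorized).
#' @param baseline_activity Baseline activity, nonzero.
#' @return Relative variation in percent.
#' @examples
#' relative_activity(2.22, 1)  # +122
#' @export
relative_activity <- function(activity, baseline_activity) {
  if (!is_num1(baseline_activity) || baseline_activity == 0) {
    stop_tq("topoquant_degenerate_baseline_error", "baseline activity must be nonzero")
  }
  100 * (activity - baseline_activity) / baseline_activity
}

#' Tabulate RSU for a set of quantified lanes
#'
#' Convenience wrapper: given per-lane weighted mean Lk values and the ids of
#' the two reference lanes (which must come from the same gel/batch as the
#' samples), returns a table of weighted Lk and RSU per lane.
#'
#' @param weighted Named numeric vector of weighted mean Lk per lane, or a
#'   data.frame with columns `lane_id` and `weighted_lk`.
#' @param ref0,ref1 Lane ids of the 0-RSU and 1-RSU references.
#' @return A data.frame `lane_id`, `weighted_lk`, `rsu`, `ref0_lane`,
#'   `ref1_lane`.
#' @export
rsu_table <- function(weighted, ref0 = "ref0", ref1 = "ref1") {
  if (is.data.frame(weighted)) {
    ids <- weighted$lane_id
    w <- weighted$weighted_lk
  } else {
    ids <- names(weighted)
    w <- as.numeric(weighted)
  }
  if (is.null(ids)) stop_tq("topoquant_invalid_parameter", "lanes must be named")
  if (!(ref0 %in% ids)) stop_tq("topoquant_config_error", sprintf("reference lane '%s' not present", ref0))
  if (!(ref1 %in% ids)) stop_tq("topoquant_config_error", sprintf("reference lane '%s' not present", ref1))
  r <- rsu(w, w[ids == ref0][1], w[ids == ref1][1])
  data.frame(lane_id = ids, weighted_lk = w, rsu = r,
             ref0_lane = ref0, ref1_lane = ref1, stringsAsFactors = FALSE)
}
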