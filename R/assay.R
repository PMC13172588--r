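#' Wound-healing migration rate
#'
#' `(W0 - W1) / W0 * 100`, the percentage of the initial wound width closed
#' between 0 h and the endpoint.  A pure ratio, so invariant to the width
#' unit.  Values are not clamped: a widened wound gives a negative rate
#' with a warning.
#'
#' @param w0 initial wound width(s), > 0.
#' @param w1 final wound width(s), >= 0 (same unit as `w0`).
#' @return migration rate(s) in percent.
#' @examples
#' migration_rate(100, 50)  # 50
#' @export
migration_rate <- function(w0, w1) {
  if (any(!is.finite(w0)) || any(w0 <= 0)) {
    stop("initial wound width w0 must be > 0", call. = FALSE)
  }
  if (any(!is.finite(w1)) || any(w1 < 0)) {
    stop("final wound width w1 must be >= 0", call. = FALSE)
  }
  rate <- (w0 - w1) / w0 * 100
  if (any(rate < 0)) warning("negative migration rate: wound widened", call. = FALSE)
  rate
}

#' Spheroid invasion area
#'
#' `I1 - I0`, the change in spheroid area from 0 h to 48 h; the sign is
#' preserved and shrinkage triggers a warning.
#'
#' @param i0 initial spheroid area(s), >= 0.
#' @param i1 final spheroid area(s), >= 0.
#' @return area difference(s).
#' @export
invasion_area <- function(i0, i1) {
  if (any(!is.finite(i0)) || any(i0 < 0) || any(!is.finite(i1)) || any(i1 < 0)) {
    stop("spheroid areas must be non-negative", call. = FALSE)
  }
  out <- i1 - i0
  if (any(out < 0)) warning("negative invasion area: spheroid shrank", call. = FALSE)
  out
}

#' IHC staining-area grade
#'
#' Maps the stained area fraction to the grade bands 0: (0-5%],
#' 1: (5-25%], 2: (25-50%], 3: (50-75%], 4: (>75%].  Interval endpoints are
#' left-open/right-closed, so exactly 5% is grade 0 and grade 1 starts
#' strictly above 5%; the cut points are configurable.
#'
#' @param area_fraction stained area fraction(s) in `[0, 1]`.
#' @param breaks upper bounds of grades 0-3 (default `c(.05, .25, .50, .75)`).
#' @return integer grade(s) 0-4.
#' @export
ihc_area_grade <- function(area_fraction, breaks = c(0.05, 0.25, 0.50, 0.75)) {
  if (any(!is.finite(area_fraction)) || any(area_fraction < 0) ||
      any(area_fraction > 1)) {
    stop("area_fraction must lie in [0, 1]", call. = FALSE)
  }
  stopifnot(length(breaks) == 4L, !is.unsorted(breaks))
  vapply(area_fraction, function(f) sum(f > breaks), integer(1))
}

#' IHC composite score
#'
#' Area grade (0-4, from [ihc_area_grade()]) multiplied by the intensity
#' grade (0 negative, 1 weak, 2 moderate, 3 strong); the composite ranges
#' from 0 to 12 and is non-decreasing in both inputs.
#'
#' @param area_fraction stained area fraction(s) in `[0, 1]`.
#' @param intensity_grade intensity grade(s) in `{0, 1, 2, 3}`.
#' @param breaks passed to [ihc_area_grade()].
#' @return integer composite score(s) in `[0, 12]`.
#' @examples
#' ihc_score(0.80, 3)  # 12
#' @export
ihc_score <- function(area_fraction, intensity_grade,
                      breaks = c(0.05, 0.25, 0.50, 0.75)) {
  if (!all(intensity_grade %in% 0:3)) {
    stop("intensity_grade must be one of 0, 1, 2, 3", call. = FALSE)
  }
  ihc_area_grade(area_fraction, breaks) * as.integer(intensity_grade)
}

#' qPCR 2^-ddCt fold change
#'
#' `ddCt = (Ct_target,case - Ct_ref,case) - (Ct_target,ctrl - Ct_ref,ctrl)`
#' and fold change `2^(-ddCt)`.  Invariant to adding a constant to every Ct;
#' swapping case and control inverts the fold change.
#'
#' @param ct_target_case,ct_ref_case target/reference Ct in the case sample.
#' @param ct_target_ctrl,ct_ref_ctrl target/reference Ct in the control.
#' @return fold change(s) `2^(-ddCt)`.
#' @examples
#' ddct_fold(20, 15, 22, 15)  # ddCt = -2, fold = 4
#' @export
ddct_fold <- function(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl) {
  vals <- c(ct_target_case, ct_ref_case, ct_target_ctrl, ct_ref_ctrl)
  if (any(!is.finite(vals))) stop("Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_case - ct_ref_case) - (ct_target_ctrl - ct_ref_ctrl)
  2^(-ddct)
}
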