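#' TCFA decision thresholds
#'
#' The rule constants for thin-cap fibroatheroma calling and artefact-based
#' exclusion: lipid arc >= `arc_min_deg` (inclusive) and minimum fibrous cap
#' thickness < `cap_max_um` (strict) in at least `min_qualifying` out of
#' `window_frames` consecutive frames; frames with more than
#' `aline_artefact_max` of their A-lines artefacted are excluded (strict >);
#' lesions or pullbacks retaining less than `retention_min` of their frames
#' are not evaluable (so exactly 50% retained stays in).
#'
#' @param arc_min_deg Minimum lipid arc in degrees (default 90, inclusive).
#' @param cap_max_um Cap-thickness threshold in micrometres (default 65,
#'   exclusive).
#' @param window_frames Sliding-window length in frames (default 10).
#' @param min_qualifying Qualifying frames required within a window
#'   (default 3).
#' @param aline_artefact_max Maximum tolerated artefacted A-line fraction per
#'   frame (default 0.25, frames strictly above are excluded).
#' @param retention_min Minimum retained-frame fraction for a lesion or
#'   pullback to stay evaluable (default 0.50).
#' @return An object of class `"tcfa_thresholds"`.
#' @export
tcfa_thresholds <- function(arc_min_deg = 90, cap_max_um = 65,
                            window_frames = 10L, min_qualifying = 3L,
                            aline_artefact_max = 0.25,
                            retention_min = 0.50) {
  stopifnot(min_qualifying <= window_frames, window_frames >= 1,
            aline_artefact_max > 0, aline_artefact_max < 1,
            retention_min > 0, retention_min < 1,
            arc_min_deg >= 0, arc_min_deg <= 360, cap_max_um > 0)
  structure(list(arc_min_deg = arc_min_deg, cap_max_um = cap_max_um,
                 window_frames = as.integer(window_frames),
                 min_qualifying = as.integer(min_qualifying),
                 aline_artefact_max = aline_artefact_max,
                 retention_min = retention_min),
            class = "tcfa_thresholds")
}

#' Frame-level artefact exclusion
#'
#' A frame is excluded from analysis when more than `aline_artefact_max`
#' (default 25%) of its A-lines are affected by severe artefacts; the
#' comparison is strict, so a frame at exactly the threshold is retained.
#'
#' @param frame An [oct_frame()], or a list with `artefact_alines` and
#'   `n_alines`.
#' @param thresholds A [tcfa_thresholds()].
#' @return `TRUE` when the frame is excluded.
#' @export
frame_excluded <- function(frame, thresholds = tcfa_thresholds()) {
  stopifnot(frame$n_alines > 0)
  length(frame$artefact_alines) / frame$n_alines > thresholds$aline_artefact_max
}

#' Lesion/pullback evaluability under the retention rule
#'
#' A unit (lesion span or whole pullback) stays evaluable when the fraction
#' of retained (non-excluded) frames is at least `retention_min`; units that
#' retained less than 50% of their frames are dropped from analysis.
#'
#' @param excluded Logical vector of per-frame exclusion flags over the unit.
#' @param thresholds A [tcfa_thresholds()].
#' @return `TRUE` when the unit is evaluable.
#' @export
unit_evaluable <- function(excluded, thresholds = tcfa_thresholds()) {
  stopifnot(length(excluded) > 0)
  mean(!excluded) >= thresholds$retention_min
}

#' Frame-level TCFA qualification
#'
#' A frame qualifies when its lipid arc is at least `arc_min_deg` (inclusive)
#' and its minimum fibrous cap thickness is below `cap_max_um` (strict).
#' Non-analyzable frames and frames without lipid never qualify.
#'
#' @param metrics A `"plaque_metrics"` object, or a list/row with
#'   `lipid_arc_deg`, `min_cap_um`, `analyzable`.
#' @param thresholds A [tcfa_thresholds()].
#' @return Logical.
#' @export
frame_qualifies <- function(metrics, thresholds = tcfa_thresholds()) {
  if (!isTRUE(metrics$analyzable)) return(FALSE)
  arc <- metrics$lipid_arc_deg
  cap <- metrics$min_cap_um
  if (is.na(arc) || is.na(cap)) return(FALSE)
  arc >= thresholds$arc_min_deg && cap < thresholds$cap_max_um
}

#' Vectorised frame qualification over a metrics table
#'
#' @param metrics Data.frame with `lipid_arc_deg`, `min_cap_um`,
#'   `analyzable` columns (one row per frame).
#' @param thresholds A [tcfa_thresholds()].
#' @return Logical vector, `FALSE` for non-analyzable or lipid-free frames.
#' @export
frames_qualify <- function(metrics, thresholds = tcfa_thresholds()) {
  q <- metrics$analyzable &
    !is.na(metrics$lipid_arc_deg) & !is.na(metrics$min_cap_um) &
    metrics$lipid_arc_deg >= thresholds$arc_min_deg &
    metrics$min_cap_um < thresholds$cap_max_um
  q & !is.na(q)
}

# core sliding-window rule: does any window of `window` consecutive positions
# hold >= `min_q` qualifying frames?  Sequences shorter than the window are
# treated as a single window.  Returns the 1-based start of the first winning
# window, or 0L.
window_scan <- function(q, window, min_q) {
  n <- length(q)
  if (n == 0L) return(0L)
  if (n <= window) return(if (sum(q) >= min_q) 1L else 0L)
  cs <- cumsum(q)
  wins <- cs[window:n] - c(0, cs[seq_len(n - window)])
  hit <- wins >= min_q
  if (any(hit)) which.max(hit) else 0L
}

#' Consecutive-frame window rule
#'
#' The decision engine behind [call_unit_tcfa()]: `TRUE` when some window of
#' `window_frames` consecutive positions of the qualify sequence contains at
#' least `min_qualifying` qualifying frames (a sequence shorter than the
#' window is a single window).
#'
#' @param qualify Logical vector of per-frame qualification flags.
#' @param thresholds A [tcfa_thresholds()].
#' @return Logical.
#' @export
window_positive <- function(qualify, thresholds = tcfa_thresholds()) {
  window_scan(qualify, thresholds$window_frames,
              thresholds$min_qualifying) > 0L
}

#' Call TCFA status for one unit (lesion or pullback)
#'
#' Applies the consecutive-frame rule: the unit is TCFA-positive when some
#' window of `window_frames` consecutive frame positions contains at least
#' `min_qualifying` qualifying frames. By default the window slides over
#' retained frames in original order with excluded frames removed
#' (exclusion means "unreadable", not "plaque absent");
#' `window_mode = "original"` keeps original frame positions with excluded
#' frames counting as non-qualifying.
#'
#' @param qualify Logical vector of per-frame qualification flags, in
#'   original frame order over the unit.
#' @param excluded Logical vector of per-frame exclusion flags (same length).
#' @param thresholds A [tcfa_thresholds()].
#' @param scope `"target_lesion"` or `"complete_segment"`.
#' @param unit_id Identifier recorded on the call.
#' @param frame_index Optional original frame indices (defaults to
#'   `0:(n-1)`).
#' @param window_mode `"retained"` (default) or `"original"`.
#' @return An object of class `"tcfa_call"`: list with `scope`, `unit_id`,
#'   `evaluable`, `positive` (`NA` when not evaluable), `qualifying_frames`
#'   (original indices of qualifying frames in the first winning window),
#'   `excluded_frames`, `n_frames`, `n_retained`.
#' @export
call_unit_tcfa <- function(qualify, excluded = rep(FALSE, length(qualify)),
                           thresholds = tcfa_thresholds(),
                           scope = "target_lesion", unit_id = NA_character_,
                           frame_index = seq_along(qualify) - 1L,
                           window_mode = c("retained", "original")) {
  window_mode <- match.arg(window_mode)
  stopifnot(length(qualify) == length(excluded),
            length(frame_index) == length(qualify))
  qualify <- as.logical(qualify) & !excluded  # excluded frames never qualify
  call <- list(scope = scope, unit_id = unit_id,
               evaluable = unit_evaluable(excluded, thresholds),
               positive = NA, qualifying_frames = integer(),
               excluded_frames = frame_index[excluded],
               n_frames = length(qualify), n_retained = sum(!excluded))
  if (!call$evaluable) return(structure(call, class = "tcfa_call"))
  if (window_mode == "retained") {
    keep <- !excluded
    q <- qualify[keep]
    idx <- frame_index[keep]
  } else {
    q <- qualify
    idx <- frame_index
  }
  start <- window_scan(q, thresholds$window_frames, thresholds$min_qualifying)
  call$positive <- start > 0L
  if (call$positive) {
    k <- min(thresholds$window_frames, length(q))
    win <- start:(start + k - 1L)
    call$qualifying_frames <- idx[win][q[win]]
  }
  structure(call, class = "tcfa_call")
}

#' @export
print.tcfa_call <- function(x, ...) {
  cat(sprintf("<tcfa_call %s/%s> %s (%d/%d frames retained)\n",
              x$scope, x$unit_id,
              if (!x$evaluable) "not evaluable"
              else if (x$positive) "TCFA-positive" else "TCFA-negative",
              x$n_retained, x$n_frames))
  invisible(x)
}

#' Patient-level TCFA status
#'
#' A patient is TCFA-positive when at least one evaluable unit in the scope
#' is positive, irrespective of the number of included units. Patients with
#' no evaluable unit are dropped from that scope's analysis set (`NA`).
#'
#' @param calls List of `"tcfa_call"` objects for one patient and scope.
#' @return `TRUE`/`FALSE`, or `NA` when no unit is evaluable.
#' @export
call_patient <- function(calls) {
  ev <- vapply(calls, function(x) isTRUE(x$evaluable), logical(1))
  if (!any(ev)) return(NA)
  any(vapply(calls[ev], function(x) isTRUE(x$positive), logical(1)))
}
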