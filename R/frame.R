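#' Construct a segmentation frame
#'
#' Bundles one OCT cross-section as a labelled pixel grid with its physical
#' spacing and per-A-line artefact flags. Label codes follow [OCT_LABELS].
#'
#' @param labels Integer matrix of class codes 0--9 (rows = y, columns = x).
#' @param pixel_spacing_um Isotropic pixel spacing in micrometres (> 0).
#' @param n_alines Number of A-lines (radial scan lines) in the frame.
#' @param artefact_alines Integer vector of 1-based A-line indices flagged as
#'   affected by severe attenuation artefacts (blood, gas bubbles).
#' @param frame_index 0-based position of the frame within its pullback.
#' @return An object of class `"oct_frame"`.
#' @export
oct_frame <- function(labels, pixel_spacing_um, n_alines = 504L,
                      artefact_alines = integer(), frame_index = 0L) {
  stopifnot(is.matrix(labels), pixel_spacing_um > 0, n_alines > 0)
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (any(labels < 0L | labels > 9L))
    stop("label codes must lie in 0..9")
  artefact_alines <- as.integer(artefact_alines)
  if (any(artefact_alines < 1L | artefact_alines > n_alines))
    stop("artefact_alines must be 1-based indices in [1, n_alines]")
  structure(
    list(labels = labels,
         pixel_spacing_um = as.numeric(pixel_spacing_um),
         n_alines = as.integer(n_alines),
         artefact_alines = sort(unique(artefact_alines)),
         frame_index = as.integer(frame_index)),
    class = "oct_frame"
  )
}

#' @export
print.oct_frame <- function(x, ...) {
  cat(sprintf(
    "<oct_frame #%d> %dx%d px @ %.1f um/px, %d A-lines (%d artefacted)\n",
    x$frame_index, nrow(x$labels), ncol(x$labels), x$pixel_spacing_um,
    x$n_alines, length(x$artefact_alines)))
  invisible(x)
}
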