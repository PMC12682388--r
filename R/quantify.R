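# column layout of the ray matrix returned by cpp_cast_rays
RAY_COLS <- c("lumen_r", "lipid_r", "lum_x", "lum_y", "lip_x", "lip_y",
              "gw_frac")

as_ray_mat <- function(rays) {
  if (is.data.frame(rays)) as.matrix(rays[RAY_COLS]) else rays
}

#' Centroid of the lumen
#'
#' Arithmetic mean of the lumen-pixel coordinates (pixel centres, 0-based,
#' x = column, y = row). When the guidewire artefact splits the lumen, the
#' centroid of all lumen pixels is still used.
#'
#' @param frame An [oct_frame()].
#' @return Numeric `c(x, y)`, or `NULL` when the frame has no lumen pixels
#'   (such frames are non-analyzable).
#' @export
lumen_centroid <- function(frame) {
  v <- cpp_lumen_centroid(frame$labels)
  if (v[3] == 0) return(NULL)
  c(x = v[1], y = v[2])
}

#' Cast angular rays through a label map
#'
#' Samples the label map along `n_bins` evenly spaced rays from the lumen
#' centroid (nearest-pixel lookup at radial steps of `step` pixels) and
#' records, per angular bin, the lumen boundary radius (outer edge of the
#' initial contiguous lumen/guidewire run), the first lipid radius, the pixel
#' coordinates backing both, and the guidewire fraction along the ray.
#' Angles increase counter-clockwise from +x; bin k covers
#' `[k, k+1) * 360 / n_bins` degrees and is sampled at its centre.
#'
#' @param frame An [oct_frame()].
#' @param centroid Numeric `c(x, y)` ray origin in 0-based pixel coordinates.
#' @param n_bins Number of angular bins (default 360, i.e. 1 degree bins).
#' @param step Radial sampling step in pixels (<= 0.5).
#' @param bg_break Terminate a ray after this many consecutive background
#'   samples beyond the lumen (0 = scan to the grid edge). The vessel wall
#'   is radially contiguous, so a sustained background run cannot be
#'   followed by tissue in any mask this package produces.
#' @return A data.frame with one row per bin: `lumen_r`, `lipid_r` (pixels,
#'   `NA` when undefined), `lum_x`, `lum_y`, `lip_x`, `lip_y`, `gw_frac`.
#' @export
cast_rays <- function(frame, centroid = lumen_centroid(frame),
                      n_bins = 360L, step = 0.5, bg_break = 0L) {
  m <- cast_rays_mat(frame, centroid, n_bins, step, bg_break)
  out <- as.data.frame(m)
  names(out) <- RAY_COLS
  out
}

# matrix fast path shared with quantify_frame
cast_rays_mat <- function(frame, centroid, n_bins = 360L, step = 0.5,
                          bg_break = 0L) {
  if (is.null(centroid)) stop("no lumen pixels: cannot cast rays")
  stopifnot(n_bins >= 90L, step <= 0.5, step > 0)
  if (centroid[1L] < 0 || centroid[1L] > ncol(frame$labels) - 1 ||
      centroid[2L] < 0 || centroid[2L] > nrow(frame$labels) - 1)
    stop("centroid lies outside the pixel grid")
  cpp_cast_rays(frame$labels, centroid[1L], centroid[2L],
                as.integer(n_bins), step, as.integer(bg_break))
}

# lipid evidence per bin: a first-lipid radius exists and the ray is not
# dominated by the guidewire shadow
lipid_bin_flags <- function(m) {
  !is.na(m[, 2L]) & m[, 7L] <= GW_SHADOW_FRACTION
}

#' Lipid arc from ray profiles
#'
#' Largest contiguous run of lipid-positive angular bins, in degrees, with
#' wraparound across 0 degrees. Returns 0 when no bin holds lipid. Bins
#' dominated by the guidewire shadow contribute no lipid evidence.
#'
#' @param rays Ray profiles from [cast_rays()].
#' @return Lipid arc in degrees, in `[0, 360]`.
#' @export
lipid_arc <- function(rays) {
  pos <- lipid_bin_flags(as_ray_mat(rays))
  n <- length(pos)
  bin_w <- 360 / n
  if (!any(pos)) return(0)
  if (all(pos)) return(360)
  # longest circular run via the doubled sequence
  r <- rle(c(pos, pos))
  runs <- r$lengths[r$values]
  min(max(runs), n) * bin_w
}

#' Minimum fibrous cap thickness from ray profiles
#'
#' Over all lipid-positive bins, the minimum of
#' `(first-lipid radius - lumen boundary radius) * pixel spacing`, measured
#' radially from the lumen centroid. Candidate lumen/lipid pixel pairs that
#' are direct grid neighbours (8-connectivity, Chebyshev distance <= 1) are
#' ignored, so touching segmentations cannot produce zero-thickness caps.
#' Bins whose lipid lies radially inside the lumen boundary (inconsistent
#' mask) are skipped; their count is returned in attribute
#' `"n_inconsistent"`.
#'
#' @param rays Ray profiles from [cast_rays()].
#' @param pixel_spacing_um Pixel spacing in micrometres.
#' @return Minimum cap thickness in micrometres, or `NA` when no lipid bin
#'   exists (no lipid means no cap to measure) or every candidate pair is
#'   adjacent.
#' @export
min_cap_thickness <- function(rays, pixel_spacing_um) {
  m <- as_ray_mat(rays)
  keep <- lipid_bin_flags(m) & !is.na(m[, 1L])
  if (!any(keep)) return(NA_real_)
  m <- m[keep, , drop = FALSE]
  gap <- m[, 2L] - m[, 1L]
  inconsistent <- gap <= 0
  adjacent <- pmax(abs(m[, 5L] - m[, 3L]), abs(m[, 6L] - m[, 4L])) <= 1
  ok <- !inconsistent & !adjacent
  val <- if (any(ok)) min(gap[ok]) * pixel_spacing_um else NA_real_
  structure(val, n_inconsistent = sum(inconsistent))
}

#' Quantify plaque metrics for one frame
#'
#' Composes centroid, ray casting, lipid arc and minimum cap thickness into
#' per-frame plaque metrics. A frame is non-analyzable (metrics absent) when
#' it has no lumen pixels, or when `thresholds` are supplied and the frame
#' fails the A-line artefact criterion (see [frame_excluded()]).
#'
#' @param frame An [oct_frame()].
#' @param n_bins Number of angular bins (default 360).
#' @param thresholds Optional [tcfa_thresholds()]; when given, artefacted
#'   frames are marked non-analyzable.
#' @param bg_break Ray termination rule, see [cast_rays()]; the default
#'   stops a ray after 16 pixels of uninterrupted background.
#' @return An object of class `"plaque_metrics"`: list with `lipid_arc_deg`,
#'   `min_cap_um`, `lumen_centroid`, `analyzable`, `frame_index`.
#' @export
quantify_frame <- function(frame, n_bins = 360L, thresholds = NULL,
                           bg_break = 32L) {
  na_metrics <- function() {
    structure(list(lipid_arc_deg = NA_real_, min_cap_um = NA_real_,
                   lumen_centroid = NULL, analyzable = FALSE,
                   frame_index = frame$frame_index),
              class = "plaque_metrics")
  }
  if (!is.null(thresholds) && frame_excluded(frame, thresholds))
    return(na_metrics())
  ctr <- lumen_centroid(frame)
  if (is.null(ctr)) return(na_metrics())
  m <- cast_rays_mat(frame, ctr, n_bins = n_bins, bg_break = bg_break)
  arc <- lipid_arc(m)
  cap <- as.numeric(min_cap_thickness(m, frame$pixel_spacing_um))
  structure(list(lipid_arc_deg = arc, min_cap_um = cap,
                 lumen_centroid = ctr, analyzable = TRUE,
                 frame_index = frame$frame_index),
            class = "plaque_metrics")
}

#' @export
print.plaque_metrics <- function(x, ...) {
  cat(sprintf("<plaque_metrics #%d> arc %.1f deg, cap %s um, %s\n",
              x$frame_index,
              ifelse(is.na(x$lipid_arc_deg), NaN, x$lipid_arc_deg),
              ifelse(is.na(x$min_cap_um), "--", format(x$min_cap_um)),
              if (x$analyzable) "analyzable" else "non-analyzable"))
  invisible(x)
}

#' Quantify all frames of a pullback
#'
#' @param frames List of [oct_frame()] objects.
#' @param n_bins Number of angular bins.
#' @param thresholds Optional [tcfa_thresholds()] for artefact exclusion.
#' @return A data.frame with columns `frame_index`, `lipid_arc_deg`,
#'   `min_cap_um`, `analyzable`.
#' @export
quantify_pullback <- function(frames, n_bins = 360L, thresholds = NULL) {
  n <- length(frames)
  fi <- integer(n); arc <- cap <- numeric(n); ana <- logical(n)
  for (i in seq_len(n)) {
    m <- quantify_frame(frames[[i]], n_bins = n_bins,
                        thresholds = thresholds)
    fi[i] <- m$frame_index; arc[i] <- m$lipid_arc_deg
    cap[i] <- m$min_cap_um; ana[i] <- m$analyzable
  }
  data.frame(frame_index = fi, lipid_arc_deg = arc, min_cap_um = cap,
             analyzable = ana)
}
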