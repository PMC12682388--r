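#' Write a pullback of label maps as multi-frame TIFF with JSON sidecar
#'
#' Label maps are stored as one 8-bit page per frame (codes 0-9); the
#' sidecar JSON records pixel spacing, A-line count, per-frame artefact
#' A-line indices (0-based) and lesion spans (0-based half-open intervals).
#'
#' @param frames List of [oct_frame()] objects.
#' @param path Output TIFF path; the sidecar is written at `<path>.json`.
#' @param lesion_spans Optional list of `c(start, end)` spans.
#' @return `path`, invisibly.
#' @export
write_pullback_tiff <- function(frames, path, lesion_spans = list()) {
  stopifnot(length(frames) > 0)
  pages <- lapply(frames, function(f) f$labels / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8L, compression = "none")
  meta <- list(
    pixel_spacing_um = frames[[1]]$pixel_spacing_um,
    n_alines = frames[[1]]$n_alines,
    n_frames = length(frames),
    artefact_alines = lapply(frames, function(f) f$artefact_alines - 1L),
    lesion_spans = lesion_spans)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a pullback written by [write_pullback_tiff()]
#'
#' @param path TIFF path with `<path>.json` sidecar alongside.
#' @return List with `frames` (list of [oct_frame()]) and `metadata`.
#' @export
read_pullback_tiff <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  art <- meta$artefact_alines
  frames <- lapply(seq_along(pages), function(i) {
    a <- if (i <= length(art)) unlist(art[[i]]) else integer()
    oct_frame(pages[[i]], meta$pixel_spacing_um,
              n_alines = meta$n_alines,
              artefact_alines = as.integer(a) + 1L,
              frame_index = i - 1L)
  })
  list(frames = frames, metadata = meta)
}

#' Read / write per-frame metrics tables
#'
#' CSV with columns `frame_index`, `lipid_arc_deg`, `min_cap_um`,
#' `analyzable` (plus any extra columns present).
#'
#' @param metrics Data.frame from [quantify_pullback()].
#' @param path CSV path.
#' @return The data.frame (read) or `path` invisibly (write).
#' @export
write_metrics_csv <- function(metrics, path) {
  write.csv(metrics, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_csv
#' @export
read_metrics_csv <- function(path) {
  df <- read.csv(path)
  need <- c("frame_index", "lipid_arc_deg", "min_cap_um", "analyzable")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("metrics table missing columns: ", paste(miss, collapse = ", "))
  df
}
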