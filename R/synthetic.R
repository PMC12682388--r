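#' Generate one synthetic segmentation frame
#'
#' Rasterises an idealised OCT cross-section on a square grid with the
#' catheter at the image centre: a (near-)circular lumen, an intima band
#' whose minimum radial width over the lipid pool equals the requested cap
#' thickness (to within one pixel), a contiguous lipid pool subtending the
#' requested arc about the lumen centroid, and media/background beyond.
#' A requested fraction of A-lines is flagged as artefacted. Every pixel
#' carries exactly one of the ten [OCT_LABELS] classes.
#'
#' @param arc_deg Lipid arc in degrees, in `[0, 360]`; 0 plants no lipid.
#' @param cap_um Fibrous cap thickness in micrometres (over the lipid pool).
#' @param lumen_radius_px Lumen radius in pixels.
#' @param pixel_spacing_um Pixel spacing in micrometres.
#' @param aline_artefact_fraction Fraction of A-lines to flag as artefacted.
#' @param grid_px Grid side length in pixels.
#' @param n_alines Number of A-lines.
#' @param arc_start_deg Angular start of the lipid pool (degrees CCW from
#'   +x); drawn uniformly when `NULL`.
#' @param lipid_depth_um Radial depth of the lipid pool.
#' @param intima_um Intima thickness outside the lipid pool.
#' @param media_um Media band thickness.
#' @param guidewire Plant a small guidewire artefact inside the lumen.
#' @param frame_index 0-based frame position.
#' @return An [oct_frame()].
#' @export
generate_frame <- function(arc_deg, cap_um, lumen_radius_px = 120,
                           pixel_spacing_um = 10,
                           aline_artefact_fraction = 0,
                           grid_px = 704L, n_alines = 504L,
                           arc_start_deg = NULL, lipid_depth_um = 400,
                           intima_um = 250, media_um = 150,
                           guidewire = FALSE, frame_index = 0L) {
  stopifnot(arc_deg >= 0, arc_deg <= 360, cap_um >= 0,
            aline_artefact_fraction >= 0, aline_artefact_fraction <= 1)
  cap_px <- cap_um / pixel_spacing_um
  lipid_px <- lipid_depth_um / pixel_spacing_um
  intima_px <- intima_um / pixel_spacing_um
  media_px <- media_um / pixel_spacing_um
  outer <- lumen_radius_px +
    max(cap_px + lipid_px, intima_px) + media_px
  if (outer >= grid_px / 2 - 2)
    stop(sprintf(
      "geometry does not fit: vessel outer radius %.0f px vs grid half-width %.0f px",
      outer, grid_px / 2))
  if (is.null(arc_start_deg)) arc_start_deg <- runif(1, 0, 360)
  arc_start_deg <- arc_start_deg %% 360
  pf <- polar_fields(grid_px)
  lab <- cpp_frame_labels(pf$dx, pf$dy, pf$r, pf$theta, lumen_radius_px,
                          cap_px, arc_start_deg, arc_deg, lipid_px,
                          intima_px, media_px, guidewire)
  n_bad <- round(aline_artefact_fraction * n_alines)
  bad <- if (n_bad > 0) sample.int(n_alines, n_bad) else integer()
  oct_frame(lab, pixel_spacing_um, n_alines = n_alines,
            artefact_alines = bad, frame_index = frame_index)
}

# polar coordinate fields of a square grid about its centre, cached per
# grid size (they are reused for every frame of a run)
.polar_cache <- new.env(parent = emptyenv())
polar_fields <- function(grid_px) {
  key <- as.character(grid_px)
  pf <- .polar_cache[[key]]
  if (!is.null(pf)) return(pf)
  ctr <- (grid_px - 1) / 2
  off <- seq_len(grid_px) - 1 - ctr
  dx <- matrix(off, grid_px, grid_px, byrow = TRUE)  # x = column
  dy <- matrix(off, grid_px, grid_px)                # y = row
  r <- sqrt(dx^2 + dy^2)
  theta <- atan2(dy, dx) * 180 / pi
  theta[theta < 0] <- theta[theta < 0] + 360
  pf <- list(dx = dx, dy = dy, r = r, theta = theta)
  .polar_cache[[key]] <- pf
  pf
}

# per-frame (arc, cap) profile of a planted plaque; kinds:
#  "tcfa"    -- >= 3 consecutive thin-cap frames inside the plaque
#  "lipid"   -- lipid-rich but thick-capped (never qualifies)
#  "sub_arc" -- lipid arc below 90 degrees (never qualifies)
make_plaque_profile <- function(n_frames, kind, config) {
  jitter_clamp <- function(base, n, lo, hi, sd = 6)
    pmin(pmax(base + rnorm(n, 0, sd), lo), hi)
  if (kind == "tcfa") {
    arc_base <- runif(1, config$planted_arc_range[1],
                      config$planted_arc_range[2])
    arc <- jitter_clamp(arc_base, n_frames, 95, 320)
    cap <- runif(n_frames, config$nontcfa_cap_range[1],
                 config$nontcfa_cap_range[2])
    n_thin <- sample(seq(config$thin_frames_range[1],
                         min(config$thin_frames_range[2], n_frames)), 1)
    start <- sample.int(n_frames - n_thin + 1L, 1)
    cap[start:(start + n_thin - 1L)] <-
      runif(n_thin, config$planted_cap_range[1], config$planted_cap_range[2])
  } else if (kind == "lipid") {
    arc_base <- runif(1, config$nontcfa_arc_range[1],
                      config$nontcfa_arc_range[2])
    arc <- jitter_clamp(arc_base, n_frames, 95, 320)
    cap <- runif(n_frames, config$nontcfa_cap_range[1],
                 config$nontcfa_cap_range[2])
  } else {
    arc_base <- runif(1, config$sub_arc_range[1], config$sub_arc_range[2])
    arc <- jitter_clamp(arc_base, n_frames, 20, 85)
    cap <- runif(n_frames, config$nontcfa_cap_range[1],
                 config$nontcfa_cap_range[2])
  }
  data.frame(arc_deg = arc, cap_um = cap)
}

# one planted plaque: absolute frame span within the pullback + profile
make_plaque <- function(span_start, span_len, kind, config) {
  profile <- make_plaque_profile(span_len, kind, config)
  qual <- profile$arc_deg >= 90 & profile$cap_um < 65
  is_tcfa <- window_scan(qual, 10L, 3L) > 0L
  # planted truth must match the plaque kind by construction
  stopifnot(is_tcfa == (kind == "tcfa"))
  list(span = c(span_start, span_start + span_len),
       profile = profile,
       arc_start_deg = runif(1, 0, 360),
       is_tcfa = is_tcfa, kind = kind)
}

# lesion lengths: log-normal around the configured median, clamped so the
# lesion plus margins fits the pullback
draw_lesion_frames <- function(config) {
  n <- round(rlnorm(1, log(config$frames_per_lesion_median),
                    config$frames_per_lesion_sdlog))
  as.integer(min(max(n, 60L), config$pullback_frames - 60L))
}

# artefacted-A-line fractions for one lesion span (artefacts cluster by
# lesion; most lesions are perfectly clean)
draw_artefact_fractions <- function(n_frames, config) {
  frac <- numeric(n_frames)
  if (runif(1) < config$artefact_lesion_rate) {
    hit <- runif(n_frames) < config$artefact_frame_rate
    frac[hit] <- runif(sum(hit), config$artefact_aline_fraction_range[1],
                       config$artefact_aline_fraction_range[2])
  }
  frac
}

#' Simulate a synthetic OCT cohort
#'
#' Draws the full latent structure of a study cohort: patients with 1-3
#' target lesions (one pullback per lesion), planted plaque profiles with
#' known TCFA truth, per-frame artefact contamination, reference-reader
#' calls on the target lesions, and proportional-hazards follow-up driven by
#' the complete-segment TCFA truth. Frames themselves are rasterised lazily
#' (see [generate_pullback()] and [run_tcfa_pipeline()]).
#'
#' @param config A [cohort_config()].
#' @return An object of class `"oct_cohort"`: list with `config`, `patients`
#'   (data.frame), `lesions` (list of lesion specs), `pullbacks` (list of
#'   pullback specs), `corelab` (data.frame), `survival` (data.frame).
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  lesions <- list(); pullbacks <- list()
  pat_rows <- vector("list", config$n_patients)
  for (p in seq_len(config$n_patients)) {
    pid <- sprintf("P%04d", p)
    set.seed(patient_seed(config$rng_seed, pid))
    n_les <- sample.int(length(config$lesions_per_patient_probs), 1,
                        prob = config$lesions_per_patient_probs)
    extra_tcfa <- runif(1) < config$extra_segment_tcfa_rate
    extra_in <- if (extra_tcfa) sample.int(n_les, 1) else 0L
    tl_pos <- FALSE
    for (l in seq_len(n_les)) {
      lid <- sprintf("%s-L%d", pid, l)
      pbid <- sprintf("%s-PB%d", pid, l)
      n_frames <- draw_lesion_frames(config)
      start <- sample.int(config$pullback_frames - n_frames - 40L, 1) + 20L
      is_tcfa <- runif(1) < config$tcfa_lesion_prevalence
      kind <- if (is_tcfa) "tcfa"
              else if (runif(1) < config$lipid_lesion_rate) "lipid"
              else "sub_arc"
      plq_len <- sample(seq(config$plaque_frames_range[1],
                            min(config$plaque_frames_range[2], n_frames)), 1)
      plq_start <- start + sample.int(n_frames - plq_len + 1L, 1) - 1L
      plaque <- make_plaque(plq_start, plq_len, kind, config)
      tl_pos <- tl_pos || plaque$is_tcfa
      artefact <- numeric(config$pullback_frames)
      artefact[(start + 1L):(start + n_frames)] <-
        draw_artefact_fractions(n_frames, config)
      lumen_r <- runif(1, config$lumen_radius_um_range[1],
                       config$lumen_radius_um_range[2]) /
        config$pixel_spacing_um
      extra <- NULL
      if (extra_in == l) {
        # plant an out-of-lesion TCFA plaque elsewhere in this pullback
        gap_lo <- c(20L, start + n_frames + 10L)
        gap_hi <- c(start - 10L, config$pullback_frames - 20L)
        room <- gap_hi - gap_lo
        side <- which(room >= 20L)
        if (length(side)) {
          s <- side[which.max(room[side])]
          elen <- min(30L, room[s])
          estart <- gap_lo[s] + sample.int(room[s] - elen + 1L, 1) - 1L
          extra <- make_plaque(estart, elen, "tcfa", config)
        }
      }
      lesions[[lid]] <- list(
        lesion_id = lid, pullback_id = pbid, patient_id = pid,
        frame_span = c(start, start + n_frames),
        plaque = plaque, planted_is_tcfa = plaque$is_tcfa, kind = kind)
      pullbacks[[pbid]] <- list(
        pullback_id = pbid, patient_id = pid,
        n_frames = config$pullback_frames,
        lesion_ids = lid, lumen_radius_px = lumen_r,
        artefact_fraction = artefact, extra_plaque = extra)
    }
    cs_pos <- tl_pos ||
      any(vapply(pullbacks[paste0(pid, "-PB", seq_len(n_les))],
                 function(pb) !is.null(pb$extra_plaque), logical(1)))
    pat_rows[[p]] <- data.frame(
      patient_id = pid, n_lesions = n_les,
      true_tcfa_target_lesion = tl_pos,
      true_tcfa_complete_segment = cs_pos)
  }
  patients <- do.call(rbind, pat_rows)
  set.seed(patient_seed(config$rng_seed, "corelab"))
  corelab <- simulate_corelab_reads(lesions, config)
  set.seed(patient_seed(config$rng_seed, "survival"))
  survival <- simulate_survival(
    setNames(patients$true_tcfa_complete_segment, patients$patient_id),
    config, hr = config$true_hr_complete_segment)
  survival$exposure_true_target_lesion <- patients$true_tcfa_target_lesion
  survival$exposure_true_complete_segment <- patients$true_tcfa_complete_segment
  structure(list(config = config, patients = patients, lesions = lesions,
                 pullbacks = pullbacks, corelab = corelab,
                 survival = survival),
            class = "oct_cohort")
}

#' @export
print.oct_cohort <- function(x, ...) {
  cat(sprintf(
    "<oct_cohort> %d patients, %d lesions (%.1f%% planted TCFA), %d pullbacks\n",
    nrow(x$patients), length(x$lesions),
    100 * mean(vapply(x$lesions, `[[`, logical(1), "planted_is_tcfa")),
    length(x$pullbacks)))
  invisible(x)
}

# planted (arc, cap) for one absolute frame of a pullback; NULL when the
# frame carries no plaque
frame_plant <- function(pullback, lesions, i) {
  for (lid in pullback$lesion_ids) {
    plq <- lesions[[lid]]$plaque
    if (i >= plq$span[1] && i < plq$span[2])
      return(list(arc = plq$profile$arc_deg[i - plq$span[1] + 1L],
                  cap = plq$profile$cap_um[i - plq$span[1] + 1L],
                  arc_start = plq$arc_start_deg))
  }
  ep <- pullback$extra_plaque
  if (!is.null(ep) && i >= ep$span[1] && i < ep$span[2])
    return(list(arc = ep$profile$arc_deg[i - ep$span[1] + 1L],
                cap = ep$profile$cap_um[i - ep$span[1] + 1L],
                arc_start = ep$arc_start_deg))
  NULL
}

# rasterise one frame of a pullback spec
render_frame <- function(pullback, lesions, i, config) {
  pl <- frame_plant(pullback, lesions, i)
  arc <- if (is.null(pl)) 0 else pl$arc
  cap <- if (is.null(pl)) 100 else pl$cap
  arc_start <- if (is.null(pl)) 0 else pl$arc_start
  generate_frame(arc, cap,
                 lumen_radius_px = pullback$lumen_radius_px,
                 pixel_spacing_um = config$pixel_spacing_um,
                 aline_artefact_fraction = pullback$artefact_fraction[i + 1L],
                 grid_px = config$grid_px, n_alines = config$n_alines,
                 arc_start_deg = arc_start, frame_index = i)
}

#' Rasterise a full synthetic pullback
#'
#' Renders every frame of a pullback spec as a label map. Frames outside any
#' planted plaque contain lumen, intima, media and background only.
#'
#' @param pullback A pullback spec from [simulate_cohort()].
#' @param lesions The cohort's lesion-spec list.
#' @param config The [cohort_config()].
#' @return List with `frames` (list of [oct_frame()]) and `metadata` (lesion
#'   spans, spacing, A-line count).
#' @export
generate_pullback <- function(pullback, lesions, config) {
  spans <- lapply(lesions[pullback$lesion_ids], `[[`, "frame_span")
  if (length(spans) > 1) {
    s <- do.call(rbind, spans)
    s <- s[order(s[, 1]), , drop = FALSE]
    if (any(s[-1, 1] < s[-nrow(s), 2]))
      stop("overlapping lesion spans in pullback")
  }
  for (sp in spans)
    if (sp[1] < 0 || sp[2] > pullback$n_frames)
      stop("lesion span outside pullback bounds")
  frames <- lapply(seq_len(pullback$n_frames) - 1L,
                   function(i) render_frame(pullback, lesions, i, config))
  list(frames = frames,
       metadata = list(pullback_id = pullback$pullback_id,
                       patient_id = pullback$patient_id,
                       pixel_spacing_um = config$pixel_spacing_um,
                       n_alines = config$n_alines,
                       lesion_spans = spans))
}

#' Simulate reference-reader (core-lab) TCFA calls
#'
#' Emulates manual core-laboratory reading of each target lesion. With
#' probability `frame_skill` the reader locates the frame with the thinnest
#' planted cap; otherwise a uniformly chosen plaque frame is read (manual
#' TCFA screening rarely measures every frame, and frame selection is the
#' dominant source of interobserver variability). The selected frame's cap
#' and arc are measured with Gaussian error and the frame-level rule (lipid
#' arc >= 90 degrees and cap < 65 um on a single frame -- no
#' consecutive-frame requirement) gives the call. Lesions without lipid are
#' read negative. With zero noise and `frame_skill = 1` the calls equal the
#' planted frame-rule truth.
#'
#' @param lesions Lesion-spec list from [simulate_cohort()].
#' @param config A [cohort_config()] (supplies the noise defaults).
#' @param cap_noise_sd,arc_noise_sd Override the configured reader noise.
#' @param frame_skill Override the configured frame-location skill.
#' @return A data.frame with `lesion_id`, `patient_id`, `corelab_tcfa`.
#' @export
simulate_corelab_reads <- function(lesions, config,
                                   cap_noise_sd = config$reader_cap_noise_sd,
                                   arc_noise_sd = config$reader_arc_noise_sd,
                                   frame_skill = config$reader_frame_skill) {
  stopifnot(cap_noise_sd >= 0, arc_noise_sd >= 0,
            frame_skill >= 0, frame_skill <= 1)
  rows <- lapply(lesions, function(les) {
    prof <- les$plaque$profile
    if (nrow(prof) == 0) {
      call <- FALSE
    } else {
      k <- if (runif(1) < frame_skill) which.min(prof$cap_um)
           else sample.int(nrow(prof), 1)
      cap <- prof$cap_um[k] + rnorm(1, 0, cap_noise_sd)
      arc <- prof$arc_deg[k] + rnorm(1, 0, arc_noise_sd)
      call <- arc >= 90 && cap < 65
    }
    data.frame(lesion_id = les$lesion_id, patient_id = les$patient_id,
               corelab_tcfa = call)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate proportional-hazards follow-up
#'
#' Exponential event times with per-patient hazard
#' `baseline x HR^exposure`, administrative censoring at the configured
#' horizon with uniform jitter, and first-event types drawn from the
#' configured multinomial (death / MI / revascularisation).
#'
#' @param exposure Named logical vector (names become `patient_id`).
#' @param config A [cohort_config()].
#' @param hr Hazard ratio applied to exposed patients (defaults to the
#'   configured marginal target-lesion HR).
#' @return A data.frame: `patient_id`, `time_days`, `event`, `event_type`.
#' @export
simulate_survival <- function(exposure, config,
                              hr = config$true_hr_target_lesion) {
  stopifnot(hr > 0)
  n <- length(exposure)
  lambda0 <- -log(1 - config$baseline_event_rate_2y) / 730
  lambda <- lambda0 * hr^as.numeric(exposure)
  t_event <- rexp(n, rate = lambda)
  censor <- config$admin_censor_days +
    runif(n, -config$admin_censor_jitter_days,
          config$admin_censor_jitter_days)
  event <- t_event <= censor
  typ <- rep("none", n)
  if (any(event))
    typ[event] <- sample(names(config$event_type_probs), sum(event),
                         replace = TRUE, prob = config$event_type_probs)
  data.frame(
    patient_id = if (is.null(names(exposure)))
      sprintf("P%04d", seq_len(n)) else names(exposure),
    time_days = pmin(t_event, censor), event = event, event_type = typ,
    row.names = NULL)
}
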