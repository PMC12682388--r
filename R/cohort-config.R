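#' Synthetic cohort configuration
#'
#' Houses the study-scale constants the synthetic generator emulates:
#' lesions per patient (mean 1.18, max 3), frames per lesion (median ~200,
#' IQR 136-264), near-zero artefact rates (per-lesion excluded-frame median
#' 0%, 90th percentile ~3.2%), lesion-level TCFA prevalence ~30.7%,
#' reference-reader noise calibrated to a lesion-level kappa ~0.38, a 2-year
#' composite event rate ~8% and a complete-segment hazard ratio of 5.5 from
#' which the marginal target-lesion hazard ratio ~2 emerges through the
#' nesting of the two exposures.
#'
#' Planted cap thicknesses keep a guard band of at least two pixels around
#' the 65 um threshold (thin caps at most 60 um, thick caps at least 100 um
#' at the default 10 um spacing) so that pixel-level measurement error
#' cannot flip planted truth; near-threshold reader discordance is produced
#' by the reader noise model instead.
#'
#' @param n_patients Number of patients.
#' @param lesions_per_patient_probs Probabilities of 1, 2, 3 lesions per
#'   patient (mean 1.18 at the default).
#' @param frames_per_lesion_median Median lesion length in frames.
#' @param frames_per_lesion_iqr Target interquartile bounds (frames).
#' @param frames_per_lesion_sdlog Log-normal shape for lesion lengths.
#' @param pullback_frames Frames per pullback.
#' @param grid_px Square label-map side in pixels.
#' @param pixel_spacing_um Isotropic pixel spacing in micrometres.
#' @param n_alines A-lines per frame.
#' @param lumen_radius_um_range Per-lesion lumen radius range (um).
#' @param tcfa_lesion_prevalence Fraction of target lesions planted as TCFA.
#' @param extra_segment_tcfa_rate Probability that a patient carries an
#'   additional TCFA plaque outside any target lesion (drives
#'   complete-segment prevalence ~59%).
#' @param planted_arc_range Lipid arc range (degrees) for TCFA plaques.
#' @param planted_cap_range Thin-frame cap range (um) for TCFA plaques.
#' @param nontcfa_arc_range Arc range for lipid-rich non-TCFA plaques.
#' @param nontcfa_cap_range Cap range (um) for non-TCFA plaques.
#' @param sub_arc_range Arc range for small-arc (arc < 90 deg) plaques.
#' @param lipid_lesion_rate Fraction of non-TCFA lesions carrying a
#'   lipid-rich (arc >= 90) plaque; the rest get a small-arc plaque.
#' @param thin_frames_range Range of consecutive thin-cap frames planted in
#'   a TCFA plaque (at least 3 so the 3-of-10 rule is satisfiable).
#' @param plaque_frames_range Planted plaque length range (frames).
#' @param artefact_lesion_rate Fraction of lesions affected by artefacts at
#'   all (artefacts cluster by lesion).
#' @param artefact_frame_rate Within affected lesions, per-frame probability
#'   of artefact flags.
#' @param artefact_aline_fraction_range Range of the artefacted A-line
#'   fraction on flagged frames.
#' @param reader_cap_noise_sd Reader measurement noise on cap thickness (um).
#' @param reader_arc_noise_sd Reader measurement noise on lipid arc (deg).
#' @param reader_frame_skill Probability that the reader locates the
#'   thinnest-cap frame of a plaque (otherwise a random plaque frame is
#'   read); frame selection dominates interobserver variability in manual
#'   TCFA reading.
#' @param baseline_event_rate_2y Two-year composite event probability in the
#'   complete-segment-negative arm.
#' @param true_hr_target_lesion Expected marginal target-lesion hazard
#'   ratio (emergent; used directly when simulating a single exposure).
#' @param true_hr_complete_segment Hazard ratio applied to the
#'   complete-segment exposure in the event-time generator.
#' @param event_type_probs First-event type multinomial
#'   (death / MI / revascularisation).
#' @param admin_censor_days Administrative censoring horizon (days).
#' @param admin_censor_jitter_days Uniform jitter on the censoring visit.
#' @param rng_seed Master seed; per-patient substreams are derived from it.
#' @return An object of class `"cohort_config"` (a validated list).
#' @export
cohort_config <- function(n_patients = 414L,
                          lesions_per_patient_probs = c(0.84, 0.14, 0.02),
                          frames_per_lesion_median = 200L,
                          frames_per_lesion_iqr = c(136L, 264L),
                          frames_per_lesion_sdlog = 0.49,
                          pullback_frames = 540L,
                          grid_px = 704L,
                          pixel_spacing_um = 10,
                          n_alines = 504L,
                          lumen_radius_um_range = c(800, 1400),
                          tcfa_lesion_prevalence = 0.307,
                          extra_segment_tcfa_rate = 0.375,
                          planted_arc_range = c(100, 260),
                          planted_cap_range = c(40, 60),
                          nontcfa_arc_range = c(95, 250),
                          nontcfa_cap_range = c(90, 150),
                          sub_arc_range = c(30, 80),
                          lipid_lesion_rate = 0.7,
                          thin_frames_range = c(3L, 10L),
                          plaque_frames_range = c(15L, 45L),
                          artefact_lesion_rate = 0.25,
                          artefact_frame_rate = 0.06,
                          artefact_aline_fraction_range = c(0.05, 0.45),
                          reader_cap_noise_sd = 55,
                          reader_arc_noise_sd = 20,
                          reader_frame_skill = 0.7,
                          baseline_event_rate_2y = 0.024,
                          true_hr_target_lesion = 2.0,
                          true_hr_complete_segment = 5.5,
                          event_type_probs = c(death = 0.41, mi = 0.21,
                                               revasc = 0.38),
                          admin_censor_days = 730,
                          admin_censor_jitter_days = 30,
                          rng_seed = 1L) {
  cfg <- as.list(environment())
  fr <- c("tcfa_lesion_prevalence", "extra_segment_tcfa_rate",
          "lipid_lesion_rate", "artefact_lesion_rate",
          "artefact_frame_rate", "baseline_event_rate_2y")
  for (f in fr) {
    v <- cfg[[f]]
    if (v < 0 || v > 1) stop(f, " must lie in [0, 1]")
  }
  stopifnot(
    n_patients >= 1,
    abs(sum(lesions_per_patient_probs) - 1) < 1e-8,
    all(lesions_per_patient_probs >= 0),
    frames_per_lesion_iqr[1] <= frames_per_lesion_median,
    frames_per_lesion_median <= frames_per_lesion_iqr[2],
    all(planted_cap_range > 0), diff(planted_cap_range) >= 0,
    all(artefact_aline_fraction_range >= 0),
    all(artefact_aline_fraction_range <= 1),
    reader_cap_noise_sd >= 0, reader_arc_noise_sd >= 0,
    reader_frame_skill >= 0, reader_frame_skill <= 1,
    baseline_event_rate_2y > 0, baseline_event_rate_2y < 1,
    true_hr_target_lesion > 0, true_hr_complete_segment > 0,
    thin_frames_range[1] >= 3,
    sum(event_type_probs) > 0)
  mean_lesions <- sum(seq_along(lesions_per_patient_probs) *
                        lesions_per_patient_probs)
  if (mean_lesions < 1) stop("lesions per patient must average >= 1")
  cfg$event_type_probs <- event_type_probs / sum(event_type_probs)
  structure(cfg, class = "cohort_config")
}

#' Read / write a cohort configuration as YAML
#'
#' The YAML file mirrors the [cohort_config()] fields one for one.
#'
#' @param path File path.
#' @return For `read_cohort_config`, a `"cohort_config"`.
#' @export
read_cohort_config <- function(path) {
  vals <- yaml::read_yaml(path)
  unknown <- setdiff(names(vals), names(formals(cohort_config)))
  if (length(unknown))
    stop("unknown config fields: ", paste(unknown, collapse = ", "))
  if (!is.null(vals$event_type_probs))
    vals$event_type_probs <- unlist(vals$event_type_probs)
  do.call(cohort_config, vals)
}

#' @rdname read_cohort_config
#' @param config A `"cohort_config"`.
#' @export
write_cohort_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$event_type_probs <- as.list(cfg$event_type_probs)  # keep the names
  yaml::write_yaml(cfg, path)
  invisible(path)
}

# deterministic per-patient substream seed derived from the master seed by
# stable string hashing of the patient id, so cohorts are reproducible under
# re-ordering; kept below 2^31
patient_seed <- function(master_seed, patient_id) {
  h <- 0
  for (ch in utf8ToInt(as.character(patient_id)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(master_seed) * 2654435) %% 2147483647)
}
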