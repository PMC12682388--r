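# flood fill over 4-connectivity, test-local, for connectivity checks
n_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  comp <- 0L
  for (start in which(mask & lab == 0L)) {
    if (lab[start] != 0L) next
    comp <- comp + 1L
    queue <- start
    while (length(queue)) {
      i <- queue[[1]]; queue <- queue[-1]
      if (lab[i] != 0L) next
      lab[i] <- comp
      y <- (i - 1L) %% nrow(mask) + 1L; x <- (i - 1L) %/% nrow(mask) + 1L
      for (d in list(c(0, 1), c(0, -1), c(1, 0), c(-1, 0))) {
        yy <- y + d[1]; xx <- x + d[2]
        if (yy >= 1 && yy <= nrow(mask) && xx >= 1 && xx <= ncol(mask)) {
          j <- (xx - 1L) * nrow(mask) + yy
          if (mask[j] && lab[j] == 0L) queue <- c(queue, j)
        }
      }
    }
  }
  comp
}

test_that("generated frames carry exactly one of the ten classes per pixel
           and a connected lumen", {
  set.seed(51)
  f <- test_frame(140, 60, grid = 160L, lumen_r = 40, spacing = 20)
  expect_true(all(f$labels %in% 0:9))
  expect_identical(dim(f$labels), c(160L, 160L))
  expect_equal(n_components(f$labels == OCT_LABELS[["lumen"]]), 1L)
  # requested artefact fraction is honoured
  fa <- test_frame(0, 0, grid = 160L, lumen_r = 40, spacing = 20,
                   aline_artefact_fraction = 0.3)
  expect_equal(length(fa$artefact_alines), round(0.3 * 504))
  # geometry that cannot fit raises an explicit error
  expect_error(generate_frame(90, 50, lumen_radius_px = 100, grid_px = 128L),
               "does not fit")
})

test_that("pullback generation honours spans and artefact settings", {
  cfg <- test_config(n_patients = 2L)
  plaque <- list(span = c(120, 150),
                 profile = data.frame(arc_deg = rep(150, 30),
                                      cap_um = rep(50, 30)),
                 arc_start_deg = 10, is_tcfa = TRUE, kind = "tcfa")
  lesion <- list(lesion_id = "L1", pullback_id = "PB1", patient_id = "P1",
                 frame_span = c(100, 300), plaque = plaque,
                 planted_is_tcfa = TRUE, kind = "tcfa")
  pb <- list(pullback_id = "PB1", patient_id = "P1", n_frames = 540L,
             lesion_ids = "L1", lumen_radius_px = 40,
             artefact_fraction = numeric(540), extra_plaque = NULL)
  out <- generate_pullback(pb, list(L1 = lesion), cfg)
  expect_length(out$frames, 540L)
  expect_equal(diff(out$metadata$lesion_spans[[1]]), 200)
  # frames outside the plaque contain no lipid
  expect_false(any(out$frames[[50]]$labels == OCT_LABELS[["lipid"]]))
  expect_true(any(out$frames[[130]]$labels == OCT_LABELS[["lipid"]]))
  # zero artefact rate leaves every A-line clean
  expect_true(all(vapply(out$frames, function(f)
    length(f$artefact_alines) == 0L, logical(1))))
  # overlapping lesion spans are rejected
  lesion2 <- lesion; lesion2$lesion_id <- "L2"
  lesion2$frame_span <- c(250, 400)
  pb2 <- pb; pb2$lesion_ids <- c("L1", "L2")
  expect_error(generate_pullback(pb2, list(L1 = lesion, L2 = lesion2), cfg),
               "overlapping")
})

test_that("artefact contamination yields a zero median excluded-frame
           fraction per lesion", {
  cfg <- test_config(n_patients = 180L, rng_seed = 52L)
  co <- simulate_cohort(cfg)
  expect_gte(length(co$lesions), 200 * 0.9)
  frac <- vapply(co$lesions, function(les) {
    af <- co$pullbacks[[les$pullback_id]]$artefact_fraction
    span <- (les$frame_span[1] + 1):les$frame_span[2]
    mean(round(af[span] * cfg$n_alines) / cfg$n_alines > 0.25)
  }, numeric(1))
  expect_identical(median(frac), 0)
  expect_lt(quantile(frac, 0.9), 0.10)
})

test_that("cohort structure matches its configured distributions", {
  cfg <- test_config(n_patients = 450L, rng_seed = 53L)
  co <- simulate_cohort(cfg)
  expect_gte(length(co$lesions), 500)
  planted <- vapply(co$lesions, `[[`, logical(1), "planted_is_tcfa")
  expect_lt(abs(mean(planted) - cfg$tcfa_lesion_prevalence), 0.05)
  fpl <- vapply(co$lesions, function(l) diff(l$frame_span), numeric(1))
  expect_gte(median(fpl), cfg$frames_per_lesion_iqr[1])
  expect_lte(median(fpl), cfg$frames_per_lesion_iqr[2])
  # every patient has >= 1 lesion and nested exposure flags
  expect_true(all(co$patients$n_lesions >= 1))
  expect_true(all(co$patients$true_tcfa_complete_segment >=
                    co$patients$true_tcfa_target_lesion))
  # lesions per patient average near the configured mean
  expect_lt(abs(mean(co$patients$n_lesions) - 1.18), 0.06)
})

test_that("reference reads equal planted frame-rule truth in the zero-noise
           limit", {
  cfg <- test_config(n_patients = 120L, rng_seed = 54L)
  co <- simulate_cohort(cfg)
  set.seed(55)
  reads <- simulate_corelab_reads(co$lesions, cfg, cap_noise_sd = 0,
                                  arc_noise_sd = 0, frame_skill = 1)
  truth <- vapply(co$lesions, function(les) {
    p <- les$plaque$profile
    any(p$arc_deg >= 90 & p$cap_um < 65)
  }, logical(1))
  expect_identical(unname(reads$corelab_tcfa), unname(truth))
  # on these planted profiles the any-frame rule and the 3-of-10 rule
  # coincide, so zero-noise agreement with planted lesion truth is perfect
  tab <- build_contingency(
    vapply(co$lesions, `[[`, logical(1), "planted_is_tcfa"),
    reads$corelab_tcfa)
  expect_equal(cohen_kappa(tab)$kappa, 1)
})

test_that("near-threshold caps flip with the closed-form Gaussian tail", {
  # constant 64 um cap, cap noise sd 20: positive probability is
  # P(64 + e < 65) = pnorm(1 / 20) ~ 0.52
  lesions <- lapply(seq_len(800), function(i)
    list(lesion_id = sprintf("L%03d", i), patient_id = "P1",
         plaque = list(profile = data.frame(arc_deg = rep(180, 10),
                                            cap_um = rep(64, 10)))))
  cfg <- test_config(n_patients = 2L)
  set.seed(56)
  reads <- simulate_corelab_reads(lesions, cfg, cap_noise_sd = 20,
                                  arc_noise_sd = 0, frame_skill = 1)
  expect_equal(mean(reads$corelab_tcfa), pnorm(1 / 20), tolerance = 0.05)
})

test_that("survival generator matches the exponential closed form", {
  cfg <- test_config(n_patients = 2L, baseline_event_rate_2y = 0.063,
                     admin_censor_jitter_days = 0)
  set.seed(57)
  expo <- setNames(rep(TRUE, 5000), sprintf("P%04d", 1:5000))
  sv <- simulate_survival(expo, cfg, hr = 1.99)
  got <- mean(sv$event & sv$time_days <= 730)
  expect_equal(got, 1 - (1 - 0.063)^1.99, tolerance = 0.015)
  # event types follow the configured multinomial
  tt <- table(sv$event_type[sv$event]) / sum(sv$event)
  expect_lt(max(abs(as.numeric(tt[names(cfg$event_type_probs)]) -
                      cfg$event_type_probs)), 0.06)
  # censoring at day zero: no events, survival identically one
  cfg0 <- test_config(n_patients = 2L, admin_censor_days = 0,
                      admin_censor_jitter_days = 0)
  sv0 <- simulate_survival(expo[1:50], cfg0)
  expect_true(all(!sv0$event))
  expect_true(all(sv0$time_days == 0))
})

test_that("identical seeds reproduce the cohort and its masks exactly", {
  cfg <- test_config(n_patients = 6L, rng_seed = 58L)
  co1 <- simulate_cohort(cfg)
  co2 <- simulate_cohort(cfg)
  expect_identical(co1$patients, co2$patients)
  expect_identical(co1$corelab, co2$corelab)
  expect_identical(co1$survival, co2$survival)
  pb <- co1$pullbacks[[1]]
  set.seed(59)
  f1 <- generate_pullback(pb, co1$lesions, cfg)
  set.seed(59)
  f2 <- generate_pullback(pb, co2$lesions, cfg)
  expect_identical(f1$frames[[150]]$labels, f2$frames[[150]]$labels)
})
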