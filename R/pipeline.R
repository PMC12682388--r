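# cheap content digest for the run manifest (stable across sessions)
content_digest <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  sprintf("%08x-%d", sum(as.integer(raw)) %% .Machine$integer.max,
          length(raw))
}

#' Run the full synthetic TCFA pipeline
#'
#' Orchestrates simulate -> rasterise -> quantify -> call -> agree ->
#' outcomes for both scopes (target lesion and complete imaged segment) as a
#' single reproducible run. Frames are rasterised and quantified one at a
#' time so pullbacks are never held in memory. Identical seeds give
#' identical outputs.
#'
#' @param config A [cohort_config()].
#' @param thresholds A [tcfa_thresholds()].
#' @param n_bins Angular bins for quantification.
#' @param window_mode Sliding-window indexing, see [call_unit_tcfa()].
#' @param output_dir Optional directory; when given, calls, survival,
#'   agreement and outcome reports plus the manifest are written there.
#' @param progress Print per-stage progress.
#' @return An object of class `"tcfa_run"`: list with `cohort`, `metrics`,
#'   `lesion_calls`, `pullback_calls`, `patient_calls`, `agreement`,
#'   `outcomes`, `manifest`.
#' @export
run_tcfa_pipeline <- function(config = cohort_config(),
                              thresholds = tcfa_thresholds(),
                              n_bins = 360L,
                              window_mode = c("retained", "original"),
                              output_dir = NULL, progress = FALSE) {
  window_mode <- match.arg(window_mode)
  t0 <- Sys.time()
  say <- function(...) if (progress) message(sprintf(...))
  say("simulating cohort (%d patients)", config$n_patients)
  cohort <- simulate_cohort(config)

  say("quantifying %d pullbacks", length(cohort$pullbacks))
  metrics <- vector("list", length(cohort$pullbacks))
  names(metrics) <- names(cohort$pullbacks)
  for (pbid in names(cohort$pullbacks)) {
    pb <- cohort$pullbacks[[pbid]]
    nf <- pb$n_frames
    arc <- cap <- rep(NA_real_, nf)
    ana <- logical(nf)
    excl <- logical(nf)
    # frames without a planted plaque share one plaque-free geometry per
    # pullback (fixed lumen radius): quantify it once and reuse
    plain <- NULL
    for (i in seq_len(nf) - 1L) {
      n_bad <- round(pb$artefact_fraction[i + 1L] * config$n_alines)
      excl[i + 1L] <- n_bad / config$n_alines > thresholds$aline_artefact_max
      if (excl[i + 1L]) next
      pl <- frame_plant(pb, cohort$lesions, i)
      if (is.null(pl)) {
        if (is.null(plain))
          plain <- quantify_frame(render_frame(pb, cohort$lesions, i,
                                               config), n_bins = n_bins)
        m <- plain
      } else {
        m <- quantify_frame(render_frame(pb, cohort$lesions, i, config),
                            n_bins = n_bins)
      }
      arc[i + 1L] <- m$lipid_arc_deg
      cap[i + 1L] <- m$min_cap_um
      ana[i + 1L] <- m$analyzable
    }
    metrics[[pbid]] <- data.frame(
      pullback_id = pbid, frame_index = seq_len(nf) - 1L,
      lipid_arc_deg = arc, min_cap_um = cap, analyzable = ana,
      excluded = excl)
  }

  say("calling TCFA status")
  lesion_calls <- lapply(cohort$lesions, function(les) {
    mt <- metrics[[les$pullback_id]]
    span <- les$frame_span
    sel <- mt$frame_index >= span[1] & mt$frame_index < span[2]
    mt <- mt[sel, , drop = FALSE]
    qual <- frames_qualify(mt, thresholds)
    call_unit_tcfa(qual, mt$excluded, thresholds,
                   scope = "target_lesion", unit_id = les$lesion_id,
                   frame_index = mt$frame_index, window_mode = window_mode)
  })
  pullback_calls <- lapply(cohort$pullbacks, function(pb) {
    mt <- metrics[[pb$pullback_id]]
    qual <- frames_qualify(mt, thresholds)
    call_unit_tcfa(qual, mt$excluded, thresholds,
                   scope = "complete_segment", unit_id = pb$pullback_id,
                   frame_index = mt$frame_index, window_mode = window_mode)
  })
  call_row <- function(x, pid) data.frame(
    scope = x$scope, unit_id = x$unit_id, patient_id = pid,
    evaluable = x$evaluable, positive = x$positive,
    n_frames = x$n_frames, n_retained = x$n_retained)
  lesion_df <- do.call(rbind, Map(
    call_row, lesion_calls,
    vapply(cohort$lesions, `[[`, character(1), "patient_id")))
  pullback_df <- do.call(rbind, Map(
    call_row, pullback_calls,
    vapply(cohort$pullbacks, `[[`, character(1), "patient_id")))
  rownames(lesion_df) <- rownames(pullback_df) <- NULL

  pts <- cohort$patients$patient_id
  ai_tl <- vapply(pts, function(pid) call_patient(
    lesion_calls[lesion_df$patient_id == pid]), logical(1))
  ai_cs <- vapply(pts, function(pid) call_patient(
    pullback_calls[pullback_df$patient_id == pid]), logical(1))
  cl_pat <- vapply(pts, function(pid)
    any(cohort$corelab$corelab_tcfa[cohort$corelab$patient_id == pid]),
    logical(1))
  patient_calls <- data.frame(
    patient_id = pts, ai_tcfa_target_lesion = ai_tl,
    ai_tcfa_complete_segment = ai_cs, cl_tcfa_target_lesion = cl_pat,
    true_tcfa_target_lesion = cohort$patients$true_tcfa_target_lesion,
    true_tcfa_complete_segment = cohort$patients$true_tcfa_complete_segment)

  say("agreement statistics")
  lesion_df$corelab_tcfa <-
    cohort$corelab$corelab_tcfa[match(lesion_df$unit_id,
                                      cohort$corelab$lesion_id)]
  ev <- lesion_df$evaluable
  pat_ok <- !is.na(patient_calls$ai_tcfa_target_lesion)
  agree_block <- function(ai, ref) {
    tryCatch({
      tab <- build_contingency(ai, ref)
      list(table = tab, kappa = cohen_kappa(tab),
           percent = percent_agreement(tab))
    }, error = function(e) NULL)  # empty or degenerate analysis set
  }
  agreement <- list(
    lesion = agree_block(lesion_df$positive[ev],
                         lesion_df$corelab_tcfa[ev]),
    patient = agree_block(patient_calls$ai_tcfa_target_lesion[pat_ok],
                          patient_calls$cl_tcfa_target_lesion[pat_ok]))

  say("outcome analyses")
  surv <- cohort$survival
  surv$exposure_ai_target_lesion <- patient_calls$ai_tcfa_target_lesion
  surv$exposure_ai_complete_segment <- patient_calls$ai_tcfa_complete_segment
  surv$exposure_cl_target_lesion <- patient_calls$cl_tcfa_target_lesion
  outcomes <- list()
  y2 <- binary_outcome_2y(surv)
  for (sc in c("ai_target_lesion", "ai_complete_segment",
               "cl_target_lesion")) {
    col <- paste0("exposure_", sc)
    sub <- surv[!is.na(surv[[col]]), , drop = FALSE]
    res <- list(n = nrow(sub), n_events = sum(sub$event))
    res$cox <- tryCatch(cox_univariable(sub, col),
                        error = function(e) NULL, warning = function(w) NULL)
    res$logrank <- tryCatch(logrank_test(sub, col),
                            error = function(e) NULL)
    res$km <- tryCatch(km_table(kaplan_meier(sub, col)),
                       error = function(e) NULL)
    y2s <- binary_outcome_2y(sub)
    res$cstat <- tryCatch(binary_cstat(sub[[col]], y2s),
                          error = function(e) NULL)
    outcomes[[sc]] <- res
  }
  # prognostic 2x2 for the complete segment (NPV of a negative AI read)
  ok <- !is.na(surv$exposure_ai_complete_segment) & !is.na(y2)
  outcomes$complete_segment_prognostic <- tryCatch({
    prog_tab <- build_contingency(surv$exposure_ai_complete_segment[ok],
                                  y2[ok])
    list(table = prog_tab, metrics = diagnostic_metrics(prog_tab))
  }, error = function(e) NULL)
  outcomes$delong_ai_cs_vs_cl <- tryCatch(
    delong_paired_test(surv$exposure_ai_complete_segment,
                       surv$exposure_cl_target_lesion, y2),
    error = function(e) NULL)

  n_frames_total <- sum(vapply(metrics, nrow, integer(1)))
  n_frames_excl <- sum(vapply(metrics, function(m) sum(m$excluded),
                              integer(1)))
  manifest <- list(
    seed = config$rng_seed,
    config_digest = content_digest(unclass(config)),
    started = format(t0), finished = format(Sys.time()),
    n_patients = nrow(cohort$patients),
    n_lesions = length(cohort$lesions),
    n_pullbacks = length(cohort$pullbacks),
    frames = list(total = n_frames_total, excluded = n_frames_excl,
                  retained = n_frames_total - n_frames_excl),
    lesions = list(total = nrow(lesion_df),
                   evaluable = sum(lesion_df$evaluable),
                   excluded = sum(!lesion_df$evaluable)),
    pullbacks = list(total = nrow(pullback_df),
                     evaluable = sum(pullback_df$evaluable),
                     excluded = sum(!pullback_df$evaluable)),
    patients = list(
      total = nrow(patient_calls),
      analysed_target_lesion = sum(pat_ok),
      dropped_target_lesion = sum(!pat_ok),
      analysed_complete_segment =
        sum(!is.na(patient_calls$ai_tcfa_complete_segment)),
      dropped_complete_segment =
        sum(is.na(patient_calls$ai_tcfa_complete_segment))),
    digests = list(
      lesion_calls = content_digest(lesion_df),
      pullback_calls = content_digest(pullback_df),
      patient_calls = content_digest(patient_calls),
      survival = content_digest(surv)))
  stopifnot(
    manifest$lesions$total ==
      manifest$lesions$evaluable + manifest$lesions$excluded,
    manifest$pullbacks$total ==
      manifest$pullbacks$evaluable + manifest$pullbacks$excluded,
    manifest$frames$total ==
      manifest$frames$retained + manifest$frames$excluded)

  run <- structure(
    list(cohort = cohort, metrics = metrics, lesion_calls = lesion_df,
         pullback_calls = pullback_df, patient_calls = patient_calls,
         survival = surv, agreement = agreement, outcomes = outcomes,
         manifest = manifest),
    class = "tcfa_run")
  if (!is.null(output_dir)) write_run_reports(run, output_dir)
  run
}

#' @export
print.tcfa_run <- function(x, ...) {
  m <- x$manifest
  kap <- if (is.null(x$agreement$lesion)) NA_real_
         else x$agreement$lesion$kappa$kappa
  cat(sprintf(
    paste0("<tcfa_run seed %s> %d patients, %d lesions ",
           "(%d evaluable), kappa %.2f\n"),
    m$seed, m$n_patients, m$lesions$total, m$lesions$evaluable, kap))
  invisible(x)
}

#' Write the machine-readable reports of a pipeline run
#'
#' @param run A `"tcfa_run"`.
#' @param output_dir Directory (created if absent).
#' @return `output_dir`, invisibly.
#' @export
write_run_reports <- function(run, output_dir) {
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, nm) write.csv(
    df, file.path(output_dir, nm), row.names = FALSE)
  w(run$lesion_calls, "lesion_calls.csv")
  w(run$pullback_calls, "pullback_calls.csv")
  w(run$patient_calls, "patient_calls.csv")
  w(run$survival, "survival.csv")
  ag_json <- function(blk) {
    if (is.null(blk)) return(NULL)
    list(table = unclass(blk$table)[c("a", "b", "c", "d", "n")],
         kappa = blk$kappa$kappa, kappa_ci = blk$kappa$ci95,
         percent = blk$percent)
  }
  report <- list(
    agreement = list(lesion = ag_json(run$agreement$lesion),
                     patient = ag_json(run$agreement$patient)),
    outcomes = lapply(
      run$outcomes[c("ai_target_lesion", "ai_complete_segment",
                     "cl_target_lesion")],
      function(res) list(
        n = res$n, n_events = res$n_events,
        hr = if (is.null(res$cox)) NULL else res$cox$hr,
        hr_ci = if (is.null(res$cox)) NULL else res$cox$ci95,
        logrank_p = if (is.null(res$logrank)) NULL else res$logrank$p,
        cstat = if (is.null(res$cstat)) NULL else res$cstat$c,
        cstat_ci = if (is.null(res$cstat)) NULL else res$cstat$ci95)))
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  jsonlite::write_json(run$manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(output_dir)
}

#' Recompute agreement and outcome reports from call tables
#'
#' Runs the statistical stages on externally produced tables (for example
#' call tables reconstructed from a publication), independently of the
#' imaging stages. Row order is irrelevant.
#'
#' @param calls Data.frame with at least `ai_tcfa` and `corelab_tcfa`
#'   logical columns (one row per lesion or patient).
#' @param survival Optional survival-record data.frame (see
#'   [validate_survival_records()]) with one or more logical `exposure_*`
#'   columns.
#' @return List with `agreement` (table, kappa, percent agreement,
#'   diagnostic metrics) and, when `survival` is given, `outcomes` per
#'   exposure column.
#' @export
replay_from_tables <- function(calls, survival = NULL) {
  need <- c("ai_tcfa", "corelab_tcfa")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stop("calls table missing columns: ", paste(miss, collapse = ", "))
  if (nrow(calls) == 0) stop("calls table is empty")
  tab <- build_contingency(calls$ai_tcfa, calls$corelab_tcfa)
  out <- list(agreement = list(
    table = tab, kappa = cohen_kappa(tab),
    percent = percent_agreement(tab)))
  if (!is.null(survival)) {
    cols <- grep("^exposure_", names(survival), value = TRUE)
    if (!length(cols)) stop("survival table has no exposure_* columns")
    survival <- validate_survival_records(survival, cols)
    out$outcomes <- lapply(setNames(cols, cols), function(col) {
      sub <- survival[!is.na(survival[[col]]), , drop = FALSE]
      list(cox = cox_univariable(sub, col),
           logrank = logrank_test(sub, col),
           cstat = binary_cstat(sub[[col]], binary_outcome_2y(sub)))
    })
  }
  out
}
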