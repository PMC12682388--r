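# Independent oracles used across the suite.  These deliberately re-derive
# quantities by brute force (pure R, exhaustive search) rather than calling
# the implementation under test.

# brute-force polar transform: march a single ray with nearest-pixel lookup
# and report (lumen boundary radius, first lipid radius).  Mirrors the
# published measurement definition; written independently of the C++ path.
oracle_ray <- function(labels, cx, cy, theta_rad, step = 0.5) {
  nr <- nrow(labels); nc <- ncol(labels)
  rmax <- sqrt(nr^2 + nc^2)
  t <- seq(0, rmax, by = step)
  px <- round(cx + t * cos(theta_rad))
  py <- round(cy + t * sin(theta_rad))
  on <- px >= 0 & px < nc & py >= 0 & py < nr
  t <- t[on]; px <- px[on]; py <- py[on]
  v <- labels[cbind(py + 1L, px + 1L)]
  lum <- v == 2L; gw <- v == 1L
  # initial contiguous lumen/guidewire run
  run_end <- which(!(lum | gw))[1]
  run <- if (is.na(run_end)) seq_along(v) else seq_len(run_end - 1L)
  lum_in_run <- run[lum[run]]
  lumen_r <- if (length(lum_in_run)) t[max(lum_in_run)] else NA_real_
  lum_i <- if (length(lum_in_run)) max(lum_in_run) else NA_integer_
  lip_i <- which(v == 5L)[1]
  list(lumen_r = lumen_r,
       lipid_r = if (is.na(lip_i)) NA_real_ else t[lip_i],
       lum_xy = if (is.na(lum_i)) c(NA, NA) else c(px[lum_i], py[lum_i]),
       lip_xy = if (is.na(lip_i)) c(NA, NA) else c(px[lip_i], py[lip_i]),
       gw_frac = mean(gw))
}

# full polar transform over n_bins rays (bin-centre sampling)
oracle_polar <- function(labels, cx, cy, n_bins = 360L, step = 0.5) {
  lapply(seq_len(n_bins) - 1L, function(k)
    oracle_ray(labels, cx, cy, (k + 0.5) * 2 * pi / n_bins, step))
}

# arc and cap recomputed from the oracle polar transform with the same
# adjacency-exclusion convention
oracle_arc_cap <- function(labels, cx, cy, spacing, n_bins = 360L,
                           gw_max = 0.3) {
  rays <- oracle_polar(labels, cx, cy, n_bins)
  has_lip <- vapply(rays, function(r)
    !is.na(r$lipid_r) && r$gw_frac <= gw_max, logical(1))
  arc <- if (!any(has_lip)) 0 else if (all(has_lip)) 360 else {
    rl <- rle(c(has_lip, has_lip))
    min(max(rl$lengths[rl$values]), n_bins) * 360 / n_bins
  }
  gaps <- vapply(rays, function(r) {
    if (is.na(r$lipid_r) || r$gw_frac > gw_max || is.na(r$lumen_r))
      return(NA_real_)
    if (r$lipid_r <= r$lumen_r) return(NA_real_)
    if (max(abs(r$lip_xy - r$lum_xy)) <= 1) return(NA_real_)
    r$lipid_r - r$lumen_r
  }, numeric(1))
  cap <- if (all(is.na(gaps))) NA_real_ else min(gaps, na.rm = TRUE) * spacing
  list(arc = arc, cap = cap)
}

# direct enumeration of the consecutive-frame rule: examine every window of
# `window` consecutive positions (whole sequence when shorter)
oracle_window_positive <- function(pattern, window = 10L, min_q = 3L) {
  n <- length(pattern)
  if (n == 0L) return(FALSE)
  k <- min(window, n)
  any(vapply(seq_len(n - k + 1L), function(s)
    sum(pattern[s:(s + k - 1L)]) >= min_q, logical(1)))
}

# hand-computed two-group log-rank statistic (hypergeometric expectation and
# variance term by term over distinct event times)
oracle_logrank_chisq <- function(time, event, group) {
  times <- sort(unique(time[event]))
  O <- E <- V <- 0
  for (tt in times) {
    at_risk <- time >= tt
    n <- sum(at_risk); n1 <- sum(at_risk & group)
    d <- sum(event & time == tt); d1 <- sum(event & time == tt & group)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# written-out Cox partial likelihood for untied data (Breslow = Efron when
# no ties), maximised by grid refinement
oracle_cox_loglik <- function(beta, time, event, x) {
  ll <- 0
  for (i in which(event)) {
    risk <- time >= time[i]
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}
oracle_cox_mle <- function(time, event, x) {
  grid <- seq(-5, 5, by = 0.01)
  ll <- vapply(grid, oracle_cox_loglik, numeric(1), time, event, x)
  b0 <- grid[which.max(ll)]
  fine <- seq(b0 - 0.02, b0 + 0.02, by = 1e-5)
  llf <- vapply(fine, oracle_cox_loglik, numeric(1), time, event, x)
  fine[which.max(llf)]
}

# small-geometry cohort configuration used throughout the tests (fits a
# 192 px grid at 20 um/pixel)
test_config <- function(...) {
  cohort_config(grid_px = 192L, pixel_spacing_um = 20,
                lumen_radius_um_range = c(700, 1000),
                pullback_frames = 160L,
                frames_per_lesion_median = 70L,
                frames_per_lesion_iqr = c(50L, 95L),
                frames_per_lesion_sdlog = 0.3,
                ...)
}

# convenience wrapper for planted single-frame geometry in tests
test_frame <- function(arc, cap, lumen_r = 60, spacing = 10,
                       grid = 288L, ...) {
  generate_frame(arc, cap, lumen_radius_px = lumen_r,
                 pixel_spacing_um = spacing, grid_px = grid, ...)
}
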