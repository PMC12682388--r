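# analytic construction helper: concentric annuli with optional angular
# restriction of the lipid band, built directly from pixel radii/angles
annuli_labels <- function(grid = 224L, lumen_r = 50, bands = list(),
                          base = 0L) {
  ctr <- (grid - 1) / 2
  off <- seq_len(grid) - 1 - ctr
  dx <- matrix(off, grid, grid, byrow = TRUE)
  dy <- matrix(off, grid, grid)
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx) * 180 / pi
  th[th < 0] <- th[th < 0] + 360
  lab <- matrix(base, grid, grid)
  lab[r < lumen_r] <- 2L
  for (b in bands) {
    sel <- r >= b$r_in & r < b$r_out
    if (!is.null(b$arc)) {
      rel <- (th - b$arc[1]) %% 360
      sel <- sel & rel < (b$arc[2] - b$arc[1]) %% 360
    }
    lab[sel & lab == base] <- b$class
  }
  lab
}

test_that("lumen centroid equals the mean of lumen pixel coordinates", {
  lab <- annuli_labels(224L, lumen_r = 50)
  f <- oct_frame(lab, 10)
  ctr <- lumen_centroid(f)
  expect_equal(unname(ctr), c(111.5, 111.5), tolerance = 0.5)

  # single lumen pixel
  lab1 <- matrix(0L, 100, 100)
  lab1[21, 11] <- 2L  # x = 10, y = 20 (0-based)
  ctr1 <- lumen_centroid(oct_frame(lab1, 10))
  expect_equal(unname(ctr1), c(10, 20))

  # eccentric crescent: compare with direct coordinate-mean oracle
  lab2 <- annuli_labels(224L, lumen_r = 50)
  lab2[annuli_labels(224L, lumen_r = 40) == 2L] <- 0L  # carve hole
  lab2[, 1:100] <- 0L                                  # make it a crescent
  idx <- which(lab2 == 2L, arr.ind = TRUE)
  ctr2 <- lumen_centroid(oct_frame(lab2, 10))
  expect_equal(unname(ctr2), c(mean(idx[, 2]) - 1, mean(idx[, 1]) - 1))

  # no lumen pixels -> NULL, frame non-analyzable
  f0 <- oct_frame(matrix(0L, 50, 50), 10)
  expect_null(lumen_centroid(f0))
  expect_false(quantify_frame(f0)$analyzable)
})

test_that("ray casting recovers analytic annulus radii in every bin", {
  lab <- annuli_labels(224L, lumen_r = 50, bands = list(
    list(class = 3L, r_in = 50, r_out = 56),
    list(class = 5L, r_in = 56, r_out = 80),
    list(class = 4L, r_in = 80, r_out = 90)))
  f <- oct_frame(lab, 10)
  rays <- cast_rays(f, c(111.5, 111.5))
  expect_equal(nrow(rays), 360L)
  expect_true(all(abs(rays$lumen_r - 50) <= 1))
  expect_true(all(abs(rays$lipid_r - 56) <= 1))
})

test_that("lipid arc takes the largest contiguous run with wraparound", {
  mk <- function(arcs) {
    lab <- annuli_labels(224L, lumen_r = 50, bands = c(
      lapply(arcs, function(a)
        list(class = 5L, r_in = 58, r_out = 80, arc = a)),
      list(list(class = 3L, r_in = 50, r_out = 90))))
    cast_rays(oct_frame(lab, 10), c(111.5, 111.5))
  }
  # contiguous 120-degree pool
  expect_equal(lipid_arc(mk(list(c(30, 150)))), 120, tolerance = 1)
  # two pools 50 and 80 degrees: the larger wins
  expect_equal(lipid_arc(mk(list(c(0, 50), c(120, 200)))), 80,
               tolerance = 1)
  # pool spanning 350 -> 10 degrees: wraparound gives 20, not 350
  expect_equal(lipid_arc(mk(list(c(350, 10)))), 20, tolerance = 1)
  # no lipid
  lab0 <- annuli_labels(224L, lumen_r = 50,
                        bands = list(list(class = 3L, r_in = 50,
                                          r_out = 70)))
  expect_identical(lipid_arc(cast_rays(oct_frame(lab0, 10),
                                       c(111.5, 111.5))), 0)
})

test_that("minimum cap thickness is radial gap times spacing", {
  # 6-pixel gap at 10 um/px -> 60 um within one pixel
  lab <- annuli_labels(224L, lumen_r = 50, bands = list(
    list(class = 3L, r_in = 50, r_out = 56),
    list(class = 5L, r_in = 56, r_out = 80)))
  f <- oct_frame(lab, 10)
  cap <- min_cap_thickness(cast_rays(f, c(111.5, 111.5)), 10)
  expect_true(abs(cap - 60) <= 10)
  # no lipid -> absent
  lab0 <- annuli_labels(224L, lumen_r = 50)
  expect_true(is.na(min_cap_thickness(
    cast_rays(oct_frame(lab0, 10), c(111.5, 111.5)), 10)))
})

test_that("lumen-lipid pixel pairs that touch are ignored in the minimum", {
  # lipid touches the lumen everywhere except a 30-degree sector with an
  # 8-pixel intima gap (plus 3-degree transition bands so boundary rays see
  # one regime or the other cleanly): the touching pairs are 8-connected and
  # must be ignored, leaving 80 um
  lab <- annuli_labels(224L, lumen_r = 50, bands = list(
    list(class = 3L, r_in = 50, r_out = 58, arc = c(357, 33)),
    list(class = 5L, r_in = 58, r_out = 85, arc = c(357, 33)),
    list(class = 5L, r_in = 50, r_out = 85, arc = c(33, 357))))
  f <- oct_frame(lab, 10)
  cap <- min_cap_thickness(cast_rays(f, c(111.5, 111.5)), 10)
  expect_true(abs(cap - 80) <= 10)
})

test_that("quantify_frame composes the measurements on planted geometry", {
  set.seed(41)
  f <- test_frame(120, 50, arc_start_deg = 25)
  m <- quantify_frame(f)
  expect_true(m$analyzable)
  expect_true(abs(m$lipid_arc_deg - 120) <= 2)
  expect_true(abs(m$min_cap_um - 50) <= 10)
  # all-background frame is non-analyzable
  expect_false(quantify_frame(oct_frame(matrix(0L, 64, 64), 10))$analyzable)
  # lipid-free frame: arc 0 and cap absent together
  m0 <- quantify_frame(test_frame(0, 0))
  expect_identical(m0$lipid_arc_deg, 0)
  expect_true(is.na(m0$min_cap_um))
  # full annulus
  m360 <- quantify_frame(test_frame(360, 80))
  expect_equal(m360$lipid_arc_deg, 360)
  expect_true(abs(m360$min_cap_um - 80) <= 10)
})

test_that("measurements agree with the brute-force polar oracle", {
  set.seed(42)
  for (i in 1:12) {
    arc <- runif(1, 0, 360)
    cap <- runif(1, 30, 160)
    f <- test_frame(arc, cap, lumen_r = runif(1, 40, 70),
                    arc_start_deg = runif(1, 0, 360))
    ctr <- lumen_centroid(f)
    m <- quantify_frame(f)
    o <- oracle_arc_cap(f$labels, ctr[1], ctr[2], f$pixel_spacing_um)
    expect_equal(m$lipid_arc_deg, o$arc)
    if (is.na(o$cap)) expect_true(is.na(m$min_cap_um))
    else expect_equal(m$min_cap_um, o$cap)
  }
})

test_that("rotating the planted pool moves the measurement by at most one
           bin / one pixel", {
  set.seed(43)
  base <- quantify_frame(test_frame(117, 54, arc_start_deg = 0))
  for (rot in c(5, 37, 90, 213)) {
    m <- quantify_frame(test_frame(117, 54, arc_start_deg = rot))
    expect_true(abs(m$lipid_arc_deg - base$lipid_arc_deg) <= 1)
    expect_true(abs(m$min_cap_um - base$min_cap_um) <= 10)
  }
})

test_that("doubling grid resolution changes arc by <= 1 degree and cap by
           <= the coarse pixel", {
  set.seed(44)
  coarse <- quantify_frame(generate_frame(
    140, 60, lumen_radius_px = 50, pixel_spacing_um = 20, grid_px = 256L,
    arc_start_deg = 10))
  fine <- quantify_frame(generate_frame(
    140, 60, lumen_radius_px = 100, pixel_spacing_um = 10, grid_px = 512L,
    arc_start_deg = 10))
  expect_true(abs(coarse$lipid_arc_deg - fine$lipid_arc_deg) <= 1)
  expect_true(abs(coarse$min_cap_um - fine$min_cap_um) <= 20)
})

test_that("enlarging the pool or thickening the intima is monotone in the
           measurement", {
  set.seed(45)
  arcs <- c(40, 80, 120, 200, 280)
  got <- vapply(arcs, function(a)
    quantify_frame(test_frame(a, 60, arc_start_deg = 15))$lipid_arc_deg,
    numeric(1))
  expect_true(all(diff(got) >= 0))
  caps <- c(30, 60, 90, 130)
  gotc <- vapply(caps, function(cp)
    quantify_frame(test_frame(120, cp, arc_start_deg = 15))$min_cap_um,
    numeric(1))
  expect_true(all(diff(gotc) >= 0))
})

test_that("guidewire-shadow bins contribute no lipid evidence", {
  set.seed(46)
  f <- test_frame(120, 50, arc_start_deg = 200, guidewire = TRUE)
  # the guidewire sits along +x (bins near 0 degrees); the pool at
  # 200-320 degrees is unaffected
  m <- quantify_frame(f)
  expect_true(abs(m$lipid_arc_deg - 120) <= 2)
  rays <- cast_rays(f, lumen_centroid(f))
  expect_true(any(rays$gw_frac > 0))
})
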