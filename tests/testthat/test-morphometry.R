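# Exhaustive-window oracle used against max_cross_section.
window_scan_oracle <- function(pixels, z_step, z_window) {
  k <- floor(z_window / z_step + 1e-9) + 1
  best <- -1; best_z0 <- NA
  for (z0 in min(pixels[, "z"]):max(pixels[, "z"])) {
    sel <- pixels[, "z"] >= z0 & pixels[, "z"] <= min(z0 + k - 1, max(pixels[, "z"]))
    a <- nrow(unique(pixels[sel, c("y", "x"), drop = FALSE]))
    if (a > best) { best <- a; best_z0 <- z0 }
  }
  list(area = best, z0 = best_z0)
}

test_that("max cross-section scans contiguous z-windows deterministically", {
  # particle confined to one slice: that slice's footprint
  p1 <- cbind(y = c(3L, 3L, 4L), x = c(5L, 6L, 5L), z = c(2L, 2L, 2L))
  mc <- max_cross_section(p1, z_step_um = 0.2, z_window_um = 2)
  expect_identical(mc$area_px, 3L)
  expect_identical(nrow(mc$footprint), 3L)
  # z-window spanning all slices: the full max projection
  p2 <- cbind(y = rep(1:3, 3), x = rep(1:3, each = 3),
              z = rep(1:3, length.out = 9))
  mc2 <- max_cross_section(p2, z_step_um = 0.2, z_window_um = 10)
  expect_identical(mc2$area_px, nrow(unique(p2[, c("y", "x")])))
  # window smaller than slice spacing is an error
  expect_error(max_cross_section(p1, z_step_um = 2, z_window_um = 1),
               "z_window")
})

test_that("max cross-section matches the exhaustive window-scan oracle", {
  # blob widest in slices 4-13 at 0.2 um steps (10 slices = 1.8 um span)
  set.seed(17)
  mk_slice <- function(z, n) cbind(y = sample(1:40, n, TRUE),
                                   x = sample(1:40, n, TRUE),
                                   z = rep(z, n))
  sizes <- c(3, 4, 5, 20, 22, 25, 26, 25, 24, 23, 22, 21, 20, 5, 4)
  pixels <- do.call(rbind, lapply(seq_along(sizes),
                                  function(z) mk_slice(z, sizes[z])))
  mc <- max_cross_section(pixels, z_step_um = 0.2, z_window_um = 2)
  oracle <- window_scan_oracle(pixels, 0.2, 2)
  expect_identical(mc$area_px, as.integer(oracle$area))
  expect_identical(mc$z_range[1], as.integer(oracle$z0))
  # random particles: oracle equivalence across several draws
  for (s in 1:5) {
    set.seed(s)
    px <- do.call(rbind, lapply(1:8, function(z)
      mk_slice(z, sample(3:15, 1))))
    mc <- max_cross_section(px, 0.2, 1.0)
    expect_identical(mc$area_px, as.integer(window_scan_oracle(px, 0.2, 1.0)$area))
  }
})

test_that("nucleator recovers disc areas within quantisation tolerance", {
  px <- 0.1
  # definitional: six measured distances of 1.0 give area pi
  expect_equal(nucleator_from_radii(rep(1, 6))$area_um2, pi)
  # disc of radius 2 um: area within one pixel of radius quantisation
  m <- raster_disc(2.0, px)
  est <- vapply(seq(0, pi / 3, length.out = 8),
                function(a) nucleator_area(m, px, start_angle = a)$area_um2, 0)
  expect_lt(abs(mean(est) - pi * 4), 2 * pi * 2.0 * px)   # dA for dr = 1 px
  # within 2 pixel-areas for radii of 3, 5 and 8 pixels (start-angle mean)
  for (r_px in c(3, 5, 8)) {
    r <- r_px * px
    m <- raster_disc(r, px)
    est <- vapply(seq(0, pi / 3, length.out = 16),
                  function(a) nucleator_area(m, px, start_angle = a)$area_um2, 0)
    expect_lt(abs(mean(est) - pi * r^2), 2 * px^2)
  }
})

test_that("nucleator on a 2:1 ellipse matches the exact estimator expectation", {
  # closed-form oracle: E over start angle of pi * (mean of 6 radii)^2 for
  # the continuous ellipse r(phi) = 1 / sqrt(cos^2/a^2 + sin^2/b^2)
  a <- 2; b <- 1
  r_ell <- function(phi) 1 / sqrt(cos(phi)^2 / a^2 + sin(phi)^2 / b^2)
  st <- seq(0, pi / 3, length.out = 4001)[-4001]
  oracle <- mean(vapply(st, function(s) pi * mean(r_ell(s + (0:5) * pi / 3))^2, 0))
  px <- 0.1
  m <- raster_ellipse(a, b, px)
  est <- vapply(seq(0, 2 * pi, length.out = 9)[-9],
                function(aa) nucleator_area(m, px, start_angle = aa)$area_um2, 0)
  expect_lt(abs(mean(est) - oracle) / oracle, 0.03)
  # the published pi * mean(r)^2 form underestimates elongated profiles;
  # agreement with the true ellipse area is correspondingly looser
  expect_lt(abs(mean(est) - pi * a * b) / (pi * a * b), 0.10)
})

test_that("highly concave footprints are flagged but still measured", {
  # C-shape whose centroid falls in the mouth
  m <- matrix(FALSE, 30, 30)
  m[5:25, 5:8] <- TRUE; m[5:8, 5:25] <- TRUE; m[22:25, 5:25] <- TRUE
  res <- nucleator_area(m, 0.1, start_angle = 0.3)
  expect_false(res$center_inside)
  expect_true(is.finite(res$area_um2) && res$area_um2 > 0)
})

test_that("size-transition detection reproduces the worked derivative example", {
  st <- detect_size_threshold(c(0.2, 0.3, 0.4, 1.0, 1.1, 1.2), k = 3)
  expect_equal(st$derivative, c(0.1, 0.1, 0.6, 0.1, 0.1))
  expect_equal(st$mean_derivative, 0.2)
  expect_equal(st$peak, 0.6)
  expect_equal(st$threshold_um2, 0.7)
  # uniform spacing: peak equals the mean, no transition at k = 3
  st2 <- detect_size_threshold(c(1, 2, 3, 4), k = 3)
  expect_true(is.na(st2$threshold_um2))
  # degenerate inputs
  expect_error(detect_size_threshold(c(1, 2)), "at least 3")
  expect_true(is.na(detect_size_threshold(rep(2, 5))$threshold_um2))
})

test_that("the transition rule is scale- and translation-equivariant and permutation-invariant", {
  set.seed(23)
  areas <- c(runif(40, 0.2, 0.8), runif(60, 1.0, 4.0))
  st <- detect_size_threshold(areas)
  # permutation invariance
  expect_equal(detect_size_threshold(sample(areas))$threshold_um2,
               st$threshold_um2)
  # scaling by c > 0 scales the threshold by c
  for (cc in c(0.5, 3.7)) {
    expect_equal(detect_size_threshold(cc * areas)$threshold_um2,
                 cc * st$threshold_um2)
  }
  # adding a constant shifts the threshold by the same constant
  expect_equal(detect_size_threshold(areas + 2.5)$threshold_um2,
               st$threshold_um2 + 2.5)
})

test_that("size classification is strict at the threshold", {
  expect_identical(classify_by_size(c(0.88, 4.76, 0.1), 0.88),
                   c("fiber", "terminal", "fiber"))
  expect_identical(classify_by_size(numeric(0), 0.88), character(0))
  expect_error(classify_by_size(1, NA_real_), "undefined")
})
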