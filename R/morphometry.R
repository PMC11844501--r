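# Nucleator morphometry and the fiber/terminal size-transition rule.

#' Largest cross-section of a volumetric particle within a z-window
#'
#' Scans all contiguous windows of optical slices spanning at most
#' `z_window_um` and returns the maximum-projection footprint (the set of
#' distinct (y, x) pixels) with the largest area. Ties are broken towards
#' the smallest starting slice, making the result deterministic.
#'
#' @param pixels Integer matrix of (y, x, z) voxel indices (one particle).
#' @param z_step_um Slice spacing (um).
#' @param z_window_um Maximum window span (um); must be >= `z_step_um`.
#' @return List: `footprint` ((y, x) matrix), `area_px`, `z_range`
#'   (first and last slice of the chosen window).
#' @export
max_cross_section <- function(pixels, z_step_um, z_window_um = 2.0) {
  if (z_window_um < z_step_um) stop("z_window_um must be >= z_step_um")
  if (!is.matrix(pixels) || !("z" %in% colnames(pixels))) {
    pixels <- cbind(pixels, z = 1L)   # planar particle: single-slice support
  }
  zmin <- min(pixels[, "z"]); zmax <- max(pixels[, "z"])
  nwin <- floor(z_window_um / z_step_um + 1e-9) + 1L   # slices per window
  best <- NULL; best_area <- -1L; best_z0 <- NA_integer_
  for (z0 in zmin:zmax) {
    z1 <- min(z0 + nwin - 1L, zmax)
    sel <- pixels[, "z"] >= z0 & pixels[, "z"] <= z1
    if (!any(sel)) next
    fp <- unique(pixels[sel, c("y", "x"), drop = FALSE])
    if (nrow(fp) > best_area) {
      best <- fp; best_area <- nrow(fp); best_z0 <- z0
      best_z1 <- z1
    }
    if (z1 == zmax && z0 == zmin) break   # one window already covers everything
  }
  list(footprint = best, area_px = best_area,
       z_range = as.integer(c(best_z0, best_z1)))
}

#' Nucleator area estimate of a footprint
#'
#' The classical nucleator probe applied to a 2-D footprint: from the
#' footprint centroid, `ray_count` equally spaced rays are cast and the
#' distance from the centre to the last foreground pixel along each ray is
#' recorded; the profile area is `pi * mean(r)^2`. With 6 rays this is the
#' mean of 6 centre-to-edge distances. The start angle is random by
#' default (isotropic, hence unbiased in orientation); pass `start_angle`
#' for reproducible measurements.
#'
#' Highly concave footprints whose centroid falls outside the foreground
#' are flagged (`center_inside = FALSE`); the area is still returned.
#'
#' @param footprint Integer matrix of (y, x) pixel indices, or a logical
#'   matrix mask.
#' @param pixel_um Pixel edge length (um).
#' @param ray_count Number of rays (>= 2; default 6).
#' @param start_angle Angle of the first ray (radians); `NULL` draws one
#'   uniformly from the current RNG stream.
#' @return List of class `nucleator_measurement`: `center_um`, `radii_um`,
#'   `r_mean_um`, `area_um2`, `center_inside`, `start_angle`.
#' @export
nucleator_area <- function(footprint, pixel_um, ray_count = 6L,
                           start_angle = NULL) {
  if (is.logical(footprint)) {
    idx <- which(footprint)
    footprint <- cbind(y = ((idx - 1L) %% nrow(footprint)) + 1L,
                       x = ((idx - 1L) %/% nrow(footprint)) + 1L)
  }
  if (!nrow(footprint)) stop("empty footprint")
  if (ray_count < 2L) stop("ray_count must be >= 2")
  if (is.null(start_angle)) start_angle <- stats::runif(1, 0, 2 * pi)
  ys <- footprint[, 1]; xs <- footprint[, 2]
  y0 <- min(ys) - 1L; x0 <- min(xs) - 1L
  m <- matrix(FALSE, max(ys) - y0, max(xs) - x0)
  m[cbind(ys - y0, xs - x0)] <- TRUE
  # centroid in um (pixel centres at (index - 0.5) * pixel)
  cx <- (mean(xs) - 0.5) * pixel_um
  cy <- (mean(ys) - 0.5) * pixel_um
  ci <- floor(cy / pixel_um) + 1L - y0
  cj <- floor(cx / pixel_um) + 1L - x0
  center_inside <- ci >= 1 && ci <= nrow(m) && cj >= 1 && cj <= ncol(m) && m[ci, cj]
  tmax <- (sqrt(nrow(m)^2 + ncol(m)^2) + 2) * pixel_um
  step <- pixel_um / 10
  tt <- seq(0, tmax, by = step)
  angles <- start_angle + 2 * pi * (seq_len(ray_count) - 1L) / ray_count
  radii <- vapply(angles, function(a) {
    sx <- cx + tt * cos(a); sy <- cy + tt * sin(a)
    j <- floor(sx / pixel_um) + 1L - x0
    i <- floor(sy / pixel_um) + 1L - y0
    ok <- i >= 1 & i <= nrow(m) & j >= 1 & j <= ncol(m)
    ok[ok] <- m[cbind(i[ok], j[ok])]
    if (!any(ok)) return(0)
    # half-step correction: the true exit lies between the last inside
    # sample and the next one
    tt[max(which(ok))] + step / 2
  }, 0)
  r_mean <- mean(radii)
  structure(list(center_um = c(x = cx, y = cy), radii_um = radii,
                 r_mean_um = r_mean, area_um2 = pi * r_mean^2,
                 center_inside = center_inside, start_angle = start_angle),
            class = "nucleator_measurement")
}

#' Nucleator area from measured ray distances
#'
#' Definitional form: `A = pi * mean(r)^2` for a set of centre-to-edge
#' distances.
#'
#' @param radii_um Non-negative distances (um).
#' @return A `nucleator_measurement` (without geometry fields).
#' @export
nucleator_from_radii <- function(radii_um) {
  stopifnot(all(radii_um >= 0))
  r_mean <- mean(radii_um)
  structure(list(center_um = NULL, radii_um = radii_um, r_mean_um = r_mean,
                 area_um2 = pi * r_mean^2, center_inside = NA,
                 start_angle = NA_real_),
            class = "nucleator_measurement")
}

#' @export
print.nucleator_measurement <- function(x, ...) {
  cat(sprintf("<nucleator: r = %.3f um over %d rays, area = %.4f um^2%s>\n",
              x$r_mean_um, length(x$radii_um), x$area_um2,
              if (isFALSE(x$center_inside)) " [center outside footprint]" else ""))
  invisible(x)
}

#' Detect the fiber/terminal size-transition point
#'
#' Sorts the measured areas ascending and takes adjacent differences (the
#' "derivative" of the sorted size distribution). A difference of at
#' least `k` times the mean difference marks a sharp jump; the transition
#' point is the midpoint of the two areas flanking the selected jump.
#' When no difference reaches `k` times the mean, no transition is
#' declared. The rule separates the small fiber-of-passage mode from the
#' larger putative axon-terminal mode of the size distribution.
#'
#' Two selection rules are provided. The default, `"first"`, takes the
#' first difference reaching `k` times the mean -- the first sharp jump in
#' the sorted-size plot, which is where the fiber mode ends. `"max"`
#' takes the globally largest difference (first index on ties) provided
#' it reaches `k` times the mean. With realistic right-tailed terminal
#' sizes the largest spacing often lies between the few largest processes
#' rather than at the class boundary, so the global maximum can misfire
#' into the tail; the first-jump rule is the one under which per-image
#' thresholds concentrate in the reported fiber/terminal gap.
#'
#' @param areas Numeric vector of measured areas (um^2), length >= 3.
#' @param k Peak ratio (default 3: a jump counts only when it is at least
#'   3 times the mean derivative).
#' @param rule `"first"` (default) or `"max"`, see Details.
#' @return A list of class `size_threshold`: `areas_sorted`, `derivative`,
#'   `peak`, `peak_index`, `mean_derivative`, `peak_ratio`,
#'   `threshold_um2` (`NA` when no transition), `k`, `rule`, `n`.
#' @export
detect_size_threshold <- function(areas, k = 3, rule = c("first", "max")) {
  rule <- match.arg(rule)
  if (length(areas) < 3) stop("need at least 3 areas")
  if (any(!is.finite(areas))) stop("areas must be finite")
  a <- sort(areas)
  d <- diff(a)
  md <- mean(d)
  if (md == 0) {   # all areas equal: flat distribution, no change-point
    res <- list(areas_sorted = a, derivative = d, peak = 0,
                peak_index = NA_integer_, mean_derivative = 0,
                peak_ratio = NA_real_, threshold_um2 = NA_real_,
                k = k, rule = rule, n = length(a))
    return(structure(res, class = "size_threshold"))
  }
  qualifying <- which(d >= k * md - 1e-9)   # fp-safe at exact k x mean
  i <- if (rule == "first") qualifying[1] else {
    im <- which.max(d)                      # first occurrence on ties
    if (im %in% qualifying) im else NA_integer_
  }
  if (is.na(i)) {
    im <- which.max(d)
    return(structure(list(areas_sorted = a, derivative = d, peak = d[im],
                          peak_index = im, mean_derivative = md,
                          peak_ratio = d[im] / md, threshold_um2 = NA_real_,
                          k = k, rule = rule, n = length(a)),
                     class = "size_threshold"))
  }
  structure(list(areas_sorted = a, derivative = d, peak = d[i],
                 peak_index = i, mean_derivative = md, peak_ratio = d[i] / md,
                 threshold_um2 = (a[i] + a[i + 1]) / 2, k = k, rule = rule,
                 n = length(a)),
            class = "size_threshold")
}

#' @export
print.size_threshold <- function(x, ...) {
  if (is.na(x$threshold_um2))
    cat(sprintf("<size_threshold: no transition (peak ratio %.2f < k = %g, n = %d)>\n",
                x$peak_ratio, x$k, x$n))
  else
    cat(sprintf("<size_threshold: %.4f um^2 (peak %.4f = %.1f x mean derivative, n = %d)>\n",
                x$threshold_um2, x$peak, x$peak_ratio, x$n))
  invisible(x)
}

#' Classify measured areas as fibers or putative terminals
#'
#' A process is a putative axon terminal if and only if its area strictly
#' exceeds the size-transition threshold; an area exactly at the threshold
#' is a fiber.
#'
#' @param areas Numeric vector (um^2).
#' @param threshold Size-transition point (um^2), or a `size_threshold`.
#' @return Character vector of `"fiber"` / `"terminal"`.
#' @export
classify_by_size <- function(areas, threshold) {
  if (inherits(threshold, "size_threshold")) threshold <- threshold$threshold_um2
  if (is.na(threshold)) stop("threshold is undefined (no transition detected)")
  if (!length(areas)) return(character(0))
  ifelse(areas > threshold, "terminal", "fiber")
}
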