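# Synthetic scene rendering.
#
# Terminals are rendered as 3-D Gaussian blobs whose in-plane sigma is set
# so that the area enclosed by the half-maximum isophote equals the drawn
# true area (area = 2*pi*log(2)*sigma^2), which makes "true area"
# operationally measurable. Fibers are short, slightly wavy constant-
# intensity segments whose stamped footprint area equals the drawn true
# area (length = area / width). VGLUT channels receive a co-localized blob
# at every terminal positive for that channel, plus independent background
# puncta. All randomness flows from the single seed in the spec.

SCENE_CHANNELS <- c("NP", "VGLUT1", "VGLUT2", "DAPI")

#' Render a synthetic section from a scene specification
#'
#' Produces a four-channel stack (`NP`, `VGLUT1`, `VGLUT2`, `DAPI`), the
#' layer map, and a complete ground-truth table with one row per rendered
#' neuropeptide object (true centre, true area, fiber/terminal class,
#' layer, VGLUT category). The ground truth additionally carries the
#' realized per-layer density and the true size-transition point (the
#' midpoint of the fiber/terminal support gap) as attributes.
#'
#' @param spec A [scene_spec()].
#' @param preparation,section,bregma_mm Section metadata recorded in the
#'   stack.
#' @return A list of class `scene` with elements `stack`
#'   ([section_stack()]), `layers` ([layer_map()]) and `truth` (tibble).
#' @export
render_section <- function(spec, preparation = "prep1", section = 1L,
                           bregma_mm = NA_real_) {
  spec <- validate_scene_spec(spec)
  set.seed(spec$seed)
  nz <- spec$shape[1]; ny <- spec$shape[2]; nx <- spec$shape[3]
  px <- spec$pixel_um; zs <- spec$z_step_um
  depth_um <- nz * zs
  geom <- spec$geometry
  cats <- c("1-/2-", "1+/2-", "1-/2+", "1+/2+")

  # --- draw objects layer by layer -----------------------------------------
  rows <- list()
  placed <- matrix(numeric(0), 0, 2)
  for (li in seq_len(nrow(geom))) {
    lay <- geom$layer[li]
    lambda <- spec$intensity[[lay]] * geom$area_mm2[li]
    n <- stats::rpois(1L, lambda)
    if (n == 0L) next
    pos <- place_separated(n, geom$polygon[[li]], spec$min_separation_um, placed)
    placed <- rbind(placed, pos)
    w <- spec$size_mixture$weight_fiber
    is_fiber <- stats::runif(n) < w
    area <- ifelse(is_fiber,
                   stats::runif(n, spec$size_mixture$fiber[1], spec$size_mixture$fiber[2]),
                   stats::runif(n, spec$size_mixture$terminal[1], spec$size_mixture$terminal[2]))
    category <- rep(NA_character_, n)
    n_term <- sum(!is_fiber)
    if (n_term > 0)
      category[!is_fiber] <- sample(cats, n_term, replace = TRUE, prob = spec$coloc)
    z_um <- stats::runif(n, 0.2 * depth_um, 0.8 * depth_um)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      layer = lay, x_um = pos[, "x"], y_um = pos[, "y"], z_um = z_um,
      class = ifelse(is_fiber, "fiber", "terminal"),
      area_um2 = area, category = category)
  }
  truth <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(layer = character(), x_um = numeric(), y_um = numeric(),
                   z_um = numeric(), class = character(), area_um2 = numeric(),
                   category = character())
  if (nrow(truth)) truth <- dplyr::mutate(truth, id = dplyr::row_number(), .before = 1)
  else truth$id <- integer()

  # --- render signal -------------------------------------------------------
  np <- array(0, c(ny, nx, nz))
  v1 <- array(0, c(ny, nx, nz))
  v2 <- array(0, c(ny, nx, nz))
  amp <- spec$amplitudes
  sigma_z_um <- 0.25

  # patches are computed per object and added in this frame so the big
  # channel arrays are modified in place rather than copied per object
  dm <- c(ny, nx, nz)
  cls <- truth$class; cat_ <- truth$category
  for (i in seq_len(nrow(truth))) {
    if (!is.na(cls[i]) && cls[i] == "terminal") {
      sigma_um <- sqrt(truth$area_um2[i] / (2 * pi * log(2)))
      for (p in blob_patches(dm, truth$x_um[i], truth$y_um[i], truth$z_um[i],
                             sigma_um, sigma_z_um, amp$terminal, px, zs))
        np[p$i0:p$i1, p$j0:p$j1, p$k] <- np[p$i0:p$i1, p$j0:p$j1, p$k] + p$values
      pos1 <- cat_[i] %in% c("1+/2-", "1+/2+")
      pos2 <- cat_[i] %in% c("1-/2+", "1+/2+")
      if (pos1)
        for (p in blob_patches(dm, truth$x_um[i] + stats::rnorm(1, 0, 0.05),
                               truth$y_um[i] + stats::rnorm(1, 0, 0.05),
                               truth$z_um[i], sigma_um * stats::runif(1, 0.9, 1.1),
                               sigma_z_um, amp$vglut, px, zs))
          v1[p$i0:p$i1, p$j0:p$j1, p$k] <- v1[p$i0:p$i1, p$j0:p$j1, p$k] + p$values
      if (pos2)
        for (p in blob_patches(dm, truth$x_um[i] + stats::rnorm(1, 0, 0.05),
                               truth$y_um[i] + stats::rnorm(1, 0, 0.05),
                               truth$z_um[i], sigma_um * stats::runif(1, 0.9, 1.1),
                               sigma_z_um, amp$vglut, px, zs))
          v2[p$i0:p$i1, p$j0:p$j1, p$k] <- v2[p$i0:p$i1, p$j0:p$j1, p$k] + p$values
    } else {
      for (p in fiber_patches(dm, truth$x_um[i], truth$y_um[i], truth$z_um[i],
                              truth$area_um2[i], spec$fiber_width_um,
                              amp$fiber, px, zs)) {
        blk <- np[p$i0:p$i1, p$j0:p$j1, p$k]
        blk[p$hit] <- pmax(blk[p$hit], p$amp)
        np[p$i0:p$i1, p$j0:p$j1, p$k] <- blk
      }
    }
  }

  # independent VGLUT background puncta (not tied to any terminal)
  field_um2 <- (ny * px) * (nx * px)
  for (ch in 1:2) {
    nbg <- stats::rpois(1L, spec$vglut_background_per_um2 * field_um2)
    if (nbg > 0) {
      bx <- stats::runif(nbg, 0, nx * px); by <- stats::runif(nbg, 0, ny * px)
      bz <- stats::runif(nbg, 0.2 * depth_um, 0.8 * depth_um)
      for (b in seq_len(nbg)) {
        for (p in blob_patches(dm, bx[b], by[b], bz[b], 0.25, sigma_z_um,
                               amp$vglut, px, zs)) {
          if (ch == 1)
            v1[p$i0:p$i1, p$j0:p$j1, p$k] <- v1[p$i0:p$i1, p$j0:p$j1, p$k] + p$values
          else
            v2[p$i0:p$i1, p$j0:p$j1, p$k] <- v2[p$i0:p$i1, p$j0:p$j1, p$k] + p$values
        }
      }
    }
  }

  # DAPI: flat tissue fill inside the union of the layer polygons
  tissue <- matrix(FALSE, ny, nx)
  for (li in seq_len(nrow(geom)))
    tissue <- tissue | rasterize_polygon(geom$polygon[[li]], ny, nx, px)
  dapi_sig <- amp$dapi_tissue * tissue

  # --- noise and quantisation ---------------------------------------------
  data <- array(0, c(ny, nx, nz, 4L))
  sig_of <- function(ch, k) switch(ch, NP = np[, , k], VGLUT1 = v1[, , k],
                                   VGLUT2 = v2[, , k], DAPI = dapi_sig)
  for (ci in seq_along(SCENE_CHANNELS)) {
    for (k in seq_len(nz)) {
      lam <- spec$noise$background + sig_of(SCENE_CHANNELS[ci], k)
      v <- if (isTRUE(spec$noise$poisson)) stats::rpois(length(lam), lam) else lam
      v <- v + stats::rnorm(length(lam), 0, spec$noise$gaussian_sd)
      data[, , k, ci] <- matrix(pmin(pmax(round(v), 0), 65535), ny, nx)
    }
  }

  stack <- section_stack(data, SCENE_CHANNELS, px, zs,
                         meta = list(preparation = preparation,
                                     bregma_mm = bregma_mm,
                                     section = as.integer(section)))

  dens <- dplyr::left_join(
    tibble::tibble(layer = geom$layer, area_mm2 = geom$area_mm2),
    dplyr::count(truth, .data$layer, name = "count"), by = "layer")
  dens$count[is.na(dens$count)] <- 0L
  dens$density_per_mm2 <- dens$count / dens$area_mm2
  attr(truth, "density") <- dens
  attr(truth, "transition_um2") <-
    if (isTRUE(spec$size_mixture$separable))
      (max(spec$size_mixture$fiber) + min(spec$size_mixture$terminal)) / 2
    else NA_real_

  structure(list(stack = stack, layers = geom, truth = truth, spec = spec),
            class = "scene")
}

# Dart-throwing placement: n uniform points in the polygon, each at least
# min_sep from every previously accepted point (scene-wide). Counts are
# drawn before placement, so per-layer counts stay exactly Poisson; after
# 200 failed attempts a point is accepted regardless (dense scenes).
place_separated <- function(n, poly, min_sep, existing) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  if (min_sep <= 0) return(sample_in_polygon(n, poly))
  pts <- existing
  out <- matrix(0, n, 2)
  for (i in seq_len(n)) {
    for (attempt in seq_len(200L)) {
      cand <- sample_in_polygon(1L, poly)
      ok <- !nrow(pts) ||
        min((pts[, 1] - cand[1, 1])^2 + (pts[, 2] - cand[1, 2])^2) >= min_sep^2
      if (ok || attempt == 200L) break
    }
    out[i, ] <- cand
    pts <- rbind(pts, cand)
  }
  colnames(out) <- c("x", "y")
  out
}

# Patches for a 3-D Gaussian blob. Peak amplitude `amp` is attained at the
# blob centre on its best slice; in-plane sigma is floored at 0.8 px so
# that coarse-calibration scenes still render a resolvable footprint
# (emulating PSF blur at low magnification). Returns a list of additive
# patches {i0,i1,j0,j1,k,values}; the caller adds them in place.
blob_patches <- function(dm, x_um, y_um, z_um, sigma_um, sigma_z_um, amp, px, zs) {
  ny <- dm[1]; nx <- dm[2]; nz <- dm[3]
  sx <- max(sigma_um / px, 1.0)
  cx <- x_um / px + 0.5; cy <- y_um / px + 0.5   # 1-based pixel-centre coords
  r <- ceiling(4 * sx)
  j0 <- max(1L, floor(cx) - r); j1 <- min(nx, floor(cx) + r)
  i0 <- max(1L, floor(cy) - r); i1 <- min(ny, floor(cy) + r)
  if (j0 > j1 || i0 > i1) return(list())
  gx <- exp(-((j0:j1) - cx)^2 / (2 * sx^2))
  gy <- exp(-((i0:i1) - cy)^2 / (2 * sx^2))
  zc_um <- (seq_len(nz) - 0.5) * zs
  wz <- exp(-(zc_um - z_um)^2 / (2 * sigma_z_um^2))
  wz <- wz / max(wz)
  patch <- outer(gy, gx)
  lapply(which(wz > 1e-3), function(k)
    list(i0 = i0, i1 = i1, j0 = j0, j1 = j1, k = k,
         values = amp * wz[k] * patch))
}

# Patches for a short, slightly wavy constant-intensity fiber segment.
# The stamped footprint area approximates the drawn true area
# (length = area / width), at the drawn z-slice only. Returns max-patches
# {i0,i1,j0,j1,k,hit,amp}.
fiber_patches <- function(dm, x_um, y_um, z_um, area_um2, width_um, amp, px, zs) {
  ny <- dm[1]; nx <- dm[2]; nz <- dm[3]
  len_um <- area_um2 / width_um
  ds <- 0.1
  nstep <- max(2L, ceiling(len_um / ds))
  heading <- stats::runif(1, 0, 2 * pi) + cumsum(stats::rnorm(nstep, 0, 0.35))
  xs <- x_um + cumsum(ds * cos(heading)); xs <- xs - mean(xs) + x_um
  ys <- y_um + cumsum(ds * sin(heading)); ys <- ys - mean(ys) + y_um
  k <- min(nz, max(1L, round(z_um / zs + 0.5)))
  r_px <- max(width_um / 2 / px, 1.05)
  cr <- ceiling(r_px)
  out <- vector("list", nstep)
  for (p in seq_len(nstep)) {
    cxp <- xs[p] / px + 0.5; cyp <- ys[p] / px + 0.5
    j0 <- max(1L, floor(cxp) - cr); j1 <- min(nx, floor(cxp) + cr)
    i0 <- max(1L, floor(cyp) - cr); i1 <- min(ny, floor(cyp) + cr)
    if (j0 > j1 || i0 > i1) next
    dj <- (j0:j1) - cxp; di <- (i0:i1) - cyp
    hit <- outer(di^2, dj^2, "+") <= r_px^2
    out[[p]] <- list(i0 = i0, i1 = i1, j0 = j0, j1 = j1, k = k,
                     hit = hit, amp = amp)
  }
  out[!vapply(out, is.null, TRUE)]
}

#' @export
print.scene <- function(x, ...) {
  cat("<scene> ")
  print(x$stack)
  cat(sprintf("  %d ground-truth objects (%d terminals, %d fibers)\n",
              nrow(x$truth), sum(x$truth$class == "terminal"),
              sum(x$truth$class == "fiber")))
  invisible(x)
}
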