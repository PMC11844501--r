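#' Synthetic scene specifications
#'
#' A `scene_spec` fully determines a synthetic multichannel section: image
#' shape, physical calibration, layer geometry, per-layer object intensity
#' for the neuropeptide channel, the fiber/terminal size mixture, the
#' VGLUT co-localization category mixture, noise, and a seed. Rendering the
#' same spec twice yields bit-identical stacks.
#'
#' Category labels follow the four-way VGLUT1/VGLUT2 convention:
#' `1-/2-` (neither), `1+/2-` (VGLUT1 only), `1-/2+` (VGLUT2 only),
#' `1+/2+` (both).
#'
#' @param shape Integer c(z, y, x) in voxels.
#' @param pixel_um Pixel edge length (um). Default 0.65 (implied by the
#'   2-pixel = 0.845 um^2 size floor of the tiled regime).
#' @param z_step_um Z-step (um): 2.0 for tiled scenes, 0.2 for
#'   high-resolution scenes.
#' @param geometry A [layer_map()] giving the layer polygons.
#' @param intensity Named numeric, expected objects per mm^2 in each layer
#'   of `geometry` (neuropeptide channel).
#' @param size_mixture List with elements `fiber = c(min, max)`,
#'   `terminal = c(min, max)` (uniform supports, um^2), `weight_fiber` in
#'   \[0, 1\], and `separable` (logical; when TRUE the supports must be
#'   disjoint with fiber max < terminal min).
#' @param coloc Named probabilities over the four categories; must be
#'   non-negative and sum to 1 (1e-9 tolerance).
#' @param noise List: `background` (AU), `gaussian_sd` (AU), `poisson`
#'   (logical).
#' @param amplitudes List of rendered signal amplitudes (AU above
#'   background): `terminal`, `fiber`, `vglut`, `dapi_tissue`.
#' @param vglut_background_per_um2 Density of independent background puncta
#'   in each VGLUT channel (objects per um^2).
#' @param fiber_width_um Rendered fiber width (um).
#' @param min_separation_um Minimum centre-to-centre distance between
#'   rendered neuropeptide objects (um). Keeps distinct processes
#'   resolvable, emulating the manual "clearly labeled" inclusion
#'   criterion; object counts remain exactly Poisson (counts are drawn
#'   first, positions placed by dart throwing).
#' @param seed Integer seed; all randomness in rendering flows from it.
#' @return A validated list of class `scene_spec`.
#' @export
scene_spec <- function(shape, pixel_um = 0.65, z_step_um = 2.0,
                       geometry = ob_layer_geometry(),
                       intensity = c(GL = 38, EPL = 84.4, MCL = 161.4, GCL = 306.4),
                       size_mixture = list(fiber = c(0.18, 0.80),
                                           terminal = c(0.96, 4.76),
                                           weight_fiber = 1 / 3,
                                           separable = TRUE),
                       coloc = c("1-/2-" = 1, "1+/2-" = 0, "1-/2+" = 0, "1+/2+" = 0),
                       noise = list(background = 100, gaussian_sd = 10, poisson = TRUE),
                       amplitudes = list(terminal = 3000, fiber = 1500,
                                         vglut = 2500, dapi_tissue = 300),
                       vglut_background_per_um2 = 0.005,
                       fiber_width_um = 0.3,
                       min_separation_um = 4,
                       seed = 1L) {
  spec <- structure(
    list(shape = as.integer(shape), pixel_um = pixel_um, z_step_um = z_step_um,
         geometry = geometry, intensity = intensity,
         size_mixture = size_mixture, coloc = coloc, noise = noise,
         amplitudes = amplitudes,
         vglut_background_per_um2 = vglut_background_per_um2,
         fiber_width_um = fiber_width_um,
         min_separation_um = min_separation_um, seed = as.integer(seed)),
    class = "scene_spec")
  validate_scene_spec(spec)
}

validate_scene_spec <- function(spec) {
  if (length(spec$shape) != 3L || any(spec$shape < 1L))
    stop("scene_spec invariant violated: shape must be positive c(z, y, x)")
  if (spec$pixel_um <= 0 || spec$z_step_um <= 0)
    stop("scene_spec invariant violated: calibration must be positive")
  if (!inherits(spec$geometry, "layer_map"))
    stop("scene_spec invariant violated: geometry must be a layer_map")
  if (!all(spec$geometry$layer %in% names(spec$intensity)))
    stop("scene_spec invariant violated: intensity missing for some layers")
  if (any(spec$intensity < 0))
    stop("scene_spec invariant violated: intensities must be >= 0")
  cats <- c("1-/2-", "1+/2-", "1-/2+", "1+/2+")
  if (!identical(sort(names(spec$coloc)), sort(cats)))
    stop("scene_spec invariant violated: coloc must name the four categories")
  if (any(spec$coloc < 0) || abs(sum(spec$coloc) - 1) > 1e-9)
    stop("scene_spec invariant violated: category probabilities must be >= 0 and sum to 1")
  sm <- spec$size_mixture
  if (!(sm$weight_fiber >= 0 && sm$weight_fiber <= 1))
    stop("scene_spec invariant violated: weight_fiber must be in [0, 1]")
  if (any(sm$fiber <= 0) || any(sm$terminal <= 0))
    stop("scene_spec invariant violated: size supports must be positive")
  if (isTRUE(sm$separable) && max(sm$fiber) >= min(sm$terminal))
    stop("scene_spec invariant violated: separable mixture requires fiber support max < terminal support min")
  if (spec$min_separation_um < 0)
    stop("scene_spec invariant violated: min_separation_um must be >= 0")
  # geometry invariants (simplicity, non-overlap) are enforced by layer_map()
  spec
}

#' Orexin-A-like and MCH-like study mixtures
#'
#' Canonical generative mixtures used throughout the package's benchmarks.
#' The orexin-A-like size mixture spans the reported 0.18-4.76 um^2 process
#' range with a fiber/terminal gap whose midpoint sits at 0.88 um^2; the
#' MCH-like mixture is the same geometry scaled by 0.73/0.88 so its gap
#' midpoint sits at 0.73 um^2. Category probabilities follow the reported
#' four-way VGLUT proportions: for the orexin-A-like mixture the three
#' VGLUT-positive probabilities are 0.063, 0.394 and 0.177 with the
#' remainder assigned to 1-/2-; the MCH-like mixture uses
#' 0.719/0.026/0.252/0.003 (dual-positive terminals are rare and excluded
#' from MCH summaries downstream).
#'
#' @param profile `"orexin"` or `"mch"`.
#' @return List with `size_mixture` and `coloc` entries suitable for
#'   [scene_spec()].
#' @export
study_mixture <- function(profile = c("orexin", "mch")) {
  profile <- match.arg(profile)
  if (profile == "orexin") {
    list(
      size_mixture = list(fiber = c(0.18, 0.80), terminal = c(0.96, 4.76),
                          weight_fiber = 0.45, separable = TRUE),
      coloc = c("1-/2-" = 0.366, "1+/2-" = 0.063, "1-/2+" = 0.394, "1+/2+" = 0.177)
    )
  } else {
    s <- 0.73 / 0.88
    list(
      size_mixture = list(fiber = c(0.18, 0.80) * s, terminal = c(0.96, 4.76) * s,
                          weight_fiber = 0.6, separable = TRUE),
      coloc = c("1-/2-" = 0.719, "1+/2-" = 0.026, "1-/2+" = 0.252, "1+/2+" = 0.003)
    )
  }
}

#' Spec for a tiled (20x-like) density scene
#'
#' Whole-section scene at the tiled-acquisition calibration (0.65 um pixels,
#' 2 um z-steps): four nested annular layers with per-layer intensities
#' defaulting to the reported MCH layer densities, rendered over a shallow
#' three-slice slab.
#'
#' @param intensity Objects per mm^2 per layer.
#' @param geometry Layer map (defaults to [ob_layer_geometry()]).
#' @param profile Study mixture for object sizes/categories.
#' @param nz Number of z-slices.
#' @param seed Seed.
#' @param ... Passed on to [scene_spec()].
#' @export
tiled_scene_spec <- function(intensity = c(GL = 38, EPL = 84.4, MCL = 161.4, GCL = 306.4),
                             geometry = ob_layer_geometry(),
                             profile = "mch", nz = 3L, seed = 1L, ...) {
  mix <- study_mixture(profile)
  bb <- apply(geometry$polygon[[1]]$outer, 2, max)
  margin_px <- 10
  nx <- ceiling(bb[1] / 0.65) + margin_px
  ny <- ceiling(bb[2] / 0.65) + margin_px
  scene_spec(shape = c(nz, ny, nx), pixel_um = 0.65, z_step_um = 2.0,
             geometry = geometry, intensity = intensity,
             size_mixture = mix$size_mixture, coloc = mix$coloc, seed = seed, ...)
}

#' Spec for a high-resolution (100x-like) co-localization scene
#'
#' Single-layer field at the high-resolution calibration (0.1 um pixels,
#' 0.2 um z-steps, five optical slices). The field is sized so that the
#' expected terminal density stays near 0.006 terminals/um^2, keeping
#' object merging rare while matching the requested expected terminal
#' count.
#'
#' @param n_terminals Expected number of terminals in the field.
#' @param profile `"orexin"` or `"mch"` study mixture.
#' @param layer Which OB layer the field samples.
#' @param seed Seed.
#' @param ... Passed on to [scene_spec()].
#' @export
highres_scene_spec <- function(n_terminals = 40, profile = "orexin",
                               layer = "GCL", seed = 1L, ...) {
  mix <- study_mixture(profile)
  side_um <- sqrt(n_terminals / 0.006)
  px <- 0.1
  n <- ceiling(side_um / px)
  n_total <- n_terminals / (1 - mix$size_mixture$weight_fiber)
  geom <- field_geometry(n * px, n * px, layer = layer)
  intens <- stats::setNames(n_total / geom$area_mm2[1], layer)
  scene_spec(shape = c(5L, n, n), pixel_um = px, z_step_um = 0.2,
             geometry = geom, intensity = intens,
             size_mixture = mix$size_mixture, coloc = mix$coloc, seed = seed, ...)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf("<scene_spec %dx%dx%d (z,y,x) @ %.3g um/px, %.3g um z-step; layers: %s; seed %d>\n",
              x$shape[1], x$shape[2], x$shape[3], x$pixel_um, x$z_step_um,
              paste(x$geometry$layer, collapse = ","), x$seed))
  invisible(x)
}
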