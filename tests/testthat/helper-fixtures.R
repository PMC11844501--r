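# Shared in-code fixtures: rasterised shapes, tiny scene specs, matching
# oracles. Everything is generated programmatically at test time.

# Logical mask of a disc rasterised by the centre-in-disc rule, with a
# deliberately off-grid centre.
raster_disc <- function(r_um, px, pad_um = 1) {
  n <- ceiling(2 * (r_um + pad_um) / px)
  cx <- n * px / 2 + 0.013
  cy <- n * px / 2 + 0.027
  xs <- (seq_len(n) - 0.5) * px
  outer(xs, xs, function(y, x) (x - cx)^2 + (y - cy)^2 <= r_um^2)
}

raster_ellipse <- function(a_um, b_um, px, pad_um = 1) {
  n <- ceiling(2 * (max(a_um, b_um) + pad_um) / px)
  cx <- n * px / 2 + 0.011
  cy <- n * px / 2 + 0.017
  xs <- (seq_len(n) - 0.5) * px
  outer(xs, xs, function(y, x) ((x - cx) / a_um)^2 + ((y - cy) / b_um)^2 <= 1)
}

# A tiny one-layer high-resolution scene for fast rendering in tests.
tiny_field_spec <- function(intensity_per_mm2, side_um = 20, seed = 1L,
                            profile = "mch", nz = 3L, coloc = NULL,
                            size_mixture = NULL, ...) {
  mix <- study_mixture(profile)
  px <- 0.1
  n <- ceiling(side_um / px)
  geom <- field_geometry(n * px, n * px, layer = "GCL")
  scene_spec(shape = c(nz, n, n), pixel_um = px, z_step_um = 0.2,
             geometry = geom,
             intensity = c(GCL = intensity_per_mm2),
             size_mixture = size_mixture %||% mix$size_mixture,
             coloc = coloc %||% mix$coloc,
             seed = seed, ...)
}
`%||%` <- function(x, y) if (is.null(x)) y else x

# Scaled-down four-layer section geometry for fast tiled-regime tests.
small_ob_geometry <- function() {
  ob_layer_geometry(a = 400, b = 300,
                    thickness = c(GL = 70, EPL = 90, MCL = 40), margin = 20)
}

# Object-level recall: fraction of ground-truth objects with a detected
# particle centroid within `tol_um`.
match_recall <- function(truth, particles, tol_um = 2) {
  if (!nrow(truth)) return(NA_real_)
  if (!nrow(particles)) return(0)
  d2 <- outer(truth$x_um, particles$x_um, "-")^2 +
    outer(truth$y_um, particles$y_um, "-")^2
  mean(sqrt(apply(d2, 1, min)) <= tol_um)
}
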