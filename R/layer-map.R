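#' Layer contour maps
#'
#' A `layer_map` holds the traced contours of the olfactory-bulb layers as
#' closed polygons in section coordinates (micrometres). It is a tibble with
#' one row per layer: `layer` (one of GL, EPL, MCL, GCL), a `polygon`
#' list-column (each element `list(outer = ring, holes = list(ring, ...))`)
#' and the polygon `area_mm2`. Layers in a mid-bulb coronal section are
#' nested annuli: glomerular (GL, outermost), external plexiform (EPL),
#' mitral cell (MCL) and granule cell (GCL, core) layers.
#'
#' @param layers Character vector of layer names, subset of
#'   `c("GL","EPL","MCL","GCL")`, unique.
#' @param polygons List of polygons, parallel to `layers`.
#' @return A tibble of class `layer_map`.
#' @export
layer_map <- function(layers, polygons) {
  ob_layers <- c("GL", "EPL", "MCL", "GCL")
  if (!all(layers %in% ob_layers))
    stop("layer names must be among ", paste(ob_layers, collapse = ", "))
  if (anyDuplicated(layers)) stop("layer names must be unique")
  polygons <- lapply(polygons, normalize_polygon)
  for (i in seq_along(polygons)) {
    for (r in c(list(polygons[[i]]$outer), polygons[[i]]$holes)) {
      if (!ring_is_simple(r))
        stop("layer polygon '", layers[i], "' is self-intersecting")
    }
  }
  areas <- vapply(polygons, polygon_area_um2, 0) / 1e6
  if (any(areas <= 0)) stop("all layer polygons must have positive area")
  if (length(polygons) > 1) {
    for (i in seq_len(length(polygons) - 1)) {
      for (j in (i + 1):length(polygons)) {
        if (polygons_overlap(polygons[[i]], polygons[[j]]))
          stop("layer polygons '", layers[i], "' and '", layers[j], "' overlap")
      }
    }
  }
  out <- tibble::tibble(layer = layers, polygon = polygons, area_mm2 = areas)
  class(out) <- c("layer_map", class(out))
  out
}

normalize_polygon <- function(p) {
  if (is.matrix(p)) p <- list(outer = p, holes = list())
  p$holes <- p$holes %||% list()
  storage.mode(p$outer) <- "double"
  p$holes <- lapply(p$holes, function(h) { storage.mode(h) <- "double"; h })
  p
}

#' Default nested-annulus layer geometry for a coronal OB section
#'
#' Stands in for manually traced contours: four concentric elliptical
#' annuli (GL outermost, then EPL, MCL, with the GCL filling the core).
#' Layer thicknesses default to values in the range reported for the mouse
#' olfactory bulb. The section is centred at (`a` + `margin`,
#' `b` + `margin`) so the whole ellipse sits inside a non-negative
#' coordinate frame.
#'
#' @param a,b Outer semi-axes of the section ellipse (micrometres).
#' @param thickness Named numeric: radial thickness (um) of GL, EPL, MCL.
#' @param margin Margin between the ellipse and the image border (um).
#' @return A `layer_map`.
#' @export
ob_layer_geometry <- function(a = 750, b = 560,
                              thickness = c(GL = 90, EPL = 130, MCL = 45),
                              margin = 30) {
  cx <- a + margin; cy <- b + margin
  t1 <- thickness[["GL"]]; t2 <- thickness[["EPL"]]; t3 <- thickness[["MCL"]]
  if (a - t1 - t2 - t3 <= 0 || b - t1 - t2 - t3 <= 0)
    stop("layer thicknesses exceed the section semi-axes")
  e0 <- ellipse_ring(a, b, cx, cy)
  e1 <- ellipse_ring(a - t1, b - t1, cx, cy)
  e2 <- ellipse_ring(a - t1 - t2, b - t1 - t2, cx, cy)
  e3 <- ellipse_ring(a - t1 - t2 - t3, b - t1 - t2 - t3, cx, cy)
  layer_map(
    layers = c("GL", "EPL", "MCL", "GCL"),
    polygons = list(
      list(outer = e0, holes = list(e1)),
      list(outer = e1, holes = list(e2)),
      list(outer = e2, holes = list(e3)),
      list(outer = e3, holes = list())
    )
  )
}

#' Single-layer rectangular field geometry for a high-resolution scene
#'
#' A high-magnification field of view lies entirely within one layer; its
#' "map" is a single rectangle named after that layer.
#'
#' @param width_um,height_um Field size in micrometres.
#' @param layer Which OB layer the field samples.
#' @return A `layer_map` with one row.
#' @export
field_geometry <- function(width_um, height_um, layer = "GCL") {
  rect <- cbind(c(0, width_um, width_um, 0), c(0, 0, height_um, height_um))
  layer_map(layer, list(rect))
}

#' @export
format.layer_map <- function(x, ...) {
  paste0("<layer_map: ", paste(x$layer, collapse = ", "), "; total ",
         signif(sum(x$area_mm2), 4), " mm^2>")
}

#' Section image stacks
#'
#' A `section_stack` is a calibrated multichannel 3-D image: a numeric array
#' with dimensions (y, x, z, channel), the physical pixel edge and z-step in
#' micrometres, and section-level metadata (preparation id, bregma position,
#' section index). Physical coordinates are in micrometres with the origin
#' at the image corner; voxel indices are 0-based in that convention, so the
#' centre of voxel (i, j) lies at ((j + 0.5) * pixel, (i + 0.5) * pixel).
#'
#' @param data Numeric array (y, x, z, channel) or (y, x, z) / (y, x).
#' @param channels Character vector of channel names.
#' @param pixel_um Pixel edge length (um), > 0.
#' @param z_step_um Distance between optical slices (um), > 0.
#' @param meta Named list: `preparation`, `bregma_mm`, `section`.
#' @return An object of class `section_stack`.
#' @export
section_stack <- function(data, channels, pixel_um, z_step_um,
                          meta = list(preparation = "prep1", bregma_mm = NA_real_,
                                      section = 1L)) {
  if (length(dim(data)) == 2L) dim(data) <- c(dim(data), 1L, 1L)
  if (length(dim(data)) == 3L) dim(data) <- c(dim(data), 1L)
  stopifnot(length(dim(data)) == 4L)
  if (length(channels) != dim(data)[4])
    stop("channel names do not match the number of channels in the array")
  if (!is.numeric(pixel_um) || length(pixel_um) != 1 || is.na(pixel_um) || pixel_um <= 0)
    stop("pixel_um must be a single positive number (missing calibration?)")
  if (!is.numeric(z_step_um) || length(z_step_um) != 1 || is.na(z_step_um) || z_step_um <= 0)
    stop("z_step_um must be a single positive number (missing calibration?)")
  dimnames(data)[[4]] <- channels
  structure(list(data = data, channels = channels, pixel_um = pixel_um,
                 z_step_um = z_step_um, meta = meta),
            class = "section_stack")
}

#' @export
print.section_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<section_stack %d x %d px, %d z-slices, channels: %s; %.3g um/px, %.3g um z-step>\n",
              d[1], d[2], d[3], paste(x$channels, collapse = ", "),
              x$pixel_um, x$z_step_um))
  invisible(x)
}

#' Fetch one channel of a stack as a (y, x, z) array
#' @param stack A `section_stack`. @param channel Channel name.
#' @export
stack_channel <- function(stack, channel) {
  if (!channel %in% stack$channels) stop("no channel named '", channel, "'")
  arr <- stack$data[, , , channel, drop = FALSE]
  dim(arr) <- dim(arr)[1:3]
  arr
}

#' Area of one pixel in square micrometres
#' @param stack A `section_stack` (or a pixel edge length in um).
#' @export
area_per_pixel <- function(stack) {
  px <- if (inherits(stack, "section_stack")) stack$pixel_um else stack
  px^2
}

#' Pipeline configuration
#'
#' Tunable parameters of the quantification pipeline, with the defaults used
#' throughout: a strict minimum particle size of more than `min_size_px`
#' pixels (default 2, i.e. particles of >= 3 pixels are kept, matching the
#' 0.845 um^2 floor at a 0.65 um pixel edge), the object-overlap fraction
#' threshold `theta`, the morphology-similarity floor `s_min`, the
#' derivative peak ratio `k` of the size-transition rule, the maximum
#' z-projection window in micrometres, the nucleator ray count, the
#' significance level and a seed for the nucleator start angles.
#'
#' @param min_size_px Strict lower bound on particle pixel count (kept if
#'   `count > min_size_px`).
#' @param theta Overlap fraction threshold in (0, 1].
#' @param s_min Morphology-similarity (IoU) floor in \[0, 1\].
#' @param k Peak ratio of the size-transition rule (> 0).
#' @param z_window_um Maximum z-projection span (um).
#' @param ray_count Nucleator rays (>= 2).
#' @param alpha Significance level.
#' @param seed Integer seed for within-pipeline randomness.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_size_px = 2L, theta = 0.5, s_min = 0.3, k = 3,
                            z_window_um = 2.0, ray_count = 6L, alpha = 0.05,
                            seed = 1L) {
  if (!(theta > 0 && theta <= 1)) stop("theta must be in (0, 1]")
  if (!(s_min >= 0 && s_min <= 1)) stop("s_min must be in [0, 1]")
  if (!(k > 0)) stop("k must be > 0")
  if (!(ray_count >= 2)) stop("ray_count must be >= 2")
  if (!(min_size_px >= 0)) stop("min_size_px must be >= 0")
  structure(list(min_size_px = as.integer(min_size_px), theta = theta,
                 s_min = s_min, k = k, z_window_um = z_window_um,
                 ray_count = as.integer(ray_count), alpha = alpha,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}
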