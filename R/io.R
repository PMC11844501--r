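# Readers and writers: multi-page TIFF stacks with a YAML calibration
# sidecar, GeoJSON layer contours, YAML configuration, CSV tables.
#
# Stacks are stored as 16-bit multi-page TIFF, channel-major page order
# (all z of channel 1, then channel 2, ...). Calibration and section
# metadata live in a sidecar `<stem>.meta.yaml`; reading a stack without
# its sidecar is an error because pixel size must never be silently
# defaulted.

sidecar_path <- function(path) paste0(sub("\\.tiff?$", "", path), ".meta.yaml")

#' Write a section stack to TIFF (+ YAML sidecar)
#'
#' @param stack A [section_stack()]. Intensities must be integers in
#'   \[0, 65535\]; they round-trip exactly.
#' @param path Output TIFF path; the sidecar is written next to it.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  d <- dim(stack$data)
  pages <- list()
  for (ci in seq_len(d[4])) for (k in seq_len(d[3]))
    pages[[length(pages) + 1L]] <- stack$data[, , k, ci] / 65535
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  meta <- list(channels = as.list(stack$channels),
               n_z = d[3], pixel_um = stack$pixel_um,
               z_step_um = stack$z_step_um,
               preparation = stack$meta$preparation,
               bregma_mm = if (is.na(stack$meta$bregma_mm)) NULL else stack$meta$bregma_mm,
               section = stack$meta$section,
               page_order = "channel-major")
  yaml::write_yaml(meta, sidecar_path(path))
  invisible(path)
}

#' Read a section stack written by [write_stack()]
#'
#' @param path TIFF path; `<stem>.meta.yaml` must exist (calibration is
#'   never defaulted).
#' @return A [section_stack()].
#' @export
read_stack <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  sc <- sidecar_path(path)
  if (!file.exists(sc))
    stop("missing calibration metadata: expected sidecar ", sc)
  meta <- yaml::read_yaml(sc)
  if (is.null(meta$pixel_um) || is.null(meta$z_step_um))
    stop("calibration metadata incomplete in ", sc)
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
  if (length(unique(shapes)) != 1)
    stop("channels/pages have mismatched shapes: ", paste(unique(shapes), collapse = ", "))
  channels <- unlist(meta$channels)
  nz <- meta$n_z
  if (length(pages) != nz * length(channels))
    stop("page count does not match channels x z in sidecar")
  ny <- nrow(pages[[1]]); nx <- ncol(pages[[1]])
  data <- array(0, c(ny, nx, nz, length(channels)))
  p <- 1L
  for (ci in seq_along(channels)) for (k in seq_len(nz)) {
    data[, , k, ci] <- pages[[p]]; p <- p + 1L
  }
  section_stack(data, channels, meta$pixel_um, meta$z_step_um,
                meta = list(preparation = meta$preparation %||% "prep1",
                            bregma_mm = meta$bregma_mm %||% NA_real_,
                            section = meta$section %||% 1L))
}

#' Write layer contours as GeoJSON
#'
#' One Feature per layer; Polygon coordinates are (x, y) in micrometres,
#' rings closed explicitly, with the layer name in the `name` property.
#'
#' @param layers A [layer_map()]. @param path Output path.
#' @export
write_layers <- function(layers, path) {
  close_ring <- function(r) rbind(r, r[1, ])
  features <- lapply(seq_len(nrow(layers)), function(i) {
    p <- layers$polygon[[i]]
    coords <- c(list(close_ring(p$outer)), lapply(p$holes, close_ring))
    coords <- lapply(coords, function(r) lapply(seq_len(nrow(r)),
                                                function(k) as.numeric(r[k, ])))
    list(type = "Feature",
         properties = list(name = layers$layer[i]),
         geometry = list(type = "Polygon", coordinates = coords))
  })
  gj <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read layer contours from GeoJSON
#' @param path GeoJSON path written by [write_layers()] (or compatible:
#'   Polygon features with a `name` property, coordinates in um).
#' @return A [layer_map()].
#' @export
read_layers <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  gj <- jsonlite::read_json(path)
  if (!identical(gj$type, "FeatureCollection")) stop("not a GeoJSON FeatureCollection")
  names_ <- character(); polys <- list()
  for (f in gj$features) {
    if (!identical(f$geometry$type, "Polygon")) stop("only Polygon features are supported")
    rings <- lapply(f$geometry$coordinates, function(ring) {
      m <- do.call(rbind, lapply(ring, function(pt) as.numeric(unlist(pt))))
      if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
      m
    })
    names_ <- c(names_, f$properties$name)
    polys[[length(polys) + 1L]] <- list(outer = rings[[1]],
                                        holes = rings[-1])
  }
  layer_map(names_, polys)
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file.
#' @return A [pipeline_config()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y[intersect(names(y), names(formals(pipeline_config)))])
}

#' @rdname read_config
#' @param config A [pipeline_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Persist a rendered scene as a file-set fixture
#'
#' Writes `stack.tif` (+ sidecar), `layers.geojson`, `truth.csv` and
#' `spec.yaml` into a directory; [read_scene_fixture()] restores them
#' losslessly (integer image data bit-exact, ground truth identical).
#'
#' @param scene A scene from [render_section()].
#' @param dir Output directory (created if needed).
#' @export
write_scene_fixture <- function(scene, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_stack(scene$stack, file.path(dir, "stack.tif"))
  write_layers(scene$layers, file.path(dir, "layers.geojson"))
  utils::write.csv(dplyr::select(scene$truth, -dplyr::any_of("pixels")),
                   file.path(dir, "truth.csv"), row.names = FALSE)
  sp <- scene$spec
  yaml::write_yaml(list(shape = sp$shape, pixel_um = sp$pixel_um,
                        z_step_um = sp$z_step_um,
                        intensity = as.list(sp$intensity),
                        size_mixture = list(
                          fiber = sp$size_mixture$fiber,
                          terminal = sp$size_mixture$terminal,
                          weight_fiber = sp$size_mixture$weight_fiber,
                          separable = sp$size_mixture$separable),
                        coloc = as.list(sp$coloc),
                        noise = sp$noise, amplitudes = sp$amplitudes,
                        vglut_background_per_um2 = sp$vglut_background_per_um2,
                        fiber_width_um = sp$fiber_width_um,
                        seed = sp$seed),
                   file.path(dir, "spec.yaml"))
  invisible(dir)
}

#' Restore a scene fixture written by [write_scene_fixture()]
#' @param dir Fixture directory.
#' @return List with `stack`, `layers`, `truth`, `spec`.
#' @export
read_scene_fixture <- function(dir) {
  stack <- read_stack(file.path(dir, "stack.tif"))
  layers <- read_layers(file.path(dir, "layers.geojson"))
  truth <- tibble::as_tibble(utils::read.csv(file.path(dir, "truth.csv"),
                                             stringsAsFactors = FALSE))
  y <- yaml::read_yaml(file.path(dir, "spec.yaml"))
  spec <- scene_spec(shape = unlist(y$shape), pixel_um = y$pixel_um,
                     z_step_um = y$z_step_um, geometry = layers,
                     intensity = unlist(y$intensity),
                     size_mixture = list(fiber = unlist(y$size_mixture$fiber),
                                         terminal = unlist(y$size_mixture$terminal),
                                         weight_fiber = y$size_mixture$weight_fiber,
                                         separable = y$size_mixture$separable),
                     coloc = unlist(y$coloc),
                     noise = y$noise, amplitudes = y$amplitudes,
                     vglut_background_per_um2 = y$vglut_background_per_um2,
                     fiber_width_um = y$fiber_width_um, seed = y$seed)
  list(stack = stack, layers = layers, truth = truth, spec = spec)
}
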