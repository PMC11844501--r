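# Layer assignment and layer-wise density mapping.

#' Assign particles to layers by centroid containment
#'
#' Each particle is labelled by the layer polygon containing its centroid
#' (even-odd rule, boundary-inclusive), or `"outside"` when no polygon
#' contains it. Layers are tested in the order of the layer map; because
#' `layer_map()` forbids overlapping polygons, at most the shared boundary
#' of adjacent layers can match twice, in which case the earlier layer in
#' the map wins (deterministic).
#'
#' @param particles Particle tibble from [extract_particles()].
#' @param layers A [layer_map()].
#' @return The particle tibble with the `layer` column filled in.
#' @export
assign_layers <- function(particles, layers) {
  stopifnot(inherits(layers, "layer_map"))
  if (!nrow(particles)) return(particles)
  lab <- rep("outside", nrow(particles))
  unset <- rep(TRUE, nrow(particles))
  for (li in seq_len(nrow(layers))) {
    if (!any(unset)) break
    hit <- point_in_polygon(particles$x_um[unset], particles$y_um[unset],
                            layers$polygon[[li]])
    lab[unset][hit] <- layers$layer[li]
    unset[unset] <- !hit
  }
  particles$layer <- lab
  particles
}

#' Per-layer particle density for one section
#'
#' Density is defined as the number of segmented particles whose centroid
#' falls in a layer, divided by the layer's contour area. The table has
#' one row per layer, one `"outside"` row tallying particles contained in
#' no layer (area and density `NA`), and one `"whole"` row pooling all
#' in-layer particles over the summed layer area.
#'
#' @param particles Particle tibble with layers assigned (a tibble whose
#'   `layer` column is filled; see [assign_layers()]).
#' @param layers A [layer_map()].
#' @param preparation,section,bregma_mm Section identifiers (defaults are
#'   taken from these arguments, not from the particles).
#' @return A tibble: `preparation`, `section`, `bregma_mm`, `layer`,
#'   `count`, `area_mm2`, `density_per_mm2`.
#' @export
compute_density <- function(particles, layers, preparation = "prep1",
                            section = 1L, bregma_mm = NA_real_) {
  stopifnot(inherits(layers, "layer_map"))
  if (any(layers$area_mm2 <= 0)) stop("zero-area layer")
  if (nrow(particles) && all(is.na(particles$layer)))
    stop("particles have no layer labels; run assign_layers() first")
  counts <- if (nrow(particles)) table(particles$layer) else table(character())
  n_of <- function(l) as.integer(counts[l] %||% 0L)
  cnt <- unname(vapply(layers$layer, function(l)
    if (l %in% names(counts)) as.integer(counts[[l]]) else 0L, 0L))
  out <- tibble::tibble(
    preparation = preparation, section = as.integer(section),
    bregma_mm = bregma_mm,
    layer = layers$layer, count = cnt, area_mm2 = layers$area_mm2,
    density_per_mm2 = cnt / layers$area_mm2)
  outside <- if ("outside" %in% names(counts)) as.integer(counts[["outside"]]) else 0L
  dplyr::bind_rows(
    out,
    tibble::tibble(preparation = preparation, section = as.integer(section),
                   bregma_mm = bregma_mm, layer = "whole",
                   count = sum(cnt), area_mm2 = sum(layers$area_mm2),
                   density_per_mm2 = sum(cnt) / sum(layers$area_mm2)),
    tibble::tibble(preparation = preparation, section = as.integer(section),
                   bregma_mm = bregma_mm, layer = "outside",
                   count = outside, area_mm2 = NA_real_,
                   density_per_mm2 = NA_real_))
}

#' Anterior-posterior density profile
#'
#' Orders per-section density tables from anterior (largest bregma) to
#' posterior and summarises density per layer and position as mean and SEM
#' across preparations (each preparation first averaged over its sections
#' at that position).
#'
#' @param tables A density table or `dplyr::bind_rows()` of several (see
#'   [compute_density()]).
#' @return A tibble ordered by descending `bregma_mm`: `bregma_mm`,
#'   `layer`, `mean_density`, `sem_density`, `n_preparations`.
#' @export
profile_anterior_posterior <- function(tables) {
  stopifnot(nrow(tables) > 0)
  tables |>
    dplyr::filter(.data$layer != "outside") |>
    dplyr::group_by(.data$bregma_mm, .data$layer, .data$preparation) |>
    dplyr::summarise(density = mean(.data$density_per_mm2), .groups = "drop") |>
    dplyr::group_by(.data$bregma_mm, .data$layer) |>
    dplyr::summarise(
      mean_density = mean(.data$density),
      sem_density = if (dplyr::n() > 1) stats::sd(.data$density) / sqrt(dplyr::n()) else NA_real_,
      n_preparations = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$bregma_mm), .data$layer)
}
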