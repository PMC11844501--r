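# End-to-end pipelines over single scenes and multi-section studies.

#' Density pipeline for one tiled section
#'
#' Max z-projection of the neuropeptide channel, Otsu segmentation,
#' particle extraction with the strict minimum-size filter, centroid layer
#' assignment, and the per-layer density table.
#'
#' @param stack A [section_stack()]. @param layers A [layer_map()].
#' @param config A [pipeline_config()].
#' @param channel Neuropeptide channel name.
#' @param method Segmentation method (see [segment_pixels()]).
#' @return List: `particles` (layer-labelled tibble), `density` (tibble).
#' @export
analyze_density_section <- function(stack, layers, config = pipeline_config(),
                                    channel = "NP",
                                    method = list(type = "otsu")) {
  proj <- max_project(stack, channel)
  mask <- segment_pixels(proj, method)
  particles <- extract_particles(mask, stack$pixel_um, config, channel) |>
    assign_layers(layers)
  density <- compute_density(particles, layers,
                             preparation = stack$meta$preparation,
                             section = stack$meta$section,
                             bregma_mm = stack$meta$bregma_mm)
  list(particles = particles, density = density)
}

#' Morphometry + co-localization pipeline for one high-resolution scene
#'
#' Volumetric segmentation of the neuropeptide channel (Otsu threshold
#' from the max projection applied to the stack), particle extraction,
#' the largest cross-section within the configured z-window, nucleator
#' area per particle, per-image size-transition detection, promotion of
#' supra-threshold particles to putative terminals, and object-based
#' overlap scoring against both VGLUT channels.
#'
#' Nucleator start angles are drawn from a generator seeded with
#' `config$seed` (plus the section index), so repeated runs are
#' reproducible.
#'
#' @param stack,layers,config As in [analyze_density_section()].
#' @param channel Neuropeptide channel. @param vglut_channels The two
#'   marker channels.
#' @param image Image identifier recorded on each record.
#' @return List: `particles`, `measurements` (per-particle tibble with
#'   nucleator areas), `size_threshold` (a `size_threshold`), `records`
#'   (categorised terminal tibble; zero rows when no transition is
#'   detected).
#' @export
analyze_coloc_section <- function(stack, layers, config = pipeline_config(),
                                  channel = "NP",
                                  vglut_channels = c("VGLUT1", "VGLUT2"),
                                  image = NULL) {
  if (is.null(image))
    image <- paste0(stack$meta$preparation, "_s", stack$meta$section)
  set.seed(config$seed + 7L * stack$meta$section)
  px <- stack$pixel_um
  arr <- stack_channel(stack, channel)
  thr <- otsu_threshold(max_project(stack, channel))
  particles <- extract_particles(arr > thr, px, config, channel) |>
    assign_layers(layers)
  empty_rec <- tibble::tibble(image = character(), particle_id = integer(),
                              layer = character(), area_um2 = numeric(),
                              flagged = logical(),
                              overlap_vglut1 = numeric(), sim_vglut1 = numeric(),
                              overlap_vglut2 = numeric(), sim_vglut2 = numeric())
  if (!nrow(particles)) {
    return(list(particles = particles,
                measurements = tibble::tibble(),
                size_threshold = NULL,
                records = categorize(empty_rec, config$theta, config$s_min)))
  }
  meas <- purrr::map(particles$pixels, function(pxs) {
    mcs <- max_cross_section(pxs, stack$z_step_um, config$z_window_um)
    nuc <- nucleator_area(mcs$footprint, px, config$ray_count)
    list(mcs = mcs, nuc = nuc)
  })
  measurements <- particles |>
    dplyr::select(-"pixels") |>
    dplyr::mutate(
      cross_section_px = purrr::map_int(meas, ~ .x$mcs$area_px),
      nucleator_area_um2 = purrr::map_dbl(meas, ~ .x$nuc$area_um2),
      flagged = purrr::map_lgl(meas, ~ !isTRUE(.x$nuc$center_inside)))
  st <- if (nrow(measurements) >= 3)
    detect_size_threshold(measurements$nucleator_area_um2, config$k) else NULL
  if (is.null(st) || is.na(st$threshold_um2)) {
    return(list(particles = particles, measurements = measurements,
                size_threshold = st,
                records = categorize(empty_rec, config$theta, config$s_min)))
  }
  is_term <- classify_by_size(measurements$nucleator_area_um2, st) == "terminal"
  term_idx <- which(is_term)
  # per-channel masks on the same z-window as each terminal's area
  masks <- new.env(parent = emptyenv())
  vthr <- vapply(vglut_channels, function(ch)
    otsu_threshold(max_project(stack, ch)), 0)
  window_mask <- function(ch, z0, z1) {
    key <- paste(ch, z0, z1)
    if (exists(key, envir = masks, inherits = FALSE)) return(masks[[key]])
    a <- stack_channel(stack, ch)
    proj <- Reduce(pmax, lapply(z0:z1, function(k) a[, , k]))
    mk <- proj > vthr[[ch]]
    val <- list(mask = mk, labels = label_components(mk))
    masks[[key]] <- val
    val
  }
  recs <- purrr::map_dfr(term_idx, function(i) {
    mcs <- meas[[i]]$mcs
    z0 <- mcs$z_range[1]; z1 <- mcs$z_range[2]
    ov <- lapply(vglut_channels, function(ch) {
      wm <- window_mask(ch, z0, z1)
      measure_overlap(mcs$footprint, wm$mask, wm$labels)
    })
    tibble::tibble(image = image, particle_id = particles$id[i],
                   layer = particles$layer[i],
                   area_um2 = measurements$nucleator_area_um2[i],
                   flagged = measurements$flagged[i],
                   overlap_vglut1 = ov[[1]][["overlap"]],
                   sim_vglut1 = ov[[1]][["similarity"]],
                   overlap_vglut2 = ov[[2]][["overlap"]],
                   sim_vglut2 = ov[[2]][["similarity"]])
  })
  if (!nrow(recs)) recs <- empty_rec
  records <- categorize(recs, config$theta, config$s_min)
  list(particles = particles, measurements = measurements,
       size_threshold = st, records = records)
}

#' Run the co-localization pipeline over many scenes and pool
#'
#' Renders (or accepts pre-rendered) scenes, runs
#' [analyze_coloc_section()] on each, pools the categorised terminal
#' records, and summarises category proportions.
#'
#' @param scenes List of scenes ([render_section()] output) or of
#'   [scene_spec()]s (rendered on the fly).
#' @param config A [pipeline_config()].
#' @param drop_dual_max_n Passed to [summarize_proportions()] (use 2 for
#'   MCH-like runs).
#' @return List: `records` (pooled), `thresholds` (per-image
#'   `size_threshold`s), `proportions` (a `proportion_table`).
#' @export
quantify_coloc_study <- function(scenes, config = pipeline_config(),
                                 drop_dual_max_n = 0L) {
  records <- list(); thresholds <- list()
  for (i in seq_along(scenes)) {
    sc <- scenes[[i]]
    if (inherits(sc, "scene_spec")) sc <- render_section(sc, section = i)
    res <- analyze_coloc_section(sc$stack, sc$layers, config,
                                 image = paste0("img", i))
    records[[i]] <- res$records
    thresholds[[i]] <- res$size_threshold
  }
  records <- dplyr::bind_rows(records)
  proportions <- if (nrow(records))
    summarize_proportions(records, drop_dual_max_n) else NULL
  list(records = records, thresholds = thresholds, proportions = proportions)
}

#' Simulate a multi-preparation tiled density study
#'
#' Renders `n_preparations x sections_per_prep` tiled sections with
#' preparation-level biological variability (per-preparation, per-layer
#' log-normal multipliers of coefficient of variation `prep_cv`), runs
#' the density pipeline on each, and returns the estimated and true
#' density tables. Bregma positions are spaced evenly from `bregma_range`
#' anterior to posterior.
#'
#' @param n_preparations,sections_per_prep Study size.
#' @param intensity Baseline per-layer intensities (objects/mm^2).
#' @param prep_cv Between-preparation coefficient of variation (0 =
#'   identical preparations).
#' @param seed Base seed; every scene derives its own from it.
#' @param config Pipeline configuration.
#' @param geometry Layer geometry used for every section.
#' @param bregma_range Anterior and posterior bregma positions (mm).
#' @param nz,profile Passed to [tiled_scene_spec()].
#' @return List: `density` (estimated, all sections), `truth` (realized
#'   ground-truth densities per section), `profile` (the
#'   anterior-posterior summary of the estimates).
#' @export
simulate_density_study <- function(n_preparations = 3, sections_per_prep = 3,
                                   intensity = c(GL = 38, EPL = 84.4,
                                                 MCL = 161.4, GCL = 306.4),
                                   prep_cv = 0, seed = 1L,
                                   config = pipeline_config(),
                                   geometry = ob_layer_geometry(),
                                   bregma_range = c(5.04, 3.92),
                                   nz = 2L, profile = "mch") {
  set.seed(seed)
  bregmas <- seq(bregma_range[1], bregma_range[2],
                 length.out = sections_per_prep)
  est <- list(); tru <- list()
  sl <- if (prep_cv > 0) sqrt(log(1 + prep_cv^2)) else 0
  for (p in seq_len(n_preparations)) {
    mult <- if (sl > 0)
      stats::rlnorm(length(intensity), -sl^2 / 2, sl) else rep(1, length(intensity))
    names(mult) <- names(intensity)
    for (s in seq_len(sections_per_prep)) {
      sc_seed <- seed + 1000L * p + s
      spec <- tiled_scene_spec(intensity = intensity * mult[names(intensity)],
                               geometry = geometry, profile = profile,
                               nz = nz, seed = sc_seed)
      scene <- render_section(spec, preparation = paste0("prep", p),
                              section = s, bregma_mm = bregmas[s])
      res <- analyze_density_section(scene$stack, scene$layers, config)
      est[[length(est) + 1L]] <- res$density
      td <- attr(scene$truth, "density")
      td$preparation <- paste0("prep", p); td$section <- s
      td$bregma_mm <- bregmas[s]
      tru[[length(tru) + 1L]] <- td
    }
  }
  density <- dplyr::bind_rows(est)
  truth <- dplyr::bind_rows(tru)
  list(density = density, truth = truth,
       profile = profile_anterior_posterior(density))
}
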