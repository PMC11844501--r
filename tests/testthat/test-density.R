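make_particles <- function(x, y) {
  tibble::tibble(id = seq_along(x), channel = "NP", n_px = 5L, area_px = 5L,
                 area_um2 = 5 * 0.4225, x_um = x, y_um = y,
                 layer = NA_character_, pixels = replicate(length(x), NULL))
}

square_map <- function() {
  # GCL core inside a GL ring, in a 100 x 100 um frame
  outer_sq <- cbind(c(10, 90, 90, 10), c(10, 10, 90, 90))
  inner_sq <- cbind(c(30, 70, 70, 30), c(30, 30, 70, 70))
  layer_map(c("GL", "GCL"),
            list(list(outer = outer_sq, holes = list(inner_sq)),
                 list(outer = inner_sq, holes = list())))
}

test_that("centroid layer assignment follows the boundary-inclusive rule", {
  lm <- square_map()
  p <- make_particles(x = c(50, 15, 5, 30), y = c(50, 15, 5, 50))
  p <- assign_layers(p, lm)
  expect_identical(p$layer, c("GCL", "GL", "outside", "GL"))
  # the point exactly on the GL/GCL boundary goes to the first matching
  # layer in map order (deterministic)
  expect_identical(assign_layers(make_particles(30, 50), lm)$layer, "GL")
})

test_that("density is count over area with outside tallied separately", {
  lm <- square_map()
  # GCL square is 40 x 40 um = 0.0016 mm2; put 10 particles inside,
  # 3 in GL, 2 outside
  p <- make_particles(x = c(runif(10, 35, 65), runif(3, 11, 28), 2, 98),
                      y = c(runif(10, 35, 65), runif(3, 11, 28), 2, 98))
  p <- assign_layers(p, lm)
  d <- compute_density(p, lm, preparation = "prepX", section = 2L,
                       bregma_mm = 4.2)
  gcl <- d[d$layer == "GCL", ]
  expect_identical(gcl$count, 10L)
  expect_equal(gcl$density_per_mm2, 10 / 0.0016)
  expect_identical(d$count[d$layer == "outside"], 2L)
  # sum rule: layer counts + outside = total particles
  expect_identical(sum(d$count[!d$layer %in% c("outside", "whole")]) +
                     d$count[d$layer == "outside"], nrow(p))
  expect_identical(d$count[d$layer == "whole"], 13L)
  # zero particles give zero density, not NA
  d0 <- compute_density(assign_layers(make_particles(numeric(0), numeric(0)), lm), lm)
  expect_true(all(d0$density_per_mm2[!d0$layer %in% "outside"] == 0))
})

test_that("densities are invariant to duplicating the section", {
  lm <- square_map()
  set.seed(8)
  p <- assign_layers(make_particles(runif(30, 12, 88), runif(30, 12, 88)), lm)
  d1 <- compute_density(p, lm)
  # two concatenated identical sections: counts and areas both double
  d2 <- dplyr::bind_rows(compute_density(p, lm, section = 1L),
                         compute_density(p, lm, section = 2L)) |>
    dplyr::group_by(layer) |>
    dplyr::summarise(density = sum(count) / sum(area_mm2))
  for (l in c("GL", "GCL")) {
    expect_equal(d2$density[d2$layer == l],
                 d1$density_per_mm2[d1$layer == l])
  }
})

test_that("anterior-posterior profile orders by bregma and averages preparations", {
  lm <- square_map()
  p <- assign_layers(make_particles(runif(20, 12, 88), runif(20, 12, 88)), lm)
  tables <- dplyr::bind_rows(lapply(1:3, function(prep)
    compute_density(p, lm, preparation = paste0("prep", prep), bregma_mm = 4.5)))
  prof <- profile_anterior_posterior(tables)
  # three identical sections: SEM 0
  expect_true(all(prof$sem_density == 0))
  expect_true(all(prof$n_preparations == 3))
  # a single section profile equals its density table
  prof1 <- profile_anterior_posterior(compute_density(p, lm, bregma_mm = 4.0))
  d1 <- compute_density(p, lm, bregma_mm = 4.0)
  for (l in c("GL", "GCL")) {
    expect_equal(prof1$mean_density[prof1$layer == l],
                 d1$density_per_mm2[d1$layer == l])
  }
  # ordering anterior (high bregma) to posterior
  tabs <- dplyr::bind_rows(compute_density(p, lm, bregma_mm = 4.0),
                           compute_density(p, lm, bregma_mm = 5.0))
  expect_identical(profile_anterior_posterior(tabs)$bregma_mm[1], 5.0)
})

test_that("SEM follows sd/sqrt(n)", {
  out <- mean_sem(tibble::tibble(v = c(100, 200, 300)), "v")
  expect_equal(out$mean, 200)
  expect_equal(out$sem, 57.735, tolerance = 1e-4)
})

test_that("per-layer density is recovered within 10% over repeated scenes", {
  # scaled-down four-layer sections; estimates compared with the realized
  # ground-truth density of each scene
  errs <- c()
  for (s in 1:10) {
    spec <- tiled_scene_spec(geometry = small_ob_geometry(), nz = 2L,
                             seed = 500 + s)
    sc <- render_section(spec)
    res <- analyze_density_section(sc$stack, sc$layers)
    est <- res$density[!res$density$layer %in% c("whole", "outside"), ]
    tru <- attr(sc$truth, "density")
    j <- merge(est[, c("layer", "density_per_mm2")],
               tru[, c("layer", "density_per_mm2")], by = "layer")
    ok <- j$density_per_mm2.y > 0
    errs <- c(errs, abs(j$density_per_mm2.x[ok] / j$density_per_mm2.y[ok] - 1))
  }
  expect_lte(mean(errs), 0.10)
})
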