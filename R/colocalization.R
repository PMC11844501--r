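# Object-based VGLUT co-localization: overlap fraction, morphology
# similarity, four-way categorisation and proportion summaries.

#' Overlap fraction and morphology similarity against a marker mask
#'
#' Operationalises "spatially overlapping signal with similar morphology":
#' the overlap fraction is the share of the terminal footprint covered by
#' the marker mask; the similarity score is the intersection-over-union
#' between the footprint and the single marker connected component with
#' maximal intersection (0 when they are disjoint). Both lie in \[0, 1\].
#'
#' @param footprint Integer matrix of (y, x) pixel indices.
#' @param marker_mask Logical matrix (same frame as the footprint indices).
#' @param marker_labels Optional precomputed [label_components()] of
#'   `marker_mask` (saves relabelling when scoring many footprints).
#' @return Named numeric: `overlap`, `similarity`.
#' @export
measure_overlap <- function(footprint, marker_mask, marker_labels = NULL) {
  stopifnot(nrow(footprint) > 0)
  ii <- cbind(footprint[, 1], footprint[, 2])
  inside <- marker_mask[ii]
  n_fp <- nrow(footprint)
  n_int <- sum(inside)
  if (n_int == 0L) return(c(overlap = 0, similarity = 0))
  if (is.null(marker_labels)) marker_labels <- label_components(marker_mask)
  labs <- marker_labels[ii][inside]
  tab <- table(labs)
  best <- as.integer(names(tab)[which.max(tab)])
  inter <- max(tab)
  comp_size <- sum(marker_labels == best)
  c(overlap = n_int / n_fp,
    similarity = inter / (n_fp + comp_size - inter))
}

#' Assign four-way VGLUT categories to terminal records
#'
#' A terminal is positive for a channel if and only if its overlap
#' fraction is at least `theta` AND its similarity score is at least
#' `s_min` (both inclusive). Categories: `1-/2-`, `1+/2-`, `1-/2+`,
#' `1+/2+`.
#'
#' @param records Tibble with columns `overlap_vglut1`, `sim_vglut1`,
#'   `overlap_vglut2`, `sim_vglut2`.
#' @param theta Overlap fraction threshold (default 0.5).
#' @param s_min Similarity floor (default 0.3).
#' @return `records` with a `category` factor column added.
#' @export
categorize <- function(records, theta = 0.5, s_min = 0.3) {
  cats <- c("1-/2-", "1+/2-", "1-/2+", "1+/2+")
  if (!nrow(records)) {
    records$category <- factor(character(), levels = cats)
    return(records)
  }
  p1 <- records$overlap_vglut1 >= theta & records$sim_vglut1 >= s_min
  p2 <- records$overlap_vglut2 >= theta & records$sim_vglut2 >= s_min
  records$category <- factor(
    dplyr::case_when(p1 & p2 ~ "1+/2+", p1 ~ "1+/2-", p2 ~ "1-/2+",
                     TRUE ~ "1-/2-"),
    levels = cats)
  records
}

#' Category proportions, per-layer distribution and per-category sizes
#'
#' Per-image category percentages (summing to 100 within each image),
#' their mean and SEM across images, the pooled percentage (all terminals
#' pooled), per-layer category counts, and per-category area summaries.
#'
#' Dual-positive (`1+/2+`) records can be excluded when they are
#' essentially absent: if their pooled count is positive but at most
#' `drop_dual_max_n`, they are removed before percentages are computed
#' (and reported in `n_dual_excluded`). This mirrors the analysis rule
#' for MCH-like data sets, where only a couple of dual-positive terminals
#' occurred and were excluded; the default (0) excludes nothing.
#'
#' @param records Categorised terminal tibble with columns `image`,
#'   `category`, `area_um2` and optionally `layer`.
#' @param drop_dual_max_n Exclude `1+/2+` records when their pooled count
#'   is `<= drop_dual_max_n` (default 0 = keep always).
#' @return List of class `proportion_table`: `per_image`, `summary`,
#'   `per_layer`, `sizes`, `n_total`, `n_dual_excluded`.
#' @export
summarize_proportions <- function(records, drop_dual_max_n = 0L) {
  stopifnot(nrow(records) >= 1)
  cats <- levels(records$category)
  n_dual <- sum(records$category == "1+/2+")
  excluded <- 0L
  if (n_dual > 0 && n_dual <= drop_dual_max_n) {
    records <- records[records$category != "1+/2+", ]
    excluded <- n_dual
    cats <- setdiff(cats, "1+/2+")
    records$category <- factor(records$category, levels = cats)
  }
  per_image <- records |>
    dplyr::count(.data$image, .data$category, .drop = FALSE) |>
    dplyr::group_by(.data$image) |>
    dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  pooled <- records |>
    dplyr::count(.data$category, .drop = FALSE) |>
    dplyr::mutate(pooled_pct = 100 * .data$n / sum(.data$n))
  summary <- per_image |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      mean_pct = mean(.data$pct),
      sem_pct = if (dplyr::n() > 1) stats::sd(.data$pct) / sqrt(dplyr::n()) else NA_real_,
      n_images = dplyr::n(), .groups = "drop") |>
    dplyr::left_join(pooled, by = "category") |>
    dplyr::rename(n_terminals = "n")
  per_layer <- if ("layer" %in% names(records))
    dplyr::count(records, .data$layer, .data$category, .drop = FALSE)
  else NULL
  sizes <- records |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      mean_area_um2 = mean(.data$area_um2),
      sem_area_um2 = if (dplyr::n() > 1) stats::sd(.data$area_um2) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(), .groups = "drop")
  structure(list(per_image = per_image, summary = summary,
                 per_layer = per_layer, sizes = sizes,
                 n_total = nrow(records), n_dual_excluded = excluded),
            class = "proportion_table")
}

#' @export
print.proportion_table <- function(x, ...) {
  cat(sprintf("<proportion_table: %d terminals over %d images%s>\n",
              x$n_total, length(unique(x$per_image$image)),
              if (x$n_dual_excluded > 0)
                sprintf(" (%d dual-positive excluded)", x$n_dual_excluded) else ""))
  print(x$summary)
  invisible(x)
}

#' Compare terminal areas across VGLUT categories
#'
#' Mean and SEM per category plus a one-way ANOVA on category with Tukey
#' HSD pairwise contrasts. When fewer than two categories have at least
#' two records, the tests are not applicable and are returned as `NULL`
#' with `tests_applicable = FALSE`.
#'
#' @param records Categorised terminal tibble (`category`, `area_um2`).
#' @return List of class `category_size_comparison`: `sizes`, `anova`,
#'   `tukey`, `tests_applicable`.
#' @export
compare_category_sizes <- function(records) {
  sizes <- records |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      mean_area_um2 = mean(.data$area_um2),
      sem_area_um2 = if (dplyr::n() > 1) stats::sd(.data$area_um2) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(), .groups = "drop")
  usable <- sum(sizes$n >= 2)
  if (usable < 2 || length(unique(records$category[!is.na(records$category)])) < 2) {
    return(structure(list(sizes = sizes, anova = NULL, tukey = NULL,
                          tests_applicable = FALSE),
                     class = "category_size_comparison"))
  }
  dat <- dplyr::mutate(records, category = droplevels(factor(.data$category)))
  av <- nway_anova(dat, response = "area_um2", factors = "category")
  tk <- tukey_hsd(av)
  structure(list(sizes = sizes, anova = av, tukey = tk,
                 tests_applicable = TRUE),
            class = "category_size_comparison")
}

#' @export
print.category_size_comparison <- function(x, ...) {
  print(x$sizes)
  if (!x$tests_applicable) cat("(pairwise tests not applicable)\n")
  else { print(x$anova); print(x$tukey) }
  invisible(x)
}
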