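# Statistical layer: N-way ANOVA (type-II), Tukey HSD, mean +/- SEM.

#' N-way analysis of variance (type-II sums of squares)
#'
#' Fits a full-factorial linear model of the response on the given
#' factors and computes a type-II ANOVA table (robust to imbalance; for a
#' single factor this coincides with the classical one-way table). The
#' degenerate all-equal-response case is reported as F = 0, p = 1.
#'
#' @param data A data frame.
#' @param response Name of the numeric response column.
#' @param factors Character vector of grouping columns.
#' @param interactions Include interaction terms (default TRUE).
#' @return List of class `anova_result`: `table` (tibble: term, sumsq, df,
#'   statistic, p_value), `residual_df`, `cell_means`, plus the fitted
#'   model, data and formula for downstream Tukey contrasts.
#' @export
nway_anova <- function(data, response, factors, interactions = TRUE) {
  stopifnot(length(factors) >= 1, response %in% names(data),
            all(factors %in% names(data)))
  data <- as.data.frame(data)
  for (f in factors) data[[f]] <- factor(data[[f]])
  nlev <- vapply(data[factors], nlevels, 0L)
  if (all(nlev < 2)) stop("need >= 2 levels in at least one factor")
  rhs <- paste(factors, collapse = if (interactions) " * " else " + ")
  form <- stats::as.formula(paste(response, "~", rhs))
  fit <- stats::lm(form, data = data)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design: aliased term(s) ", paste(bad, collapse = ", "))
  }
  yv <- data[[response]]
  if (all(abs(yv - mean(yv)) < 1e-12 * max(1, abs(mean(yv))))) {
    # all responses equal: no variance to partition; report F = 0, p = 1
    labels <- attr(stats::terms(form), "term.labels")
    dfs <- unname(table(factor(fit$assign[fit$assign > 0],
                               levels = seq_along(labels))))
    tab <- tibble::tibble(term = labels, sumsq = 0, df = as.integer(dfs),
                          statistic = 0, p_value = 1)
    residual_df <- length(yv) - length(fit$assign)
    resid_ss <- 0
  } else {
    a2 <- car::Anova(fit, type = 2)
    tab <- tibble::tibble(
      term = rownames(a2),
      sumsq = a2[["Sum Sq"]],
      df = a2[["Df"]],
      statistic = a2[["F value"]],
      p_value = a2[["Pr(>F)"]])
    resid_row <- tab$term == "Residuals"
    residual_df <- tab$df[resid_row]
    resid_ss <- tab$sumsq[resid_row]
    tab <- tab[!resid_row, ]
  }
  residual_df <- as.integer(residual_df)
  cell_means <- data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(factors))) |>
    dplyr::summarise(mean = mean(.data[[response]]), n = dplyr::n(),
                     .groups = "drop")
  structure(list(table = tab, residual_df = residual_df,
                 residual_ss = resid_ss, cell_means = cell_means,
                 fit = fit, data = data, response = response,
                 factors = factors, formula = form),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat("N-way ANOVA (type-II sums of squares)\n")
  print(x$table)
  cat("Residual df:", x$residual_df, "\n")
  invisible(x)
}

#' Tukey HSD pairwise contrasts
#'
#' All pairwise group contrasts for each factor of a fitted
#' [nway_anova()], with studentized-range adjusted p-values and
#' significance stars at the conventional cutoffs (`*` p < 0.05, `**`
#' p < 0.01, `***` p < 0.001, `ns` otherwise).
#'
#' @param anova An `anova_result`.
#' @param alpha Significance level used for the `significant` flag and the
#'   confidence intervals.
#' @return List of class `tukey_result` with a `contrasts` tibble: `term`,
#'   `contrast`, `estimate`, `conf_low`, `conf_high`, `adj_p_value`,
#'   `stars`, `significant`. Single-group factors yield no rows.
#' @export
tukey_hsd <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "anova_result"))
  fit_aov <- stats::aov(anova$formula, data = anova$data)
  out <- list()
  for (f in anova$factors) {
    if (nlevels(anova$data[[f]]) < 2) next
    th <- stats::TukeyHSD(fit_aov, which = f, conf.level = 1 - alpha)[[f]]
    if (is.null(th) || nrow(th) == 0) next
    out[[f]] <- tibble::tibble(
      term = f, contrast = rownames(th),
      estimate = th[, "diff"], conf_low = th[, "lwr"],
      conf_high = th[, "upr"], adj_p_value = th[, "p adj"])
  }
  contrasts <- if (length(out)) dplyr::bind_rows(out) else
    tibble::tibble(term = character(), contrast = character(),
                   estimate = numeric(), conf_low = numeric(),
                   conf_high = numeric(), adj_p_value = numeric())
  contrasts$stars <- p_stars(contrasts$adj_p_value)
  contrasts$significant <- contrasts$adj_p_value < alpha
  structure(list(contrasts = contrasts, alpha = alpha),
            class = "tukey_result")
}

p_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ NA_character_, p < 0.001 ~ "***",
                   p < 0.01 ~ "**", p < 0.05 ~ "*", TRUE ~ "ns")
}

#' @export
print.tukey_result <- function(x, ...) {
  cat("Tukey HSD contrasts (alpha =", x$alpha, ")\n")
  print(x$contrasts)
  invisible(x)
}

#' Grouped mean and standard error of the mean
#'
#' SEM uses the sample standard deviation (n - 1) over the square root of
#' n; with a single observation the SEM is undefined and reported as `NA`.
#'
#' @param data A data frame.
#' @param value Name of the numeric column to summarise.
#' @param by Optional character vector of grouping columns.
#' @return Tibble with `mean`, `sem`, `n` (plus grouping columns).
#' @export
mean_sem <- function(data, value, by = character()) {
  stopifnot(value %in% names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      mean = mean(.data[[value]]),
      sem = if (dplyr::n() > 1) stats::sd(.data[[value]]) / sqrt(dplyr::n()) else NA_real_,
      n = dplyr::n(), .groups = "drop")
}

#' Assemble a deterministic markdown analysis report
#'
#' Collates whichever stage outputs are available (density tables, size
#' thresholds, proportion tables, statistics) into one markdown document
#' with a configuration echo. Missing stages are noted explicitly as
#' gaps. The report body contains no timestamps, so identical inputs
#' produce byte-identical reports.
#'
#' @param density Density table or `NULL`.
#' @param thresholds A `size_threshold`, a list of them, or `NULL`.
#' @param proportions A `proportion_table` or `NULL`.
#' @param stats An `anova_result`, `tukey_result`, list of either, or
#'   `NULL`.
#' @param config A [pipeline_config()].
#' @param path Optional file to write the report to.
#' @return Character vector of markdown lines (invisibly if written).
#' @export
build_report <- function(density = NULL, thresholds = NULL, proportions = NULL,
                         stats = NULL, config = pipeline_config(),
                         path = NULL) {
  md <- c("# punctamap analysis report", "")
  md <- c(md, "## Configuration",
          paste0("- min particle size: > ", config$min_size_px, " px"),
          paste0("- overlap threshold theta: ", config$theta),
          paste0("- similarity floor s_min: ", config$s_min),
          paste0("- peak ratio k: ", config$k),
          paste0("- z-window: ", config$z_window_um, " um"),
          paste0("- nucleator rays: ", config$ray_count),
          paste0("- alpha: ", config$alpha),
          paste0("- seed: ", config$seed), "")
  md <- c(md, "## Layer densities")
  md <- c(md, if (is.null(density)) c("_Stage not run: no density table._", "")
          else c(md_table(density), ""))
  md <- c(md, "## Size transition")
  if (is.null(thresholds)) {
    md <- c(md, "_Stage not run: no size-threshold results._", "")
  } else {
    if (inherits(thresholds, "size_threshold")) thresholds <- list(thresholds)
    tt <- dplyr::bind_rows(lapply(thresholds, generics::tidy))
    md <- c(md, md_table(tt), "")
  }
  md <- c(md, "## VGLUT co-localization")
  md <- c(md, if (is.null(proportions)) c("_Stage not run: no proportion table._", "")
          else c(md_table(proportions$summary), ""))
  md <- c(md, "## Statistics")
  if (is.null(stats)) {
    md <- c(md, "_Stage not run: no statistical results._", "")
  } else {
    if (inherits(stats, c("anova_result", "tukey_result"))) stats <- list(stats)
    for (s in stats) md <- c(md, md_table(generics::tidy(s)), "")
  }
  if (!is.null(path)) {
    writeLines(md, path)
    return(invisible(md))
  }
  md
}

md_table <- function(df) {
  df <- as.data.frame(df)
  df <- df[, !vapply(df, is.list, TRUE), drop = FALSE]
  fmt <- vapply(df, function(col) {
    if (is.numeric(col)) formatC(col, digits = 6, format = "g") else as.character(col)
  }, character(nrow(df)))
  if (nrow(df) == 1L) fmt <- matrix(fmt, nrow = 1, dimnames = list(NULL, names(df)))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(fmt, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, rows)
}
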