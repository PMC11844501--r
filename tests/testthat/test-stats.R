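test_that("one-way ANOVA F equals the squared two-sample t statistic", {
  set.seed(71)
  d <- tibble::tibble(g = rep(c("a", "b"), each = 12),
                      y = c(rnorm(12, 1), rnorm(12, 1.6)))
  av <- nway_anova(d, "y", "g")
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(av$table$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(av$table$p_value, tt$p.value, tolerance = 1e-10)
})

test_that("all-equal responses give F = 0 and p = 1", {
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 4), y = 5)
  av <- nway_anova(d, "y", "g")
  expect_identical(av$table$statistic, 0)
  expect_identical(av$table$p_value, 1)
})

test_that("ANOVA table matches hand-computed sums of squares to 1e-8", {
  # printed fixture: 3 groups, n = 5 each
  y <- c(4.1, 5.2, 4.8, 5.0, 4.6,
         6.3, 5.9, 6.8, 6.1, 6.4,
         5.1, 5.5, 4.9, 5.3, 5.6)
  g <- rep(c("g1", "g2", "g3"), each = 5)
  # textbook oracle: explicit sum-of-squares arithmetic
  grand <- mean(y)
  means <- tapply(y, g, mean)
  ss_between <- sum(5 * (means - grand)^2)
  ss_within <- sum((y - means[g])^2)
  f_oracle <- (ss_between / 2) / (ss_within / 12)
  p_oracle <- pf(f_oracle, 2, 12, lower.tail = FALSE)
  av <- nway_anova(tibble::tibble(g = g, y = y), "y", "g")
  expect_equal(av$table$sumsq, ss_between, tolerance = 1e-8)
  expect_equal(av$residual_ss, ss_within, tolerance = 1e-8)
  expect_equal(av$table$statistic, f_oracle, tolerance = 1e-8)
  expect_equal(av$table$p_value, p_oracle, tolerance = 1e-8)
  expect_identical(av$residual_df, 12L)
})

test_that("two-way type-II ANOVA runs on unbalanced designs and flags aliasing", {
  set.seed(73)
  d <- tibble::tibble(
    a = sample(c("x", "y"), 40, TRUE),
    b = sample(c("p", "q"), 40, TRUE))
  d$y <- rnorm(40) + (d$a == "x") * 0.8
  av <- nway_anova(d, "y", c("a", "b"))
  expect_setequal(av$table$term, c("a", "b", "a:b"))
  expect_true(all(av$table$p_value >= 0 & av$table$p_value <= 1))
  # aliased factor (copy of another): rank-deficient design error
  d$c <- d$a
  expect_error(nway_anova(d, "y", c("a", "c")), "rank-deficient")
})

test_that("ANOVA is invariant to group relabelling and matches a permutation test", {
  set.seed(79)
  d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 6),
                      y = rnorm(18) + rep(c(0, 0.5, 1), each = 6))
  av1 <- nway_anova(d, "y", "g")
  relab <- c(a = "zz", b = "mm", c = "aa")
  d2 <- dplyr::mutate(d, g = relab[g])
  av2 <- nway_anova(d2, "y", "g")
  expect_equal(av1$table$statistic, av2$table$statistic, tolerance = 1e-12)
  # permutation estimate of the p-value within Monte-Carlo error
  f_obs <- av1$table$statistic
  f_of <- function(y, g) {   # explicit one-way F, independent of the package
    m <- tapply(y, g, mean); n <- tapply(y, g, length)
    ssb <- sum(n * (m - mean(y))^2); ssw <- sum((y - m[g])^2)
    (ssb / (length(m) - 1)) / (ssw / (length(y) - length(m)))
  }
  f_perm <- replicate(2000, f_of(sample(d$y), d$g))
  p_perm <- mean(f_perm >= f_obs)
  mc_err <- 3 * sqrt(max(p_perm, 1 / 2000) * (1 - p_perm) / 2000)
  expect_lt(abs(p_perm - av1$table$p_value), mc_err + 0.01)
})

test_that("Tukey HSD reduces to the t-test for two groups and stars match cutoffs", {
  set.seed(83)
  d <- tibble::tibble(g = rep(c("a", "b"), each = 10),
                      y = c(rnorm(10), rnorm(10, 1.2)))
  tk <- tukey_hsd(nway_anova(d, "y", "g"))
  tt <- t.test(y ~ g, data = d, var.equal = TRUE)
  expect_equal(tk$contrasts$adj_p_value, tt$p.value, tolerance = 1e-6)
  # identical group means: all ns
  d0 <- tibble::tibble(g = rep(c("a", "b", "c"), each = 5),
                       y = rep(c(2, 2, 2), each = 5) + rep(c(-.1, 0, .1), 5))
  tk0 <- tukey_hsd(nway_anova(d0, "y", "g"))
  expect_true(all(tk0$contrasts$stars == "ns"))
  # stars are consistent with the printed cutoffs
  expect_identical(punctamap:::p_stars(c(0.2, 0.04, 0.009, 0.0009, NA)),
                   c("ns", "*", "**", "***", NA))
})

test_that("grouped mean/SEM summaries handle n = 1 and constants", {
  out <- mean_sem(tibble::tibble(v = c(1, 2, 3)), "v")
  expect_equal(out$mean, 2)
  expect_equal(out$sem, sd(c(1, 2, 3)) / sqrt(3))
  expect_equal(out$sem, 0.577, tolerance = 1e-3)
  one <- mean_sem(tibble::tibble(v = 5), "v")
  expect_identical(one$mean, 5)
  expect_true(is.na(one$sem))
  expect_identical(mean_sem(tibble::tibble(v = rep(4, 6)), "v")$sem, 0)
  g <- mean_sem(tibble::tibble(v = c(1, 2, 10, 20), grp = c("a", "a", "b", "b")),
                "v", by = "grp")
  expect_identical(nrow(g), 2L)
})

test_that("report assembly is deterministic and notes missing stages", {
  cfg <- pipeline_config(seed = 5L)
  st <- detect_size_threshold(c(0.2, 0.3, 0.4, 1.0, 1.1, 1.2))
  lm <- small_ob_geometry()
  dens <- compute_density(
    assign_layers(tibble::tibble(id = 1L, channel = "NP", n_px = 5L,
                                 area_px = 5L, area_um2 = 2.1,
                                 x_um = 420, y_um = 320,
                                 layer = NA_character_, pixels = list(NULL)),
                  lm), lm)
  full <- build_report(density = dens, thresholds = st, config = cfg)
  expect_true(any(grepl("^## Layer densities", full)))
  expect_true(any(grepl("^## Size transition", full)))
  # density-only run: gap notes for the missing stages
  partial <- build_report(density = dens, config = cfg)
  expect_true(any(grepl("Stage not run", partial)))
  # byte-identical on identical inputs
  expect_identical(build_report(density = dens, thresholds = st, config = cfg),
                   full)
  path <- withr::local_tempfile(fileext = ".md")
  build_report(density = dens, config = cfg, path = path)
  expect_true(file.exists(path))
})
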