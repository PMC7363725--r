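test_that("ICC matches a hand-computed ANOVA mean-squares plug-in", {
  # 4 subjects x 2 raters toy table; oracle below re-derives the
  # two-way decomposition with explicit sums
  vals <- rbind(c(9, 8), c(5, 6), c(12, 11), c(7, 7))
  n <- 4; k <- 2
  grand <- mean(vals)
  ssr <- 0
  for (i in 1:n) ssr <- ssr + k * (mean(vals[i, ]) - grand)^2
  ssc <- 0
  for (j in 1:k) ssc <- ssc + n * (mean(vals[, j]) - grand)^2
  sst <- 0
  for (i in 1:n) for (j in 1:k) sst <- sst + (vals[i, j] - grand)^2
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  expected <- (msr - mse) / (msr + (msc - mse) / n)

  got <- icc(measurement_table(vals, "rater"))
  expect_equal(got$estimate, expected, tolerance = 1e-12)
  expect_equal(c(got$msr, got$msc, got$mse), c(msr, msc, mse),
               tolerance = 1e-12)
})

test_that("ICC handles agreement, missing rows and degenerate input", {
  same <- matrix(rep(c(1, 5, 9, 13), 2), ncol = 2)
  expect_equal(icc(measurement_table(same))$estimate, 1.0,
               tolerance = 1e-12)

  with_na <- rbind(c(1, 2), c(NA, 5), c(7, 8), c(3, 3))
  res <- icc(measurement_table(with_na))
  expect_identical(res$n_dropped, 1L)
  expect_identical(res$n_subjects, 3L)

  flat <- matrix(c(4, 4, 4, 7, 7, 7), ncol = 2)  # identical rows
  expect_error(icc(measurement_table(flat)), "between-subject")
})

test_that("ICC is invariant under affine rescaling of the table", {
  set.seed(19)
  vals <- matrix(rnorm(30, 10, 2), ncol = 3)
  base <- icc(measurement_table(vals))$estimate
  expect_equal(icc(measurement_table(vals + 100))$estimate, base,
               tolerance = 1e-9)
  expect_equal(icc(measurement_table(vals * 3.7))$estimate, base,
               tolerance = 1e-9)
})

test_that("reliability bins follow the conventional cut points", {
  expect_identical(interpret_icc(0.77), "good")
  expect_identical(interpret_icc(0.64), "moderate")
  expect_identical(interpret_icc(0.95), "excellent")
  expect_identical(interpret_icc(0.49), "poor")
  expect_identical(interpret_icc(0.5), "moderate")
  expect_identical(interpret_icc(0.75), "moderate")
  expect_identical(interpret_icc(0.9), "good")
  expect_identical(interpret_icc(0.91), "excellent")
})

test_that("Pearson test matches its t-based P-value and handles edges", {
  x <- 1:10
  res <- pearson_test(x, 2 * x + 3)
  expect_equal(res$r, 1, tolerance = 1e-12)
  expect_identical(res$p, 0)

  d <- generate_correlated_pairs(40, 0.5, seed = 8)
  res2 <- pearson_test(d$x, d$y)
  expect_equal(res2$p, p_from_r(res2$r, res2$n), tolerance = 1e-12)
  # symmetry in r <-> -r
  expect_equal(p_from_r(0.42, 20), p_from_r(-0.42, 20), tolerance = 1e-15)
  expect_error(pearson_test(rep(1, 5), 1:5), "zero variance")
  # invariance under positive affine transforms of each variable
  res3 <- pearson_test(3 * d$x - 1, 0.5 * d$y + 10)
  expect_equal(res3$r, res2$r, tolerance = 1e-12)
})

test_that("published correlations are consistent with their P-values", {
  expect_true(p_from_r(0.59, 12) >= 0.040 && p_from_r(0.59, 12) <= 0.050)
  expect_true(p_from_r(0.50, 18) >= 0.030 && p_from_r(0.50, 18) <= 0.040)
})

test_that("correlation strength bins are gap-free and match usage", {
  expect_identical(interpret_correlation(0.59), "moderate")
  expect_identical(interpret_correlation(0.50), "moderate")
  expect_identical(interpret_correlation(0.15), "negligible")
  expect_identical(interpret_correlation(-0.85), "very strong")
  expect_identical(interpret_correlation(0.3), "fair")
  expect_identical(interpret_correlation(0.8), "very strong")
})

test_that("one-way ANOVA: null case, F = t^2, and summary equivalence", {
  g <- list(c(1, 2, 3, 4), c(1, 2, 3, 4))
  res <- one_way_anova(g)
  expect_equal(res$F, 0, tolerance = 1e-15)
  expect_equal(res$p, 1, tolerance = 1e-15)

  set.seed(23)
  a <- rnorm(12, 10, 2)
  b <- rnorm(9, 11, 2)
  res2 <- one_way_anova(list(a, b))
  tt <- t.test(a, b, var.equal = TRUE)
  expect_equal(res2$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res2$p, tt$p.value, tolerance = 1e-10)

  sm <- data.frame(mean = c(mean(a), mean(b)), sd = c(sd(a), sd(b)),
                   n = c(12, 9))
  res3 <- one_way_anova(sm)
  expect_equal(res3$F, res2$F, tolerance = 1e-10)
  expect_equal(res3$p, res2$p, tolerance = 1e-10)
  expect_error(one_way_anova(list(a)), "2 groups")
})

test_that("mandibular-length summary rows give the published verdict", {
  ref <- reference_anthropometry_summary()
  row <- ref[ref$id == "XI", ]
  res <- one_way_anova(data.frame(
    mean = c(row$mean_female, row$mean_male),
    sd = c(row$sd_female, row$sd_male),
    n = c(row$n_female, row$n_male)))
  expect_true(res$significant)
  expect_lt(res$p, 0.05)
})

test_that("aggregate_report sums regions exactly and exposes subtotals", {
  set.seed(31)
  regions <- c("PALATE", "TONGUE", "HARD_TISSUE", "MUCOSA")
  subj <- lapply(1:9, function(i) {
    v <- c(20, 35, 22, 97) + rnorm(4, 0, 3)
    names(v) <- regions
    v
  })
  grp <- c(rep("female", 4), rep("male", 3), NA, NA)
  tables <- list(PALATE = generate_rater_table(9, c(4, 0.2, 0.2), 2, 1),
                 Total = generate_rater_table(9, c(9, 0.1, 0.1), 2, 2))
  rep <- aggregate_report(subj, grp, tables)
  tab <- rep$table
  # total row mean equals the sum of region means (linearity, exact)
  expect_equal(tab$mean_total[tab$row == "Total"],
               sum(tab$mean_total[tab$row != "Total"]), tolerance = 1e-12)
  # per-subject conservation
  expect_equal(rep$per_subject[, "Total"],
               rowSums(rep$per_subject[, regions]), tolerance = 0)
  # unknown-group subjects included in totals, excluded from contrast
  expect_identical(tab$n_total[1], 9L)
  expect_identical(tab$n_female[1], 4L)
  expect_identical(tab$n_male[1], 3L)
  expect_true(all(is.finite(tab$p_value)))
  expect_equal(rep$soft_tissue_subtotal[["mean"]],
               mean(rep$per_subject[, "Total"] -
                      rep$per_subject[, "HARD_TISSUE"]), tolerance = 1e-12)
  expect_equal(rep$icc_median, median(tab$icc, na.rm = TRUE),
               tolerance = 1e-12)

  holm <- aggregate_report(subj, grp, tables, p_adjust = "holm")
  expect_true(all(holm$table$p_value >= tab$p_value - 1e-15))

  single <- aggregate_report(subj[1], NULL, NULL)
  expect_true(is.na(single$table$sd_total[1]))
})
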