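#' Subjects-by-measurements table
#'
#' Matrix container for repeated measurements: rows are subjects, columns
#' are either repeated measurements by one observer (`"repeat"`) or
#' independent raters (`"rater"`). Missing cells are `NA`, never silently
#' zero; reliability estimators drop incomplete rows listwise and report
#' how many were dropped.
#'
#' @param values numeric matrix (subjects x columns), `NA` for missing.
#' @param column_kind `"repeat"` or `"rater"`.
#' @param subject_ids optional character vector of row identifiers.
#' @return an object of class `measurement_table`.
#' @export
measurement_table <- function(values, column_kind = c("repeat", "rater"),
                              subject_ids = NULL) {
  column_kind <- match.arg(column_kind)
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("values must be numeric")
  if (nrow(values) < 2L || ncol(values) < 2L)
    stop("need at least 2 subjects and 2 columns")
  if (is.null(subject_ids)) subject_ids <- as.character(seq_len(nrow(values)))
  if (length(subject_ids) != nrow(values))
    stop("subject_ids length must match rows")
  dimnames(values) <- list(subject_ids, NULL)
  structure(list(values = values, column_kind = column_kind,
                 subject_ids = subject_ids),
            class = "measurement_table")
}

#' Intraclass correlation, absolute agreement, average measures
#'
#' Two-way ANOVA decomposition of a subjects-by-columns table into row
#' (subject), column (rater/repeat) and error mean squares, plugged into
#' the absolute-agreement average-measures estimator
#' `(MSR - MSE) / (MSR + (MSC - MSE) / n)`. The random-effects and
#' mixed-effects two-way models share this point estimate; the declared
#' model is recorded as metadata. Rows containing missing cells are
#' dropped listwise and counted.
#'
#' @param table a [measurement_table()] (or plain numeric matrix).
#' @param model `"two_way_random"` (columns are a random sample of
#'   raters) or `"two_way_mixed"` (the columns are the only raters of
#'   interest).
#' @return object of class `icc_result`: `estimate`, `model`,
#'   `definition`, `unit`, mean squares, `n_subjects`, `k_columns`,
#'   `n_dropped`, `label` (from [interpret_icc()]).
#' @export
icc <- function(table, model = c("two_way_random", "two_way_mixed")) {
  model <- match.arg(model)
  vals <- if (inherits(table, "measurement_table")) table$values
  else as.matrix(table)
  complete <- stats::complete.cases(vals)
  n_dropped <- sum(!complete)
  vals <- vals[complete, , drop = FALSE]
  n <- nrow(vals)
  k <- ncol(vals)
  if (n < 2L || k < 2L)
    stop("need at least 2 complete subjects and 2 columns")
  grand <- mean(vals)
  rm_ <- rowMeans(vals)
  cm_ <- colMeans(vals)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm_ - grand)^2)
  sst <- sum((vals - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  scale <- mean(vals^2) + 1
  if (msr <= 1e-12 * scale)
    stop("zero between-subject variance: ICC undefined")
  denom <- msr + (msc - mse) / n
  if (denom <= 0)
    stop("degenerate table (error mean square dominates): ICC undefined")
  est <- (msr - mse) / denom
  structure(list(estimate = est, model = model,
                 definition = "absolute_agreement", unit = "average",
                 msr = msr, msc = msc, mse = mse, n_subjects = n,
                 k_columns = k, n_dropped = n_dropped,
                 label = interpret_icc(est)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf(
    "ICC(A,%d) = %.3f (%s; %s, absolute agreement, average measures; n = %d)\n",
    x$k_columns, x$estimate, x$label, gsub("_", " ", x$model),
    x$n_subjects))
  if (x$n_dropped > 0)
    cat(sprintf("  %d incomplete row(s) dropped\n", x$n_dropped))
  invisible(x)
}

#' Reliability interpretation bins
#'
#' Conventional bins: below 0.5 poor, 0.5 to 0.75 moderate, above 0.75
#' up to 0.9 good, above 0.9 excellent.
#'
#' @param value an ICC estimate (at most 1).
#' @return one of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
interpret_icc <- function(value) {
  if (!is.finite(value) || value > 1) stop("ICC estimate must be <= 1")
  if (value < 0.5) "poor"
  else if (value <= 0.75) "moderate"
  else if (value <= 0.9) "good"
  else "excellent"
}

#' Pearson correlation with significance
#'
#' Sample correlation with the classical two-sided test based on
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom.
#' Pairs with a missing value are dropped (pairwise-complete).
#'
#' @param x,y paired numeric vectors.
#' @return object of class `correlation_result`: `r`, `n`, `df`, `p`,
#'   `label` (from [interpret_correlation()]).
#' @export
pearson_test <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 complete pairs")
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero variance: correlation undefined")
  r <- sum((x - mean(x)) * (y - mean(y))) /
    ((n - 1) * sd(x) * sd(y))
  r <- max(-1, min(1, r))
  p <- if (abs(r) >= 1 - 1e-15) 0 else p_from_r(r, n)
  structure(list(r = r, n = n, df = n - 2L, p = p,
                 label = interpret_correlation(r)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.3f (%s), n = %d (df = %d), two-sided P = %.4g\n",
              x$r, x$label, x$n, x$df, x$p))
  invisible(x)
}

#' Two-sided P-value from a correlation and sample size
#'
#' Summary-level companion of [pearson_test()]: the P-value implied by a
#' (possibly rounded, published) correlation coefficient and the number
#' of pairs it was computed from.
#'
#' @param r correlation coefficient, `|r| < 1`.
#' @param n number of pairs, at least 3.
#' @return two-sided P-value.
#' @export
p_from_r <- function(r, n) {
  if (!is.finite(r) || abs(r) >= 1) stop("|r| must be < 1")
  if (n < 3L) stop("need n >= 3")
  t <- r * sqrt((n - 2) / (1 - r^2))
  2 * pt(-abs(t), df = n - 2)
}

#' Correlation strength bins
#'
#' Gap-free partition of `|r|`: below 0.3 negligible, 0.3 to below 0.5
#' fair, 0.5 to below 0.8 moderate, 0.8 and above very strong.
#'
#' @param r correlation coefficient, `|r| <= 1`.
#' @return one of `"negligible"`, `"fair"`, `"moderate"`,
#'   `"very strong"`.
#' @export
interpret_correlation <- function(r) {
  if (!is.finite(r) || abs(r) > 1) stop("|r| must be <= 1")
  a <- abs(r)
  if (a < 0.3) "negligible"
  else if (a < 0.5) "fair"
  else if (a < 0.8) "moderate"
  else "very strong"
}

#' One-way ANOVA from raw vectors or summary statistics
#'
#' Classical between/within decomposition. Input is either a list of
#' numeric group vectors or a data frame with columns `mean`, `sd`, `n`
#' (one row per group), from which the sums of squares are reconstructed
#' exactly; the raw path computes the summary and reuses the same
#' arithmetic, so both agree to machine precision.
#'
#' @param groups list of numeric vectors, or a data frame of summary
#'   rows (`mean`, `sd`, `n`).
#' @param alpha significance level, default 0.05.
#' @return list with `F`, `df_between`, `df_within`, `p`, `significant`.
#' @export
one_way_anova <- function(groups, alpha = 0.05) {
  if (is.data.frame(groups)) {
    if (!all(c("mean", "sd", "n") %in% names(groups)))
      stop("summary input needs columns mean, sd, n")
    sm <- groups
  } else if (is.list(groups)) {
    groups <- lapply(groups, function(g) g[is.finite(g)])
    sm <- data.frame(mean = vapply(groups, mean, numeric(1)),
                     sd = vapply(groups, sd, numeric(1)),
                     n = vapply(groups, length, numeric(1)))
  } else stop("groups must be a list of vectors or a summary data frame")
  if (nrow(sm) < 2L) stop("need at least 2 groups")
  if (any(sm$n < 2L)) stop("each group needs n >= 2")
  N <- sum(sm$n)
  grand <- sum(sm$n * sm$mean) / N
  ssb <- sum(sm$n * (sm$mean - grand)^2)
  ssw <- sum((sm$n - 1) * sm$sd^2)
  dfb <- nrow(sm) - 1
  dfw <- N - nrow(sm)
  msb <- ssb / dfb
  msw <- ssw / dfw
  if (msw == 0) {
    f <- if (msb == 0) 0 else Inf
  } else f <- msb / msw
  p <- if (is.infinite(f)) 0 else pf(f, dfb, dfw, lower.tail = FALSE)
  list(F = f, df_between = dfb, df_within = dfw, p = p,
       significant = p < alpha)
}

#' Cohort report: per-region means, group contrasts and reliability
#'
#' Aggregates per-subject region areas into the cohort summary: mean and
#' SD per region for the whole cohort and per group (subjects with
#' unknown group are kept in the cohort totals but excluded from the
#' group contrast), a one-way ANOVA P-value per row, and an ICC per row
#' from the supplied rater tables. Each subject's total is the exact sum
#' of its four region areas, and the soft-tissue subtotal (total minus
#' hard tissue) is exposed under its own name rather than overloading
#' "mucosa".
#'
#' @param area_reports list, one element per subject: an `area_report`
#'   or a named numeric vector over PALATE, TONGUE, HARD_TISSUE, MUCOSA
#'   (cm^2).
#' @param group_assignments factor/character per subject (e.g. "female",
#'   "male", `NA` for unknown).
#' @param rater_tables optional named list mapping a row name (region or
#'   `"Total"`) to a [measurement_table()] of the two researchers'
#'   measurements.
#' @param p_adjust `"none"` (default, one test per row at alpha = 0.05,
#'   mirroring common reporting practice) or `"holm"` for a familywise
#'   correction across rows.
#' @return object of class `group_report`: `table` (data frame with one
#'   row per region plus `Total`), `icc_median`,
#'   `soft_tissue_subtotal` (mean, sd), `per_subject` matrix.
#' @export
aggregate_report <- function(area_reports, group_assignments = NULL,
                             rater_tables = NULL,
                             p_adjust = c("none", "holm")) {
  p_adjust <- match.arg(p_adjust)
  if (!length(area_reports)) stop("no subjects supplied")
  regions <- REGIONS[1:4]
  per <- t(vapply(area_reports, function(ar) {
    v <- if (inherits(ar, "area_report")) ar$region_area_cm2 else ar
    if (!all(regions %in% names(v)))
      stop("each subject needs the four region areas")
    as.numeric(v[regions])
  }, numeric(4)))
  colnames(per) <- regions
  per <- cbind(per, Total = rowSums(per))
  ns <- nrow(per)
  if (is.null(group_assignments)) group_assignments <- rep(NA_character_,
                                                           ns)
  if (length(group_assignments) != ns)
    stop("one group assignment per subject required")
  grp <- as.character(group_assignments)
  glev <- unique(grp[!is.na(grp)])

  mk <- function(v) c(mean = mean(v), sd = if (length(v) > 1) sd(v)
                      else NA_real_)
  rows <- lapply(colnames(per), function(rn) {
    v <- per[, rn]
    out <- data.frame(row = rn, mean_total = mk(v)[1], sd_total = mk(v)[2],
                      n_total = ns, stringsAsFactors = FALSE)
    for (g in glev) {
      vg <- v[!is.na(grp) & grp == g]
      out[[paste0("mean_", g)]] <- mk(vg)[1]
      out[[paste0("sd_", g)]] <- mk(vg)[2]
      out[[paste0("n_", g)]] <- length(vg)
    }
    out$p_value <- if (length(glev) >= 2 &&
                       all(vapply(glev, function(g)
                         sum(!is.na(grp) & grp == g), numeric(1)) >= 2)) {
      one_way_anova(lapply(glev, function(g) v[!is.na(grp) & grp == g]))$p
    } else NA_real_
    out$icc <- if (!is.null(rater_tables) && rn %in% names(rater_tables))
      icc(rater_tables[[rn]])$estimate else NA_real_
    out
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (p_adjust == "holm")
    tab$p_value <- stats::p.adjust(tab$p_value, method = "holm")
  soft <- per[, "Total"] - per[, "HARD_TISSUE"]
  structure(list(table = tab,
                 icc_median = if (all(is.na(tab$icc))) NA_real_
                 else median(tab$icc, na.rm = TRUE),
                 soft_tissue_subtotal = mk(soft),
                 per_subject = per),
            class = "group_report")
}

#' @export
print.group_report <- function(x, ...) {
  cat("<group_report>\n")
  print(x$table, digits = 4)
  cat(sprintf("soft-tissue subtotal (total - hard tissue): %.1f cm^2\n",
              x$soft_tissue_subtotal["mean"]))
  if (!is.na(x$icc_median))
    cat(sprintf("median ICC: %.2f\n", x$icc_median))
  invisible(x)
}

#' Reference cohort summary tables
#'
#' Published per-region intra-oral surface-area and craniofacial
#' measurement summaries (mean, SD, group sizes, ANOVA P, ICC) for an
#' adult cadaver cohort, shipped as plain CSV under `inst/extdata/`.
#' These are summary-level inputs for arithmetic cross-checks (region
#' means summing to the printed total, ICC medians, significance
#' verdicts recomputed from mean/SD/n).
#'
#' @return a data frame.
#' @export
reference_surface_summary <- function() {
  utils::read.csv(system.file("extdata", "reference_surface_summary.csv",
                              package = "oralarea"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_surface_summary
#' @export
reference_anthropometry_summary <- function() {
  utils::read.csv(system.file("extdata",
                              "reference_anthropometry_summary.csv",
                              package = "oralarea"),
                  stringsAsFactors = FALSE)
}
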