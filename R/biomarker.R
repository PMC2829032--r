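#' Normalise a band against a loading control
#'
#' Densitometry intensities are divided by the same lane's housekeeping band
#' (alpha-tubulin for Western blots, beta-actin for RT-PCR) to cancel
#' loading and exposure differences.
#'
#' @param band,loading_control Positive intensities (vectorised).
#' @return `band / loading_control`.
#' @export
#' @examples
#' normalize_band(10, 2)  # 5
normalize_band <- function(band, loading_control) {
  if (any(!is.finite(loading_control)) || any(loading_control <= 0)) {
    abort("`loading_control` must be positive.",
          class = "probdnf_normalization_error")
  }
  if (any(!is.finite(band)) || any(band <= 0)) {
    abort("`band` must be positive.", class = "probdnf_normalization_error")
  }
  band / loading_control
}

#' proBDNF percentage of total BDNF
#'
#' The stress score: `100 * pro / (pro + mat)`. The score is invariant under
#' any common rescaling of the two bands, so raw and loading-control
#' normalised intensities give identical values.
#'
#' @param pro,mat Non-negative band intensities (vectorised); `pro + mat`
#'   must be positive.
#' @return Percentage in `[0, 100]`.
#' @export
#' @examples
#' pro_fraction(40, 60)  # 40
#' pro_fraction(42, 58)  # 42
pro_fraction <- function(pro, mat) {
  if (any(!is.finite(pro)) || any(!is.finite(mat)) ||
      any(pro < 0) || any(mat < 0)) {
    abort("`pro` and `mat` must be non-negative.",
          class = "probdnf_score_error")
  }
  if (any(pro + mat <= 0)) {
    abort("`pro + mat` must be positive.", class = "probdnf_score_error")
  }
  100 * pro / (pro + mat)
}

#' Score a densitometry table
#'
#' Adds `pro_fraction` and `mat_fraction` columns to a cohort table of raw
#' band intensities.
#'
#' @param samples A data frame with columns `band_pro` and `band_mat`
#'   (schema of [generate_densitometry_cohort()]).
#' @return The input as a tibble with `pro_fraction` and `mat_fraction`
#'   appended; the two always sum to 100.
#' @export
score_samples <- function(samples) {
  samples <- as_tibble(samples)
  stopifnot(all(c("band_pro", "band_mat") %in% names(samples)))
  mutate(samples,
         pro_fraction = pro_fraction(.data$band_pro, .data$band_mat),
         mat_fraction = 100 - .data$pro_fraction)
}

#' Stress-positivity threshold from control scores
#'
#' Mean plus `sd_mult` sample standard deviations (n-1 denominator) of the
#' unstressed population's scores. With the default multiplier of 1 this is
#' the ">1SD above the control mean" rule.
#'
#' @param control_scores Numeric vector of control pro-fractions (>= 2
#'   values).
#' @param sd_mult Standard-deviation multiplier (default 1).
#' @return The threshold percentage.
#' @export
#' @examples
#' stress_threshold(c(38, 40, 42))  # 42
stress_threshold <- function(control_scores, sd_mult = 1) {
  if (!is.numeric(control_scores) || length(control_scores) < 2 ||
      any(!is.finite(control_scores))) {
    abort("Need at least two finite control scores.",
          class = "probdnf_threshold_error")
  }
  mean(control_scores) + sd_mult * sd(control_scores)
}

#' Classify scored samples against a threshold
#'
#' A sample is called positive when its pro-fraction strictly exceeds the
#' threshold; ties are negative.
#'
#' @param scored A data frame with a `pro_fraction` column (see
#'   [score_samples()]).
#' @param threshold Threshold percentage.
#' @return The input tibble with a `call` column (`"positive"`/`"negative"`).
#' @export
classify_samples <- function(scored, threshold) {
  scored <- as_tibble(scored)
  stopifnot("pro_fraction" %in% names(scored))
  assert_scalar_number(threshold, "threshold")
  mutate(scored,
         call = if_else(.data$pro_fraction > threshold, "positive", "negative"))
}

#' Tally the stress-test confusion matrix
#'
#' Maps group labels and test calls onto the standard 2x2 counts: stressed
#' positives are true positives (a), control positives false positives (b),
#' stressed negatives false negatives (c), control negatives true negatives
#' (d).
#'
#' @param true_groups Character vector in `{"control", "stressed"}`.
#' @param predictions Character vector in `{"positive", "negative"}` of the
#'   same length.
#' @return A list of class `confusion_counts` with integer fields `a`, `b`,
#'   `c`, `d`.
#' @export
#' @examples
#' confusion(c("stressed", "control"), c("positive", "negative"))
confusion <- function(true_groups, predictions) {
  if (length(true_groups) != length(predictions)) {
    abort("`true_groups` and `predictions` must have equal length.",
          class = "probdnf_label_error")
  }
  if (!all(true_groups %in% c("control", "stressed"))) {
    abort("Group labels must be 'control' or 'stressed'.",
          class = "probdnf_label_error")
  }
  if (!all(predictions %in% c("positive", "negative"))) {
    abort("Predictions must be 'positive' or 'negative'.",
          class = "probdnf_label_error")
  }
  stressed <- true_groups == "stressed"
  positive <- predictions == "positive"
  confusion_counts(
    a = sum(stressed & positive),
    b = sum(!stressed & positive),
    c = sum(stressed & !positive),
    d = sum(!stressed & !positive)
  )
}

#' @rdname confusion
#' @param a,b,c,d True-positive, false-positive, false-negative and
#'   true-negative counts.
#' @export
confusion_counts <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(counts)) || any(counts < 0) ||
      any(counts != trunc(counts))) {
    abort("Counts must be non-negative integers.",
          class = "probdnf_label_error")
  }
  structure(as.list(as.integer(counts)) |> setNames(c("a", "b", "c", "d")),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts: a=%d (TP) b=%d (FP) c=%d (FN) d=%d (TN)>\n",
              x$a, x$b, x$c, x$d))
  invisible(x)
}

#' Diagnostic test performance from confusion counts
#'
#' Computes the four standard performance metrics of a binary diagnostic
#' test: sensitivity `a/(a+c)`, specificity `d/(d+b)`, positive predictive
#' value `a/(a+b)` and negative predictive value `d/(c+d)`, each expressed
#' as a percentage. A metric whose denominator is zero is undefined and
#' reported as `NA`, never as 0. Display values are rounded to the nearest
#' integer percent (half away from zero).
#'
#' @param counts A `confusion_counts` object, e.g. from [confusion()] or
#'   [confusion_counts()].
#' @param threshold Optional threshold percentage to record in the report.
#' @return A list of class `diagnostic_report` with fields `sensitivity`,
#'   `specificity`, `ppv`, `npv` (exact percentages or `NA`), `display`
#'   (integer-rounded versions), `counts` and `threshold`. [tidy()] returns
#'   a metric-per-row tibble; [glance()] a one-row tibble.
#' @export
#' @examples
#' diagnostic_metrics(confusion_counts(a = 15, b = 2, c = 0, d = 13))
diagnostic_metrics <- function(counts, threshold = NA_real_) {
  if (!inherits(counts, "confusion_counts")) {
    abort("`counts` must be a confusion_counts object.",
          class = "probdnf_label_error")
  }
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  metrics <- list(
    sensitivity = ratio(counts$a, counts$a + counts$c),
    specificity = ratio(counts$d, counts$d + counts$b),
    ppv = ratio(counts$a, counts$a + counts$b),
    npv = ratio(counts$d, counts$c + counts$d)
  )
  structure(
    c(metrics,
      list(display = lapply(metrics, function(m)
             if (is.na(m)) NA_integer_ else as.integer(round_half_away(m))),
           counts = counts,
           threshold = threshold)),
    class = "diagnostic_report"
  )
}

#' @export
print.diagnostic_report <- function(x, ...) {
  fmt <- function(v, d) {
    if (is.na(v)) "undefined" else sprintf("%.1f%% (displays %d%%)", v, d)
  }
  cat("Diagnostic test performance\n")
  if (!is.na(x$threshold)) {
    cat(sprintf("  threshold:   %.2f%% pro-fraction\n", x$threshold))
  }
  cat(sprintf("  sensitivity: %s\n", fmt(x$sensitivity, x$display$sensitivity)))
  cat(sprintf("  specificity: %s\n", fmt(x$specificity, x$display$specificity)))
  cat(sprintf("  PPV:         %s\n", fmt(x$ppv, x$display$ppv)))
  cat(sprintf("  NPV:         %s\n", fmt(x$npv, x$display$npv)))
  invisible(x)
}

#' Two-tailed equal-variance (homoscedastic) t-test
#'
#' Pooled-variance Student's t-test with `n1 + n2 - 2` degrees of freedom,
#' the group-comparison test used throughout the densitometry and
#' semiquantitative analyses.
#'
#' @param x,y Numeric samples with at least two values each.
#' @return A list with `statistic` (t), `df`, `p_value`.
#' @export
#' @examples
#' ttest_two_tailed_equalvar(c(40, 41, 39), c(52, 53, 51))
ttest_two_tailed_equalvar <- function(x, y) {
  if (length(x) < 2 || length(y) < 2 ||
      any(!is.finite(x)) || any(!is.finite(y))) {
    abort("Each sample needs at least two finite values.",
          class = "probdnf_degenerate_data_error")
  }
  pooled <- ((length(x) - 1) * stats::var(x) + (length(y) - 1) * stats::var(y)) /
    (length(x) + length(y) - 2)
  if (pooled <= 0) {
    abort("Zero pooled variance: the t statistic is undefined.",
          class = "probdnf_degenerate_data_error")
  }
  fit <- t.test(x, y, var.equal = TRUE)
  list(statistic = unname(fit$statistic),
       df = unname(fit$parameter),
       p_value = fit$p.value)
}

#' One-way analysis of variance
#'
#' Between- over within-group mean-square ratio across two or more groups.
#' For exactly two groups `F` equals the square of the equal-variance t
#' statistic.
#'
#' @param groups A list of numeric samples, each with at least two values.
#' @return A list with `statistic` (F), `df_between`, `df_within`,
#'   `p_value`.
#' @export
#' @examples
#' anova_oneway(list(c(40, 41, 39), c(52, 53, 51)))
anova_oneway <- function(groups) {
  if (!is.list(groups) || length(groups) < 2 ||
      any(vapply(groups, length, 1L) < 2)) {
    abort("Need at least two groups with two values each.",
          class = "probdnf_degenerate_data_error")
  }
  values <- unlist(groups, use.names = FALSE)
  if (any(!is.finite(values))) {
    abort("All values must be finite.",
          class = "probdnf_degenerate_data_error")
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  within_var <- sum(vapply(groups, function(v) sum((v - mean(v))^2), 1))
  if (within_var <= 0) {
    abort("Zero within-group variance: the F statistic is undefined.",
          class = "probdnf_degenerate_data_error")
  }
  fit <- oneway.test(values ~ g, var.equal = TRUE)
  list(statistic = unname(fit$statistic),
       df_between = unname(fit$parameter[1]),
       df_within = unname(fit$parameter[2]),
       p_value = fit$p.value)
}

#' Holm-Sidak step-down pairwise comparisons
#'
#' Post-hoc procedure following a one-way ANOVA: all pairwise
#' equal-variance t-tests, with Sidak-corrected p-values applied in Holm
#' step-down order (the smallest raw p gets the full family correction).
#' With exactly two groups it reduces to the plain homoscedastic t-test.
#'
#' @param groups A named (optionally) list of numeric samples.
#' @param alpha Familywise significance level.
#' @return A tibble with one row per pair: `group1`, `group2`, `statistic`,
#'   `p_value`, `p_adjusted`, `significant`.
#' @export
holm_sidak_posthoc <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2) {
    abort("Need at least two groups.", class = "probdnf_degenerate_data_error")
  }
  nm <- names(groups) %||% paste0("group", seq_along(groups))
  if (is.null(names(groups))) names(groups) <- nm
  pairs <- utils::combn(seq_along(groups), 2)
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    tt <- ttest_two_tailed_equalvar(groups[[i]], groups[[j]])
    tibble(group1 = nm[i], group2 = nm[j],
           statistic = tt$statistic, p_value = tt$p_value)
  })
  m <- nrow(res)
  ord <- order(res$p_value)
  adj <- numeric(m)
  # Sidak correction with shrinking family size, monotonised (Holm step-down)
  for (r in seq_len(m)) {
    adj[r] <- 1 - (1 - res$p_value[ord[r]])^(m - r + 1)
  }
  adj <- cummax(pmin(adj, 1))
  res$p_adjusted <- adj[match(seq_len(m), ord)]
  res$significant <- res$p_adjusted < alpha
  res
}

#' Run the complete proBDNF/totBDNF biomarker pipeline
#'
#' From raw densitometry to diagnostic performance: scores every animal with
#' [pro_fraction()], derives the positivity threshold from the control group
#' only (mean + `sd_mult` x SD), classifies all animals, tallies the
#' confusion matrix and computes [diagnostic_metrics()]. Also reports the
#' control-vs-stressed homoscedastic t-test and one-way ANOVA on the scores.
#'
#' @param samples A densitometry table with columns `animal_id`, `group`,
#'   `tissue`, `band_pro`, `band_mat` (and optionally `band_tubulin`);
#'   exactly one tissue, both groups present.
#' @param sd_mult Threshold multiplier (default 1, the ">1SD" rule).
#' @param verbose Emit the threshold, per-animal calls and confusion counts
#'   as messages.
#' @return A list of class `biomarker_result`: `scores` (per-animal tibble
#'   with `call`), `threshold`, `counts`, `report` (a `diagnostic_report`),
#'   `ttest`, `anova`, `tissue`. [tidy()] returns the score table,
#'   [glance()] a one-row summary, [autoplot()] the scatter with the
#'   threshold line.
#' @export
#' @examples
#' res <- run_biomarker_pipeline(
#'   generate_densitometry_cohort(cohort_config("brain", seed = 11))
#' )
#' glance(res)
run_biomarker_pipeline <- function(samples, sd_mult = 1, verbose = FALSE) {
  samples <- as_tibble(samples)
  needed <- c("animal_id", "group", "band_pro", "band_mat")
  if (!all(needed %in% names(samples))) {
    abort(paste0("`samples` must contain columns: ",
                 paste(needed, collapse = ", ")),
          class = "probdnf_cohort_error")
  }
  tissue <- if ("tissue" %in% names(samples)) unique(samples$tissue) else "unspecified"
  if (length(tissue) != 1) {
    abort("`samples` must contain exactly one tissue; thresholds are never pooled across tissues.",
          class = "probdnf_cohort_error")
  }
  if (!all(c("control", "stressed") %in% samples$group)) {
    abort("Both 'control' and 'stressed' groups are required.",
          class = "probdnf_cohort_error")
  }
  scored <- score_samples(samples)
  thr <- stress_threshold(scored$pro_fraction[scored$group == "control"],
                          sd_mult = sd_mult)
  scored <- classify_samples(scored, thr)
  counts <- confusion(scored$group, scored$call)
  report <- diagnostic_metrics(counts, threshold = thr)
  ctl <- scored$pro_fraction[scored$group == "control"]
  str <- scored$pro_fraction[scored$group == "stressed"]
  if (verbose) {
    inform(sprintf("threshold (%s): %.2f%% pro-fraction", tissue, thr))
    inform(paste0("calls: ", paste0(scored$animal_id, "=",
                                    scored$call, collapse = ", ")))
    inform(sprintf("confusion: a=%d b=%d c=%d d=%d",
                   counts$a, counts$b, counts$c, counts$d))
  }
  structure(
    list(scores = scored, threshold = thr, counts = counts, report = report,
         ttest = ttest_two_tailed_equalvar(ctl, str),
         anova = anova_oneway(list(control = ctl, stressed = str)),
         tissue = tissue, sd_mult = sd_mult),
    class = "biomarker_result"
  )
}

#' @export
print.biomarker_result <- function(x, ...) {
  cat(sprintf("proBDNF/totBDNF biomarker pipeline -- tissue: %s\n", x$tissue))
  cat(sprintf("  %d control / %d stressed animals\n",
              sum(x$scores$group == "control"),
              sum(x$scores$group == "stressed")))
  cat(sprintf("  threshold (control mean + %g SD): %.2f%%\n",
              x$sd_mult, x$threshold))
  cat(sprintf("  confusion: a=%d b=%d c=%d d=%d\n",
              x$counts$a, x$counts$b, x$counts$c, x$counts$d))
  print(x$report)
  cat(sprintf("  control vs stressed: t = %.3f (p = %.3g), F = %.3f (p = %.3g)\n",
              x$ttest$statistic, x$ttest$p_value,
              x$anova$statistic, x$anova$p_value))
  invisible(x)
}

#' Write a per-animal score table as TSV
#'
#' @param result A `biomarker_result`.
#' @param path Output path.
#' @return `result`, invisibly.
#' @export
write_score_tsv <- function(result, path) {
  stopifnot(inherits(result, "biomarker_result"))
  readr::write_tsv(result$scores, path)
  invisible(result)
}
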