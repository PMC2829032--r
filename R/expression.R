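#' Normalise a transcript band against beta-actin
#'
#' @param band_variant,band_actin Positive fluorescence intensities
#'   (vectorised).
#' @return `band_variant / band_actin`.
#' @export
#' @examples
#' normalize_expression(6, 3)  # 2
normalize_expression <- function(band_variant, band_actin) {
  if (any(!is.finite(band_actin)) || any(band_actin <= 0)) {
    abort("`band_actin` must be positive.",
          class = "probdnf_normalization_error")
  }
  if (any(!is.finite(band_variant)) || any(band_variant <= 0)) {
    abort("`band_variant` must be positive.",
          class = "probdnf_normalization_error")
  }
  band_variant / band_actin
}

#' Stressed-over-control expression ratio
#'
#' Ratio of group means of normalised expression; a ratio below 1 indicates
#' down-regulation under stress.
#'
#' @param stressed_values,control_values Non-empty numeric vectors of
#'   normalised expression.
#' @return `mean(stressed) / mean(control)`.
#' @export
#' @examples
#' stress_ratio(c(0.6, 0.6), c(1, 1))  # 0.6
stress_ratio <- function(stressed_values, control_values) {
  if (length(stressed_values) < 1 || length(control_values) < 1 ||
      any(!is.finite(stressed_values)) || any(!is.finite(control_values))) {
    abort("Both groups need finite values.", class = "probdnf_ratio_error")
  }
  cm <- mean(control_values)
  if (cm <= 0) {
    abort("Control mean must be positive.", class = "probdnf_ratio_error")
  }
  mean(stressed_values) / cm
}

# Canonical display order for the seabass BDNF transcript variants.
VARIANT_ORDER <- c("1beta", "1a", "1b", "1c", "1d", "2")

#' Per-variant regulation calls from a semiquantitative RT-PCR panel
#'
#' For each transcript variant: normalises every lane against its
#' beta-actin band, computes the stressed/control ratio of group means, and
#' tests the group difference with a two-tailed homoscedastic t-test on the
#' normalised values. No multiple-testing correction is applied by default
#' (per-variant calls at `alpha`); Holm correction across variants is
#' available via `correct = "holm"`.
#'
#' @param panel A data frame with columns `variant`, `group`
#'   (`"control"`/`"stressed"`), `replicate`, `band_variant`, `band_actin`
#'   (schema of [generate_expression_panel()]).
#' @param alpha Significance level (default 0.05).
#' @param correct `"none"` (default) or `"holm"`.
#' @return A tibble of class `regulation_report` with one row per variant:
#'   `variant`, `ratio`, `p_value`, `significant`, `direction` (`"up"`,
#'   `"down"` or `"unchanged"`), `stars` (`"*"` for p < 0.05, `"**"` for
#'   p < 0.01).
#' @export
#' @examples
#' panel <- generate_expression_panel(expression_panel_config(seed = 3))
#' variant_regulation_report(panel)
variant_regulation_report <- function(panel, alpha = 0.05,
                                      correct = c("none", "holm")) {
  correct <- match.arg(correct)
  panel <- as_tibble(panel)
  needed <- c("variant", "group", "band_variant", "band_actin")
  if (!all(needed %in% names(panel))) {
    abort(paste0("`panel` must contain columns: ",
                 paste(needed, collapse = ", ")),
          class = "probdnf_panel_error")
  }
  assert_scalar_number(alpha, "alpha", 0, 1,
                       strict_lower = TRUE, strict_upper = TRUE)
  tab <- table(panel$variant, panel$group)
  if (!all(c("control", "stressed") %in% colnames(tab)) || any(tab < 2)) {
    abort("Every variant needs both groups with at least 2 replicates each.",
          class = "probdnf_panel_error")
  }
  panel <- mutate(panel,
                  expression = normalize_expression(.data$band_variant,
                                                    .data$band_actin))
  variants <- unique(panel$variant)
  if (all(variants %in% VARIANT_ORDER)) {
    variants <- VARIANT_ORDER[VARIANT_ORDER %in% variants]
  } else {
    variants <- sort(variants)
  }
  res <- purrr::map_dfr(variants, function(v) {
    ctl <- panel$expression[panel$variant == v & panel$group == "control"]
    str <- panel$expression[panel$variant == v & panel$group == "stressed"]
    tt <- ttest_two_tailed_equalvar(ctl, str)
    tibble(variant = v,
           ratio = stress_ratio(str, ctl),
           p_value = tt$p_value)
  })
  p_eff <- if (correct == "holm") stats::p.adjust(res$p_value, "holm") else res$p_value
  res <- mutate(res,
                p_adjusted = p_eff,
                significant = p_eff < alpha,
                direction = dplyr::case_when(
                  !significant ~ "unchanged",
                  ratio < 1 ~ "down",
                  TRUE ~ "up"
                ),
                stars = dplyr::case_when(
                  p_eff < 0.01 ~ "**",
                  p_eff < 0.05 ~ "*",
                  TRUE ~ ""
                ))
  if (correct == "none") res$p_adjusted <- NULL
  class(res) <- c("regulation_report", class(res))
  res
}

#' Write a regulation report as TSV
#'
#' @param report A `regulation_report`.
#' @param path Output path.
#' @return `report`, invisibly.
#' @export
write_regulation_tsv <- function(report, path) {
  stopifnot(inherits(report, "regulation_report"))
  readr::write_tsv(as_tibble(report), path)
  invisible(report)
}
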