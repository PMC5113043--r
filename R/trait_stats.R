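#' Stable carbon isotope composition from isotope ratios
#'
#' `delta13C (per mil) = (R_grain / R_standard - 1) * 1000`, where R is the
#' 13C/12C ratio of the grain sample and of the reference standard.
#'
#' @param r_grain,r_standard Positive isotope ratios (vectors recycle).
#' @return delta-13C in per mil.
#' @export
delta13c_from_ratio <- function(r_grain, r_standard) {
  if (any(r_grain <= 0) || any(r_standard <= 0)) {
    abort("isotope ratios must be positive")
  }
  (r_grain / r_standard - 1) * 1000
}

#' Isotope ratio back from a delta-13C value
#'
#' Inverse of [delta13c_from_ratio()].
#'
#' @param delta13c delta-13C in per mil.
#' @param r_standard Standard isotope ratio.
#' @return The grain isotope ratio.
#' @export
ratio_from_delta13c <- function(delta13c, r_standard) {
  (delta13c / 1000 + 1) * r_standard
}

#' Carbon isotope discrimination
#'
#' `Delta13C = (delta_a - delta_s) / (1 + delta_s / 1000)` with both deltas
#' in per mil; `delta_a` is the air value (about -8 per mil on the PDB
#' scale for free atmospheric CO2) and `delta_s` the plant (grain) value.
#' The denominator divides `delta_s` by 1000 because the deltas are
#' expressed in per mil; this is what yields discrimination values on the
#' 16-19 per mil scale typical of wheat grain.
#'
#' @param delta_s Plant delta-13C in per mil.
#' @param delta_a Air delta-13C in per mil (default -8).
#' @return Discrimination in per mil; strictly decreasing in `delta_s`.
#' @export
isotope_discrimination <- function(delta_s, delta_a = -8) {
  if (any(delta_s <= -1000)) abort("delta_s must exceed -1000 per mil")
  (delta_a - delta_s) / (1 + delta_s / 1000)
}

#' Two-way ANOVA for subspecies and environment effects
#'
#' Unbalanced two-way analysis of variance with interaction, using Type II
#' sums of squares (appropriate for the very unbalanced subspecies sizes of
#' a landrace panel) and F tests against the residual mean square. When
#' some subspecies-environment cell is empty the interaction is dropped
#' with a warning.
#'
#' @param data A data frame.
#' @param value,subspecies,environment Column names (strings) of the
#'   response, the subspecies factor and the environment factor.
#' @return A tibble: `term`, `sumsq`, `df`, `statistic`, `p_value`.
#' @export
two_way_anova <- function(data, value = "value", subspecies = "subspecies",
                          environment = "environment") {
  df <- tibble(y = as.numeric(data[[value]]),
               s = factor(data[[subspecies]]),
               e = factor(data[[environment]]))
  df <- df[complete.cases(df), ]
  if (nlevels(droplevels(df$s)) < 2 || nlevels(droplevels(df$e)) < 2) {
    abort("need at least two levels of subspecies and environment")
  }
  cells <- table(df$s, df$e)
  with_int <- all(cells > 0)
  if (!with_int) {
    warn("empty subspecies x environment cells; interaction dropped")
  }
  form <- if (with_int) y ~ s * e else y ~ s + e
  fit <- lm(form, data = df)
  if (var(df$y) == 0) {
    terms <- if (with_int) c("subspecies", "environment",
                             "subspecies:environment", "residual")
             else c("subspecies", "environment", "residual")
    dfs <- c(nlevels(df$s) - 1, nlevels(df$e) - 1,
             if (with_int) (nlevels(df$s) - 1) * (nlevels(df$e) - 1))
    return(tibble(term = terms, sumsq = 0,
                  df = c(dfs, nrow(df) - 1 - sum(dfs)),
                  statistic = NA_real_, p_value = NA_real_))
  }
  a2 <- car::Anova(fit, type = 2)
  out <- as_tibble(a2, rownames = "term") |>
    dplyr::rename(sumsq = "Sum Sq", df = "Df",
                  statistic = dplyr::any_of("F value"),
                  p_value = dplyr::any_of("Pr(>F)")) |>
    dplyr::mutate(term = dplyr::recode(.data$term,
                                       s = "subspecies", e = "environment",
                                       `s:e` = "subspecies:environment",
                                       Residuals = "residual"))
  out
}

#' Trait correlation matrix with a normality-gated method choice
#'
#' For each variable pair, both variables are tested for normality
#' (Shapiro-Wilk at `alpha`); the Pearson coefficient is used when both
#' pass, the Spearman rank coefficient otherwise, on pairwise-complete
#' observations. The method chosen is recorded per pair.
#'
#' @param data A data frame of numeric trait columns.
#' @param vars Columns to use (default: all numeric columns).
#' @param alpha Normality-test level (default 0.05).
#' @param min_n Minimum complete pairs per cell (default 5).
#' @return A tibble of class `trait_correlations` with one row per
#'   unordered pair (diagonal included): `var1`, `var2`, `method`,
#'   `estimate`, `p_value`, `n`.
#' @export
correlation_matrix <- function(data, vars = NULL, alpha = 0.05, min_n = 5) {
  if (is.null(vars)) {
    vars <- names(data)[vapply(data, is.numeric, logical(1))]
  }
  normal <- vapply(vars, function(v) {
    x <- data[[v]][!is.na(data[[v]])]
    if (length(x) < 3 || var(x) == 0) return(FALSE)
    stats::shapiro.test(x)$p.value > alpha
  }, logical(1))
  rows <- list()
  for (a in seq_along(vars)) {
    for (b in seq(a, length(vars))) {
      x <- data[[vars[a]]]; y <- data[[vars[b]]]
      cc <- complete.cases(x, y)
      n <- sum(cc)
      if (a == b) {
        rows[[length(rows) + 1L]] <- tibble(
          var1 = vars[a], var2 = vars[b], method = NA_character_,
          estimate = 1, p_value = NA_real_, n = n)
        next
      }
      if (n < min_n || var(x[cc]) == 0 || var(y[cc]) == 0) {
        rows[[length(rows) + 1L]] <- tibble(
          var1 = vars[a], var2 = vars[b], method = NA_character_,
          estimate = NA_real_, p_value = NA_real_, n = n)
        next
      }
      method <- if (normal[a] && normal[b]) "pearson" else "spearman"
      ht <- suppressWarnings(
        stats::cor.test(x[cc], y[cc], method = method, exact = FALSE))
      rows[[length(rows) + 1L]] <- tibble(
        var1 = vars[a], var2 = vars[b], method = method,
        estimate = unname(ht$estimate), p_value = ht$p.value, n = n)
    }
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("trait_correlations", class(out))
  out
}

#' Symmetric matrix view of a trait correlation table
#'
#' @param x A `trait_correlations` tibble from [correlation_matrix()].
#' @return A symmetric numeric matrix with unit diagonal.
#' @export
cor_matrix <- function(x) {
  vars <- unique(c(x$var1, x$var2))
  m <- matrix(NA_real_, length(vars), length(vars),
              dimnames = list(vars, vars))
  for (i in seq_len(nrow(x))) {
    m[x$var1[i], x$var2[i]] <- x$estimate[i]
    m[x$var2[i], x$var1[i]] <- x$estimate[i]
  }
  m
}
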