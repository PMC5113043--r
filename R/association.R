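#' Missing-data filter for association scans
#'
#' Retains markers whose missing-call fraction is strictly below
#' `max_missing` (a marker with exactly 5% missing is dropped).
#'
#' @param dataset A [marker_dataset()].
#' @param max_missing Missing-fraction cutoff (default 0.05).
#' @return Character vector of retained marker ids.
#' @export
association_filter <- function(dataset, max_missing = 0.05) {
  stopifnot(inherits(dataset, "marker_dataset"))
  frac <- colMeans(is.na(dataset$genotypes))
  dataset$marker_ids[frac < max_missing]
}

q_covariates <- function(dataset) {
  q <- dataset$q
  # rows sum to 1, so the full Q is collinear with the intercept: drop the
  # last population column
  q[, -ncol(q), drop = FALSE]
}

#' Structure-corrected GLM association scan
#'
#' For each marker, fits the general linear model
#' `response ~ intercept + Q covariates + marker` and the reduced model
#' without the marker on complete cases, and tests the marker by the
#' extra-sum-of-squares F statistic with `(1, n - K - 1)` degrees of
#' freedom (`K` populations; the last Q column is dropped against the
#' intercept). The marker's partial R-squared is
#' `(SSE_reduced - SSE_full) / SSE_reduced`. Markers monomorphic among the
#' complete cases are skipped; markers collinear with the Q covariates
#' (projected norm below tolerance) return `NA` with a diagnostic note.
#'
#' @param response Named numeric vector (names are accession ids) or a
#'   tibble with columns `accession`, `value`; typically per-environment
#'   BLUPs or a qualitative-class indicator.
#' @param dataset A [marker_dataset()].
#' @param markers Markers to scan (default: all markers passing
#'   [association_filter()]).
#' @param max_missing Passed to [association_filter()] when `markers` is
#'   not given.
#' @return A tibble: `marker`, `n`, `statistic` (F), `p_value`, `r2`
#'   (partial), `note`.
#' @export
glm_q_scan <- function(response, dataset, markers = NULL,
                       max_missing = 0.05) {
  stopifnot(inherits(dataset, "marker_dataset"))
  if (is.data.frame(response)) {
    response <- setNames(response$value, response$accession)
  }
  if (is.null(names(response))) {
    abort("`response` must be named by accession id")
  }
  if (is.null(markers)) {
    markers <- association_filter(dataset, max_missing)
  }
  acc <- intersect(dataset$accession_ids, names(response))
  y_all <- response[acc]
  qc <- q_covariates(dataset)[acc, , drop = FALSE]
  geno <- dataset$genotypes[acc, markers, drop = FALSE]
  k_pop <- ncol(dataset$q)
  res <- purrr::map(markers, function(mk) {
    x <- geno[, mk]
    cc <- !is.na(x) & !is.na(y_all)
    n <- sum(cc)
    if (n - k_pop - 1 < 1) {
      return(list(n = n, f = NA_real_, p = NA_real_, r2 = NA_real_,
                  note = "too few complete cases"))
    }
    xv <- x[cc]
    if (var(xv) == 0) {
      return(list(n = n, f = NA_real_, p = NA_real_, r2 = NA_real_,
                  note = "monomorphic in sample"))
    }
    x0 <- cbind(1, qc[cc, , drop = FALSE])
    y <- y_all[cc]
    fit0 <- stats::lm.fit(x0, y)
    # marker residual after projecting on intercept + Q: collinearity guard
    xres <- stats::lm.fit(x0, xv)$residuals
    if (sqrt(sum(xres^2)) < 1e-10 * sqrt(sum(xv^2))) {
      return(list(n = n, f = NA_real_, p = NA_real_, r2 = NA_real_,
                  note = "collinear with Q"))
    }
    fit1 <- stats::lm.fit(cbind(x0, xv), y)
    sse0 <- sum(fit0$residuals^2)
    sse1 <- sum(fit1$residuals^2)
    df2 <- n - k_pop - 1
    f <- (sse0 - sse1) / (sse1 / df2)
    p <- pf(f, 1, df2, lower.tail = FALSE)
    list(n = n, f = f, p = p, r2 = (sse0 - sse1) / sse0, note = NA_character_)
  })
  tibble(marker = markers,
         n = purrr::map_int(res, ~as.integer(.x$n)),
         statistic = purrr::map_dbl(res, "f"),
         p_value = purrr::map_dbl(res, "p"),
         r2 = purrr::map_dbl(res, "r2"),
         note = purrr::map_chr(res, "note"))
}

#' Bonferroni adjustment at a fixed family size
#'
#' `min(1, p * m)` with `m` the number of markers tested for the
#' trait-response; reported alongside raw p-values (declaration uses the
#' raw thresholds).
#'
#' @param p Numeric vector of raw p-values.
#' @param m Family size (default `length(p)`).
#' @return Adjusted p-values.
#' @export
bonferroni_adjust <- function(p, m = length(p)) {
  if (m < 1) abort("`m` must be at least 1")
  pmin(1, p * m)
}

#' Chi-square confirmation of a qualitative-trait association
#'
#' Pearson chi-square (no continuity correction) on the 2-by-k contingency
#' table of marker state by trait class within a subspecies, with
#' `df = k - 1`. Degenerate tables (a single class or a single marker
#' state) are reported not-testable rather than raised; a low expected
#' count (< 5 in any cell) is flagged.
#'
#' @param classes Character vector of trait class labels per accession.
#' @param calls Integer 0/1/NA marker calls, same accessions.
#' @return One-row tibble: `statistic`, `df`, `p_value`, `n`,
#'   `low_expected`, `testable`.
#' @export
chisq_confirm <- function(classes, calls) {
  cc <- !is.na(classes) & !is.na(calls)
  classes <- classes[cc]; calls <- calls[cc]
  tab <- table(factor(calls, levels = c(0, 1)), classes)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2 || ncol(tab) < 2) {
    return(tibble(statistic = NA_real_, df = NA_integer_,
                  p_value = NA_real_, n = length(classes),
                  low_expected = NA, testable = FALSE))
  }
  ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(statistic = unname(ht$statistic), df = as.integer(ht$parameter),
         p_value = unname(ht$p.value), n = sum(tab),
         low_expected = any(ht$expected < 5), testable = TRUE)
}

#' Simple-regression confirmation of a quantitative-trait association
#'
#' Ordinary least-squares regression of the per-accession value (BLUP) on
#' the 0/1 marker state within one subspecies-environment cell, with the
#' two-sided t-test p-value of the slope and the regression R-squared (the
#' quantity reported per cell in the association tables). Cells with a
#' monomorphic marker, or fewer than `min_n` complete accessions, are
#' reported not-testable (monomorphic cells feed the fixed-marker
#' bookkeeping).
#'
#' @param values Named numeric vector of per-accession values.
#' @param calls Integer 0/1/NA marker calls named by accession (or in the
#'   order of `values`).
#' @param min_n Minimum complete accessions (default 5).
#' @return One-row tibble: `slope`, `r2`, `p_value`, `n`, `testable`,
#'   `note`.
#' @export
regression_confirm <- function(values, calls, min_n = 5) {
  if (!is.null(names(values)) && !is.null(names(calls))) {
    calls <- calls[names(values)]
  }
  cc <- !is.na(values) & !is.na(calls)
  y <- values[cc]; x <- calls[cc]
  n <- length(y)
  if (n < min_n) {
    return(tibble(slope = NA_real_, r2 = NA_real_, p_value = NA_real_,
                  n = n, testable = FALSE, note = "too few accessions"))
  }
  if (var(x) == 0) {
    return(tibble(slope = NA_real_, r2 = NA_real_, p_value = NA_real_,
                  n = n, testable = FALSE, note = "monomorphic in cell"))
  }
  xc <- x - mean(x); yc <- y - mean(y)
  sxx <- sum(xc^2); sxy <- sum(xc * yc); syy <- sum(yc^2)
  slope <- sxy / sxx
  r2 <- if (syy > 0) sxy^2 / (sxx * syy) else NA_real_
  if (is.na(r2)) {
    return(tibble(slope = slope, r2 = NA_real_, p_value = NA_real_, n = n,
                  testable = FALSE, note = "constant response"))
  }
  if (r2 >= 1) {
    p <- 0
  } else {
    tstat <- slope / sqrt((syy - slope * sxy) / ((n - 2) * sxx))
    p <- 2 * pt(abs(tstat), n - 2, lower.tail = FALSE)
  }
  tibble(slope = slope, r2 = r2, p_value = p, n = n, testable = TRUE,
         note = NA_character_)
}

#' Declare marker-trait associations from scan and confirmation evidence
#'
#' Applies the two-stage declaration rule. A marker-trait pair is declared
#' a marker-trait association (MTA) when its whole-collection
#' structure-corrected scan passes `p < scan_alpha` (in at least one scan
#' cell, i.e. environment or class indicator) and it is confirmed:
#' qualitative traits by a subspecies chi-square with `p < chisq_alpha` in
#' at least one subspecies; quantitative traits by within-cell simple
#' regressions with `p < reg_alpha` whose significant cells span more than
#' one distinct environment or more than one distinct subspecies. All
#' inequalities are strict; a p-value exactly at a threshold does not
#' count.
#'
#' @param scan Tibble of scan results with columns `marker`, `trait`,
#'   `p_value` and optionally `cell` (environment or class); the scan-level
#'   p of a marker-trait pair is the minimum over its scan cells.
#' @param confirm Tibble of confirmation cells with columns `marker`,
#'   `trait`, `subspecies`, `environment`, `statistic`, `p_value`, `r2`,
#'   `testable`.
#' @param trait_kind Named character vector mapping trait to
#'   `"qualitative"` or `"quantitative"`.
#' @param dataset Optional [marker_dataset()] used to attach chromosome
#'   labels.
#' @param scan_alpha,chisq_alpha,reg_alpha Declaration thresholds
#'   (defaults 0.0005, 0.01, 0.05).
#' @param scan_m Family size for the reported Bonferroni-adjusted scan p
#'   (default: number of distinct markers in `scan`).
#' @return A tibble with one row per confirmation cell plus the scan-level
#'   columns: see [write_mta_report()] for the column set.
#' @export
declare_mtas <- function(scan, confirm, trait_kind, dataset = NULL,
                         scan_alpha = 0.0005, chisq_alpha = 0.01,
                         reg_alpha = 0.05, scan_m = NULL) {
  scan <- as_tibble(scan)
  confirm <- as_tibble(confirm)
  if (is.null(scan_m)) scan_m <- length(unique(scan$marker))
  scan_level <- scan |>
    dplyr::group_by(.data$marker, .data$trait) |>
    dplyr::summarise(scan_p = if (all(is.na(.data$p_value))) NA_real_
                     else min(.data$p_value, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(scan_p_bonferroni = bonferroni_adjust(.data$scan_p,
                                                        scan_m))
  cells <- confirm |>
    dplyr::left_join(scan_level, by = c("marker", "trait")) |>
    dplyr::mutate(
      trait_kind = unname(trait_kind[.data$trait]),
      cell_significant = dplyr::case_when(
        !.data$testable | is.na(.data$p_value) ~ FALSE,
        .data$trait_kind == "qualitative" ~ .data$p_value < chisq_alpha,
        TRUE ~ .data$p_value < reg_alpha))
  decl <- cells |>
    dplyr::group_by(.data$marker, .data$trait) |>
    dplyr::summarise(
      trait_kind = .data$trait_kind[1],
      scan_pass = !is.na(.data$scan_p[1]) & .data$scan_p[1] < scan_alpha,
      n_sig = sum(.data$cell_significant),
      n_env = dplyr::n_distinct(.data$environment[.data$cell_significant]),
      n_subsp = dplyr::n_distinct(.data$subspecies[.data$cell_significant]),
      .groups = "drop") |>
    dplyr::mutate(
      confirmed = dplyr::if_else(
        .data$trait_kind == "qualitative",
        .data$n_sig >= 1,
        .data$n_env > 1 | .data$n_subsp > 1),
      declared = .data$scan_pass & .data$confirmed,
      rule = dplyr::case_when(
        !.data$scan_pass ~ "scan not significant",
        !.data$confirmed & .data$trait_kind == "qualitative" ~
          "no chi-square confirmation",
        !.data$confirmed ~ "confirmed in at most one environment and subspecies",
        .data$trait_kind == "qualitative" ~
          "scan + chi-square in >=1 subspecies",
        .data$n_subsp > 1 & .data$n_env > 1 ~
          "scan + regression in >1 environment and >1 subspecies",
        .data$n_env > 1 ~ "scan + regression in >1 environment",
        TRUE ~ "scan + regression in >1 subspecies"))
  out <- cells |>
    dplyr::left_join(decl |>
                       dplyr::select("marker", "trait", "declared", "rule"),
                     by = c("marker", "trait"))
  if (!is.null(dataset)) {
    out <- dplyr::left_join(
      out, dataset$map |> dplyr::select("marker", "chromosome"),
      by = "marker")
  } else if (!("chromosome" %in% names(out))) {
    out$chromosome <- NA_character_
  }
  out |>
    dplyr::select(dplyr::any_of(mta_report_columns), dplyr::everything())
}

#' Concordance of a fixed marker with the subspecies phenotype
#'
#' For a marker-trait association whose marker is monomorphic in one or
#' more subspecies, checks whether the allele state fixed there agrees
#' with the phenotype: from the segregating subspecies the state-wise
#' trait means (or majority classes) determine which state goes with the
#' higher value (or with each class); the fixed subspecies is concordant
#' when its fixed state matches the state predicted by its own relative
#' phenotype (its trait mean being nearer the corresponding state mean,
#' or its dominant class matching that state's majority class).
#'
#' @param marker Marker id.
#' @param dataset A [marker_dataset()].
#' @param values Named per-accession numeric values (quantitative traits),
#'   or `NULL`.
#' @param classes Named per-accession class labels (qualitative traits),
#'   or `NULL`. Exactly one of `values`/`classes` must be given.
#' @return A tibble with one row per subspecies in which the marker is
#'   fixed: `subspecies`, `fixed_state`, `predicted_state`, `concordant`,
#'   `evaluable`.
#' @export
monomorphic_concordance <- function(marker, dataset, values = NULL,
                                    classes = NULL) {
  stopifnot(inherits(dataset, "marker_dataset"),
            xor(is.null(values), is.null(classes)))
  x <- dataset$genotypes[, marker]
  subsp <- dataset$subspecies
  acc <- dataset$accession_ids
  fixed_in <- character(); fixed_state <- integer()
  for (s in unique(subsp)) {
    xs <- x[subsp == s]
    xs <- xs[!is.na(xs)]
    if (length(xs) && min(xs) == max(xs)) {
      fixed_in <- c(fixed_in, s)
      fixed_state <- c(fixed_state, unname(xs[1]))
    }
  }
  if (!length(fixed_in)) {
    return(tibble(subspecies = character(), fixed_state = integer(),
                  predicted_state = integer(), concordant = logical(),
                  evaluable = logical()))
  }
  seg <- !(subsp %in% fixed_in)
  pheno <- if (!is.null(values)) values[acc] else classes[acc]
  out <- purrr::map_dfr(seq_along(fixed_in), function(k) {
    s <- fixed_in[k]
    fs <- fixed_state[k]
    in_s <- subsp == s
    ok_seg <- seg & !is.na(x) & !is.na(pheno)
    if (!is.null(values)) {
      m1 <- mean(pheno[ok_seg & x == 1])
      m0 <- mean(pheno[ok_seg & x == 0])
      mf <- mean(pheno[in_s], na.rm = TRUE)
      if (!is.finite(m1) || !is.finite(m0) || !is.finite(mf) || m1 == m0) {
        return(tibble(subspecies = s, fixed_state = fs,
                      predicted_state = NA_integer_, concordant = NA,
                      evaluable = FALSE))
      }
      pred <- as.integer(abs(mf - m1) < abs(mf - m0))
    } else {
      maj <- function(v) {
        v <- v[!is.na(v)]
        if (!length(v)) return(NA_character_)
        names(sort(table(v), decreasing = TRUE))[1]
      }
      c1 <- maj(pheno[ok_seg & x == 1])
      c0 <- maj(pheno[ok_seg & x == 0])
      cf <- maj(pheno[in_s])
      if (is.na(c1) || is.na(c0) || is.na(cf) || c1 == c0) {
        return(tibble(subspecies = s, fixed_state = fs,
                      predicted_state = NA_integer_, concordant = NA,
                      evaluable = FALSE))
      }
      pred <- dplyr::case_when(cf == c1 ~ 1L, cf == c0 ~ 0L,
                               TRUE ~ NA_integer_)
      if (is.na(pred)) {
        return(tibble(subspecies = s, fixed_state = fs,
                      predicted_state = NA_integer_, concordant = NA,
                      evaluable = FALSE))
      }
    }
    tibble(subspecies = s, fixed_state = fs,
           predicted_state = pred,
           concordant = pred == fs, evaluable = TRUE)
  })
  out
}
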