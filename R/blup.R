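#' Fit the augmented-design mixed model for one trait and environment
#'
#' Fits, by REML, the plot-level model of a modified augmented design:
#' check cultivars enter as fixed effects (intercept plus one contrast per
#' check, with the unreplicated test entries as the reference), and the
#' field row, field column and accession effects are independent random
#' terms, `y = Xb + Z_r u_r + Z_c u_c + Z_a u_a + e`. The accession term
#' applies to test entries only (a check plot's genetic mean is its fixed
#' effect), implemented as a random slope on a test-entry indicator so
#' check plots contribute nothing to it. Random terms with fewer than two
#' levels in the data (e.g. a single row) are dropped.
#'
#' The reported BLUP of an accession is the fixed intercept plus its
#' predicted random deviation; deviations are centred (the mean is folded
#' into the intercept), which leaves predictions unchanged and makes the
#' deviations sum to zero exactly. A trait with zero variance returns
#' all-zero variance components and constant BLUPs. Optimizer
#' non-convergence is flagged on the result rather than raised; a singular
#' fixed-effect design is a hard error.
#'
#' @param trial A trial tibble (see [validate_trial()]).
#' @param trait Quantitative trait name.
#' @param environment Environment code.
#' @return An object of class `augmented_reml` with elements `varcomp`
#'   (tibble: component, variance, boundary flag), `blups` (tibble:
#'   accession, blup, deviation, pev), `checks` (fixed check effects),
#'   `intercept`, `logLik`, `converged`, `n_plots`, `trait`,
#'   `environment` and `model` (the underlying fit).
#' @export
fit_augmented_reml <- function(trial, trait, environment) {
  dat <- as_tibble(trial) |>
    dplyr::filter(.data$trait == .env$trait,
                  .data$environment == .env$environment,
                  !is.na(.data$value))
  if (nrow(dat) < 4) abort("too few plots to fit the mixed model")
  n_test <- length(unique(dat$entry[!dat$is_check]))
  if (n_test < 3) abort("need at least 3 test accessions")
  dat <- dat |>
    dplyr::mutate(
      check_f = factor(dplyr::if_else(.data$is_check, .data$entry, ".test")),
      row_f = factor(.data$row), col_f = factor(.data$col),
      entry_f = factor(.data$entry),
      test_dummy = as.numeric(!.data$is_check))
  dat$check_f <- stats::relevel(dat$check_f, ref = ".test")

  has_checks <- nlevels(droplevels(dat$check_f)) > 1
  x_mat <- if (has_checks) stats::model.matrix(~check_f, dat) else
    stats::model.matrix(~1, dat)
  if (qr(x_mat)$rank < ncol(x_mat)) {
    abort("singular fixed-effect design (confounded check contrasts)")
  }

  terms <- c(
    if (nlevels(droplevels(dat$row_f)) > 1) "(1 | row_f)",
    if (nlevels(droplevels(dat$col_f)) > 1) "(1 | col_f)",
    "(0 + test_dummy | entry_f)")
  fixed <- if (has_checks) "check_f" else "1"
  form <- stats::as.formula(
    paste("value ~", fixed, "+", paste(terms, collapse = " + ")))

  zero_var <- isTRUE(all.equal(var(dat$value), 0)) || var(dat$value) == 0
  if (zero_var) {
    accs <- sort(unique(dat$entry[!dat$is_check]))
    comp <- tibble(component = c("row", "col", "accession", "residual"),
                   variance = 0, boundary = TRUE)
    return(structure(list(
      varcomp = comp,
      blups = tibble(accession = accs, blup = dat$value[1], deviation = 0,
                     pev = 0),
      checks = tibble(check = character(), effect = numeric()),
      intercept = dat$value[1], logLik = NA_real_, converged = TRUE,
      n_plots = nrow(dat), trait = trait, environment = environment,
      model = NULL), class = "augmented_reml"))
  }

  fit <- withCallingHandlers(
    lme4::lmer(form, data = dat, REML = TRUE,
               control = lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                                           check.nobs.vs.nRE = "ignore")),
    warning = function(w) invokeRestart("muffleWarning"))
  converged <- length(fit@optinfo$conv$lme4) == 0 &&
    fit@optinfo$conv$opt == 0

  vc <- as.data.frame(lme4::VarCorr(fit))
  get_var <- function(grp) {
    v <- vc$vcov[vc$grp == grp]
    if (length(v)) v[1] else 0
  }
  comp <- tibble(
    component = c("row", "col", "accession", "residual"),
    variance = c(get_var("row_f"), get_var("col_f"), get_var("entry_f"),
                 get_var("Residual")))
  tot <- sum(comp$variance)
  comp$boundary <- comp$variance < 1e-8 * max(tot, 1e-12)

  intercept <- unname(lme4::fixef(fit)["(Intercept)"])
  fe <- lme4::fixef(fit)
  checks <- tibble(
    check = sub("^check_f", "", names(fe)[-1]),
    effect = unname(fe[-1]))

  re <- lme4::ranef(fit, condVar = TRUE)$entry_f
  u <- setNames(re[, "test_dummy"], rownames(re))
  pv <- attr(re, "postVar")
  pev <- setNames(as.numeric(pv[1, 1, ]), rownames(re))
  accs <- sort(unique(dat$entry[!dat$is_check]))
  u <- u[accs]; pev <- pev[accs]
  m <- mean(u)
  blups <- tibble(accession = accs,
                  blup = unname(intercept + m + (u - m)),
                  deviation = unname(u - m),
                  pev = unname(pev))

  structure(list(
    varcomp = comp, blups = blups, checks = checks,
    intercept = intercept + m, logLik = as.numeric(stats::logLik(fit)),
    converged = converged, n_plots = nrow(dat), trait = trait,
    environment = environment, model = fit),
    class = "augmented_reml")
}

#' @export
print.augmented_reml <- function(x, ...) {
  cat(sprintf("<augmented_reml> trait %s, environment %s (%d plots)%s\n",
              x$trait, x$environment, x$n_plots,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(x$varcomp)
  invisible(x)
}

#' Tidiers for augmented-design REML fits
#'
#' `tidy()` returns the variance components, `glance()` a one-row model
#' summary and `augment()` the accession BLUP table.
#'
#' @param x An `augmented_reml` object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.augmented_reml <- function(x, ...) {
  dplyr::mutate(x$varcomp, trait = x$trait, environment = x$environment)
}

#' @rdname tidy.augmented_reml
#' @export
glance.augmented_reml <- function(x, ...) {
  tibble(trait = x$trait, environment = x$environment,
         n_plots = x$n_plots, n_accessions = nrow(x$blups),
         logLik = x$logLik, converged = x$converged,
         intercept = x$intercept)
}

#' @rdname tidy.augmented_reml
#' @export
augment.augmented_reml <- function(x, ...) {
  dplyr::mutate(x$blups, trait = x$trait, environment = x$environment)
}

#' Combine BLUP fits into an accession-by-trait-environment table
#'
#' @param fits A list of `augmented_reml` objects.
#' @param format `"wide"` (default): one row per accession, one
#'   `trait:environment` column per fit, `NA` where an accession was absent
#'   from an environment; or `"long"`: columns accession, trait,
#'   environment, value.
#' @return A tibble.
#' @export
blups_to_table <- function(fits, format = c("wide", "long")) {
  format <- match.arg(format)
  long <- purrr::map_dfr(fits, function(f) {
    tibble(accession = f$blups$accession, trait = f$trait,
           environment = f$environment, value = f$blups$blup)
  })
  dup <- long |>
    dplyr::count(.data$accession, .data$trait, .data$environment) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("conflicting duplicate BLUPs for accession '%s', %s/%s",
                  dup$accession[1], dup$trait[1], dup$environment[1]))
  }
  if (format == "long") return(long)
  long |>
    tidyr::unite("cell", "trait", "environment", sep = ":") |>
    tidyr::pivot_wider(names_from = "cell", values_from = "value")
}
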