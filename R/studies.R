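#' Seeded calibration studies for the declaration pipeline
#'
#' These utilities run the full association declaration machinery
#' ([glm_q_scan()] per environment, [regression_confirm()] in every
#' subspecies-by-environment cell for each scan hit, [declare_mtas()]) on
#' freshly simulated collections, and are used to measure its family-wise
#' error under a global null and its power against a planted QTL.
#'
#' Each run generates a collection with [generate_collection()] (no map
#' and no missing calls: every marker passes the association filter) and
#' accession-level trait values per environment: a shared polygenic value
#' (variance `var_acc`), a subspecies-by-environment shift (sd
#' `subsp_env_sd`) and independent residual noise (variance `var_error`)
#' — the same genetic architecture as the field-trial generator, at the
#' accession level at which the association stage operates. When `qtl` is
#' supplied, the planted marker's slope is calibrated against the
#' accession-level background variance so that its marker R-squared in the
#' calibration subspecies targets `target_r2`.
#'
#' @param n_runs Number of simulated collections.
#' @param seed Master seed; run `i` uses `seed + i`.
#' @param n_accessions Collection sizes (defaults 132/38/13).
#' @param n_markers Markers scanned per run (default 532, the post-filter
#'   count emulated by the generator defaults).
#' @param environments Environment codes (default two).
#' @param qtl Optional one-row tibble (`marker`, `subspecies`,
#'   `target_r2`) planting a quantitative QTL; `marker = "auto"` plants on
#'   the most informative marker (band frequency nearest 0.5 in the
#'   calibration subspecies) of each run's collection.
#' @param scan_alpha,chisq_alpha,reg_alpha Declaration thresholds.
#' @param config_args Extra arguments passed to [sim_config()].
#' @return A tibble with one row per run: `run`, `n_scan_hits`,
#'   `n_declared`, `any_declared`, and for planted runs `qtl_declared`
#'   plus the realized marker R-squared per environment in columns
#'   `realized_r2_<env>`.
#' @export
mta_declaration_study <- function(n_runs, seed,
                                  n_accessions = c(durum = 132,
                                                   turgidum = 38,
                                                   dicoccon = 13),
                                  n_markers = 532,
                                  environments = c("C", "N"),
                                  qtl = NULL,
                                  scan_alpha = 0.0005,
                                  chisq_alpha = 0.01,
                                  reg_alpha = 0.05,
                                  config_args = list()) {
  purrr::map_dfr(seq_len(n_runs), function(i) {
    args <- c(list(
      n_durum = n_accessions[["durum"]],
      n_turgidum = n_accessions[["turgidum"]],
      n_dicoccon = n_accessions[["dicoccon"]],
      n_markers = n_markers, n_mapped = 0,
      missing_marker_frac = 0,
      environments = environments,
      seed = seed + i), config_args)
    cfg <- do.call(sim_config, args)
    coll <- generate_collection(cfg)
    ds <- coll$dataset
    n_acc <- length(ds$accession_ids)
    withr::local_seed(cfg$seed + 500000L)
    g <- rnorm(n_acc, 0, sqrt(cfg$var_acc))
    subsp_idx <- cbind(match(ds$subspecies,
                             c("durum", "turgidum", "dicoccon")),
                       rep(1L, n_acc))
    beta <- 0
    qx <- NULL
    qtl_marker <- NULL
    if (!is.null(qtl)) {
      in_s <- ds$subspecies == qtl$subspecies
      qtl_marker <- qtl$marker
      if (identical(qtl_marker, "auto")) {
        # plant on the most informative marker in the calibration group
        freq <- colMeans(ds$genotypes[in_s, , drop = FALSE], na.rm = TRUE)
        qtl_marker <- names(which.min(abs(freq - 0.5)))
      }
      qx <- ds$genotypes[, qtl_marker]
      vx <- var(qx[in_s])
      bg <- cfg$var_acc + cfg$var_error
      beta <- sqrt(qtl$target_r2 / (1 - qtl$target_r2) * bg / vx)
    }
    responses <- list()
    realized <- list()
    for (env in environments) {
      shift <- rnorm(3, 0, cfg$subsp_env_sd)[subsp_idx[, 1]]
      y <- g + shift + rnorm(n_acc, 0, sqrt(cfg$var_error))
      if (!is.null(qtl)) {
        y <- y + beta * qx
        in_s <- ds$subspecies == qtl$subspecies
        realized[[env]] <- cor(qx[in_s], y[in_s])^2
      }
      responses[[env]] <- setNames(y, ds$accession_ids)
    }
    out <- declare_from_responses(ds, responses,
                                  trait = "trait",
                                  scan_alpha = scan_alpha,
                                  reg_alpha = reg_alpha)
    row <- tibble(run = i,
                  n_scan_hits = out$n_scan_hits,
                  n_declared = out$n_declared,
                  any_declared = out$n_declared > 0)
    if (!is.null(qtl)) {
      row$qtl_marker <- qtl_marker
      row$qtl_declared <- qtl_marker %in% out$declared_markers
      for (env in environments) {
        row[[paste0("realized_r2_", env)]] <- realized[[env]]
      }
    }
    row
  })
}

# scan + all-cell regression confirmation + declaration for one
# quantitative trait given per-environment accession responses
declare_from_responses <- function(dataset, responses, trait = "trait",
                                   scan_alpha = 0.0005, reg_alpha = 0.05) {
  scan <- purrr::imap_dfr(responses, function(y, env) {
    glm_q_scan(y, dataset, markers = dataset$marker_ids) |>
      dplyr::mutate(trait = .env$trait, cell = env)
  })
  hits <- unique(scan$marker[!is.na(scan$p_value) &
                               scan$p_value < scan_alpha])
  n_declared <- 0L
  declared_markers <- character()
  records <- NULL
  if (length(hits)) {
    confirm <- list()
    for (mk in hits) {
      for (s in unique(dataset$subspecies)) {
        in_s <- dataset$subspecies == s
        calls <- dataset$genotypes[in_s, mk]
        for (env in names(responses)) {
          vals <- responses[[env]][dataset$accession_ids[in_s]]
          rc <- regression_confirm(vals, calls)
          confirm[[length(confirm) + 1L]] <- rc |>
            dplyr::mutate(marker = mk, trait = .env$trait, subspecies = s,
                          environment = env, statistic = .data$slope) |>
            dplyr::select("marker", "trait", "subspecies", "environment",
                          "statistic", "p_value", "r2", "testable")
        }
      }
    }
    records <- declare_mtas(scan, dplyr::bind_rows(confirm),
                            trait_kind = setNames("quantitative", trait),
                            scan_alpha = scan_alpha,
                            reg_alpha = reg_alpha,
                            scan_m = length(dataset$marker_ids))
    declared_markers <- unique(records$marker[records$declared])
    n_declared <- length(declared_markers)
  }
  list(n_scan_hits = length(hits), n_declared = n_declared,
       declared_markers = declared_markers, records = records,
       scan = scan)
}

#' Recovery of the LD extent from a known decay curve
#'
#' Simulates syntenic-pair data from the decay curve
#' `R^2(d) = amplitude * exp(-d / tau_cm)` plus Gaussian noise, estimates
#' the extent with [ld_extent()] at a fixed critical baseline, and
#' compares it with the analytic crossing of the noise-free curve,
#' `tau_cm * log(amplitude / threshold)`.
#'
#' @param n_runs Number of seeded replicates.
#' @param seed Master seed.
#' @param n_pairs Syntenic pairs per replicate.
#' @param tau_cm,amplitude Decay scale and amplitude of the true curve.
#' @param threshold Critical `R^2` baseline.
#' @param max_cm Distance range of the simulated pairs.
#' @param noise_sd Noise standard deviation around the curve.
#' @param ... Passed to [ld_extent()].
#' @return A tibble: `run`, `extent_cm`, `analytic_cm`, `rel_error`.
#' @export
ld_extent_recovery <- function(n_runs, seed, n_pairs = 2000, tau_cm = 5,
                               amplitude = 0.4, threshold = 0.0106,
                               max_cm = 50, noise_sd = 0.02, ...) {
  analytic <- tau_cm * log(amplitude / threshold)
  purrr::map_dfr(seq_len(n_runs), function(i) {
    withr::local_seed(seed + i)
    d <- runif(n_pairs, 0, max_cm)
    r2 <- amplitude * exp(-d / tau_cm) + rnorm(n_pairs, 0, noise_sd)
    est <- ld_extent(d, r2, threshold = threshold, ...)
    tibble(run = i, extent_cm = est$extent_cm, analytic_cm = analytic,
           rel_error = abs(est$extent_cm - analytic) / analytic)
  })
}

#' Recovery of augmented-design variance components by REML
#'
#' Generates seeded field trials with known variance components at the
#' default layout, fits each with [fit_augmented_reml()] and reports the
#' relative error of every estimated component.
#'
#' @param n_runs Number of seeded trials.
#' @param seed Master seed.
#' @param config A [sim_config()]; its `var_*` entries are the truth. One
#'   environment is fitted per run.
#' @param dataset Optional pre-generated collection (defaults to
#'   `generate_collection(config)`); only entry ids matter for this study.
#' @return A tibble with one row per run and component: `run`,
#'   `component`, `true`, `estimate`, `rel_error`, `converged`.
#' @export
reml_recovery <- function(n_runs, seed, config = NULL, dataset = NULL) {
  if (is.null(config)) {
    config <- sim_config(environments = "C", qtl = NULL,
                         missing_marker_frac = 0, n_markers = 20,
                         n_mapped = 0, seed = seed)
  }
  if (is.null(dataset)) dataset <- generate_collection(config)$dataset
  truth <- c(row = config$var_row, col = config$var_col,
             accession = config$var_acc, residual = config$var_error)
  purrr::map_dfr(seq_len(n_runs), function(i) {
    tr <- generate_trial(dataset, config, seed = seed + 10L * i)
    fit <- fit_augmented_reml(tr$trial, config$quantitative_traits[1],
                              config$environments[1])
    fit$varcomp |>
      dplyr::mutate(run = i, true = unname(truth[.data$component]),
                    estimate = .data$variance,
                    rel_error = abs(.data$estimate - .data$true) /
                      .data$true,
                    converged = fit$converged) |>
      dplyr::select("run", "component", "true", "estimate", "rel_error",
                    "converged")
  })
}
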