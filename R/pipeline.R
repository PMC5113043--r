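#' Run the full analysis pipeline on a synthetic or on-disk collection
#'
#' Wires the stages together: (optionally) simulate a collection and its
#' field trial, fit per-environment REML BLUPs for every quantitative
#' trait, compute the diversity table and monomorphic scan, the LD summary,
#' the structure-corrected association scan with confirmation and
#' declaration, the concordance check for declared markers fixed in some
#' subspecies, and the supporting ANOVA / correlation statistics. All
#' report files are written as tab-separated text into `out_dir`, together
#' with a machine-readable JSON manifest recording the package version,
#' seed, thresholds and per-stage wall time.
#'
#' @param config A [sim_config()]; its `seed` drives every stage.
#' @param out_dir Output directory.
#' @param dataset,trial Optional pre-built inputs; when supplied the
#'   simulate stage is skipped.
#' @param stages Character vector of stages to run (default all):
#'   `"simulate"`, `"blup"`, `"diversity"`, `"ld"`, `"associate"`,
#'   `"stats"`.
#' @param scan_alpha,chisq_alpha,reg_alpha,max_missing Association
#'   thresholds (defaults 0.0005, 0.01, 0.05, 0.05).
#' @param n_perm Permutations for the LD significance of syntenic pairs;
#'   `0` skips the permutation stage (the critical-R2/extent estimates do
#'   not depend on it).
#' @return A list with the in-memory results of every stage, invisibly.
#' @export
run_pipeline <- function(config, out_dir, dataset = NULL, trial = NULL,
                         stages = c("simulate", "blup", "diversity", "ld",
                                    "associate", "stats"),
                         scan_alpha = 0.0005, chisq_alpha = 0.01,
                         reg_alpha = 0.05, max_missing = 0.05,
                         n_perm = 0) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  timings <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    message("[", name, "] running")
    out <- tryCatch(expr, error = function(e) {
      abort(paste0("stage '", name, "' failed: ", conditionMessage(e)))
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }
  truth <- NULL

  if ("simulate" %in% stages && is.null(dataset)) {
    sim <- stage("simulate", {
      coll <- generate_collection(config)
      tr <- generate_trial(coll$dataset, config)
      write_marker_dataset(coll$dataset, out_dir)
      write_trial(tr$trial, file.path(out_dir, "trial.tsv"))
      readr::write_tsv(coll$truth$monomorphic,
                       file.path(out_dir, "truth_monomorphic.tsv"),
                       na = "NA", progress = FALSE)
      list(dataset = coll$dataset, trial = tr$trial,
           truth = c(coll$truth, tr$truth))
    })
    dataset <- sim$dataset
    trial <- sim$trial
    truth <- sim$truth
    results$truth <- truth
  }
  if (is.null(dataset)) abort("no dataset: supply one or enable 'simulate'")
  results$dataset <- dataset

  quant <- config$quantitative_traits
  qual <- config$qualitative_traits

  if ("blup" %in% stages && !is.null(trial)) {
    results$blups <- stage("blup", {
      cases <- trial |>
        dplyr::filter(.data$trait %in% quant, !is.na(.data$value)) |>
        dplyr::distinct(.data$trait, .data$environment)
      fits <- purrr::pmap(cases, function(trait, environment) {
        fit_augmented_reml(trial, trait, environment)
      })
      varcomp <- purrr::map_dfr(fits, tidy)
      blup_long <- blups_to_table(fits, format = "long")
      readr::write_tsv(varcomp, file.path(out_dir, "varcomp.tsv"),
                       na = "NA", progress = FALSE)
      readr::write_tsv(blups_to_table(fits, format = "wide"),
                       file.path(out_dir, "blups.tsv"),
                       na = "NA", progress = FALSE)
      list(fits = fits, varcomp = varcomp, table = blup_long)
    })
  }

  if ("diversity" %in% stages) {
    results$diversity <- stage("diversity", {
      dt <- diversity_table(dataset)
      mono <- monomorphic_scan(dataset)
      readr::write_tsv(dt, file.path(out_dir, "diversity_table.tsv"),
                       na = "NA", progress = FALSE)
      readr::write_tsv(mono$markers,
                       file.path(out_dir, "monomorphic_report.tsv"),
                       na = "NA", progress = FALSE)
      list(table = dt, monomorphic = mono)
    })
  }

  if ("ld" %in% stages) {
    results$ld <- stage("ld", {
      ld <- ld_summary(dataset)
      pairs <- ld$pairs
      if (n_perm > 0) {
        syn <- which(pairs$linkage == "syntenic" & pairs$evaluable)
        pvals <- rep(NA_real_, nrow(pairs))
        for (k in seq_along(syn)) {
          i <- syn[k]
          pvals[i] <- ld_permutation_p(
            dataset$genotypes[, pairs$marker_i[i]],
            dataset$genotypes[, pairs$marker_j[i]],
            n_perm = n_perm, seed = config$seed + 1000L + k)
        }
        pairs$perm_p <- pvals
      }
      readr::write_tsv(as_tibble(pairs),
                       file.path(out_dir, "ld_pairs.tsv"),
                       na = "NA", progress = FALSE)
      readr::write_tsv(ld$summary, file.path(out_dir, "ld_summary.tsv"),
                       na = "NA", progress = FALSE)
      ld$pairs <- pairs
      ld
    })
  }

  if ("associate" %in% stages && !is.null(results$blups)) {
    results$mta <- stage("associate", {
      markers <- association_filter(dataset, max_missing)
      subsp_levels <- unique(dataset$subspecies)
      blup_long <- results$blups$table
      scan <- list(); confirm <- list()
      for (tr in quant) {
        envs <- unique(blup_long$environment[blup_long$trait == tr])
        for (env in envs) {
          resp <- blup_long |>
            dplyr::filter(.data$trait == tr, .data$environment == env)
          sc <- glm_q_scan(setNames(resp$value, resp$accession), dataset,
                           markers = markers)
          scan[[length(scan) + 1L]] <- sc |>
            dplyr::mutate(trait = tr, cell = env)
          hits <- sc$marker[!is.na(sc$p_value) & sc$p_value < scan_alpha]
          for (mk in hits) {
            for (s in subsp_levels) {
              in_s <- dataset$subspecies == s
              vals <- setNames(resp$value, resp$accession)
              vals <- vals[dataset$accession_ids[in_s]]
              rc <- regression_confirm(
                vals, dataset$genotypes[dataset$accession_ids[in_s], mk])
              confirm[[length(confirm) + 1L]] <- rc |>
                dplyr::mutate(marker = mk, trait = tr, subspecies = s,
                              environment = env,
                              statistic = .data$slope) |>
                dplyr::select("marker", "trait", "subspecies",
                              "environment", "statistic", "p_value", "r2",
                              "testable")
            }
          }
        }
      }
      if (length(qual) && !is.null(trial)) {
        class_tbl <- trial |>
          dplyr::filter(.data$trait %in% qual, !is.na(.data$class)) |>
          dplyr::distinct(.data$trait, .data$entry, .data$class)
        for (tr in qual) {
          cls <- class_tbl |> dplyr::filter(.data$trait == tr)
          labels <- setNames(cls$class, cls$entry)[dataset$accession_ids]
          for (lv in unique(labels[!is.na(labels)])) {
            ind <- setNames(as.numeric(labels == lv),
                            dataset$accession_ids)
            if (sum(ind, na.rm = TRUE) < 5) next
            sc <- glm_q_scan(ind, dataset, markers = markers)
            scan[[length(scan) + 1L]] <- sc |>
              dplyr::mutate(trait = tr, cell = lv)
          }
          sc_all <- dplyr::bind_rows(scan) |>
            dplyr::filter(.data$trait == tr)
          hits <- unique(sc_all$marker[!is.na(sc_all$p_value) &
                                         sc_all$p_value < scan_alpha])
          for (mk in hits) {
            for (s in subsp_levels) {
              in_s <- dataset$subspecies == s
              cc <- chisq_confirm(labels[in_s],
                                  dataset$genotypes[in_s, mk])
              confirm[[length(confirm) + 1L]] <- cc |>
                dplyr::mutate(marker = mk, trait = tr, subspecies = s,
                              environment = config$environments[1],
                              r2 = NA_real_) |>
                dplyr::select("marker", "trait", "subspecies",
                              "environment", "statistic", "p_value", "r2",
                              "testable")
            }
          }
        }
      }
      scan <- dplyr::bind_rows(scan) |>
        dplyr::rename(scan_cell = "cell")
      kind <- c(setNames(rep("quantitative", length(quant)), quant),
                setNames(rep("qualitative", length(qual)), qual))
      if (length(confirm)) {
        records <- declare_mtas(scan, dplyr::bind_rows(confirm), kind,
                                dataset = dataset,
                                scan_alpha = scan_alpha,
                                chisq_alpha = chisq_alpha,
                                reg_alpha = reg_alpha,
                                scan_m = length(markers))
      } else {
        records <- tibble(marker = character(), trait = character(),
                          declared = logical())
      }
      write_mta_report(records, file.path(out_dir, "mta_report.tsv"))

      # concordance for declared markers fixed in some subspecies
      conc <- list()
      declared <- records |>
        dplyr::filter(.data$declared) |>
        dplyr::distinct(.data$marker, .data$trait)
      if (nrow(declared)) {
        for (i in seq_len(nrow(declared))) {
          mk <- declared$marker[i]; tr <- declared$trait[i]
          res <- if (kind[[tr]] == "quantitative") {
            resp <- blup_long |>
              dplyr::filter(.data$trait == tr) |>
              dplyr::group_by(.data$accession) |>
              dplyr::summarise(value = mean(.data$value))
            monomorphic_concordance(
              mk, dataset, values = setNames(resp$value, resp$accession))
          } else {
            cls <- trial |>
              dplyr::filter(.data$trait == tr, !is.na(.data$class)) |>
              dplyr::distinct(.data$entry, .data$class)
            monomorphic_concordance(
              mk, dataset, classes = setNames(cls$class, cls$entry))
          }
          if (nrow(res)) {
            conc[[length(conc) + 1L]] <- res |>
              dplyr::mutate(marker = mk, trait = tr)
          }
        }
      }
      conc <- if (length(conc)) dplyr::bind_rows(conc) else
        tibble(marker = character(), trait = character(),
               subspecies = character(), fixed_state = integer(),
               predicted_state = integer(), concordant = logical(),
               evaluable = logical())
      readr::write_tsv(conc, file.path(out_dir, "concordance_report.tsv"),
                       na = "NA", progress = FALSE)
      list(scan = scan, records = records, concordance = conc)
    })
  }

  if ("stats" %in% stages && !is.null(results$blups)) {
    results$stats <- stage("stats", {
      blup_long <- results$blups$table
      subsp <- setNames(dataset$subspecies, dataset$accession_ids)
      adat <- blup_long |>
        dplyr::mutate(subspecies = subsp[.data$accession])
      anova_tbl <- purrr::map_dfr(unique(adat$trait), function(tr) {
        d <- adat |> dplyr::filter(.data$trait == tr)
        if (dplyr::n_distinct(d$environment) < 2) return(NULL)
        two_way_anova(d) |> dplyr::mutate(trait = tr, .before = 1)
      })
      wide <- blups_to_table(results$blups$fits, format = "wide")
      cors <- correlation_matrix(wide[, -1, drop = FALSE])
      if (nrow(anova_tbl)) {
        readr::write_tsv(anova_tbl, file.path(out_dir, "anova.tsv"),
                         na = "NA", progress = FALSE)
      }
      readr::write_tsv(as_tibble(cors),
                       file.path(out_dir, "correlations.tsv"),
                       na = "NA", progress = FALSE)
      list(anova = anova_tbl, correlations = cors)
    })
  }

  manifest <- list(
    package = "durumpanel",
    version = as.character(utils::packageVersion("durumpanel")),
    seed = config$seed,
    thresholds = list(scan_alpha = scan_alpha, chisq_alpha = chisq_alpha,
                      reg_alpha = reg_alpha, max_missing = max_missing,
                      n_perm = n_perm),
    stages = stages,
    timings_s = timings,
    timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
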