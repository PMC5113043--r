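#' Configuration for the synthetic landrace collection
#'
#' Bundles every knob of the synthetic-data generator. The defaults emulate
#' the statistical structure of a 183-accession Spanish tetraploid wheat
#' landrace panel: three subspecies of 132 (*durum*), 38 (*turgidum*) and
#' 13 (*dicoccon*) accessions, 749 dominant biallelic markers of which 329
#' carry consensus-map positions on chromosomes 1A-7B, nine subpopulations
#' nested within subspecies, subspecies-specific monomorphic marker
#' fractions of 11/749, 80/749 and 265/749, distance-dependent LD with a
#' characteristic decay scale `tau_cm`, and marker-wise missingness
#' calibrated so that about 532 markers pass the `< 5%` missing-data filter
#' used for association scans.
#'
#' @param n_durum,n_turgidum,n_dicoccon Subspecies sizes.
#' @param n_markers Total marker count.
#' @param n_mapped Number of markers placed on the cM map.
#' @param pops_per_subspecies Named integer vector allocating the
#'   subpopulations to subspecies (sums to the number of populations).
#' @param mono_fraction Named vector of per-subspecies monomorphic marker
#'   fractions to plant.
#' @param tau_cm LD decay scale in cM: adjacent markers at distance d are
#'   copied with probability `exp(-d / tau_cm)` by the haplotype process.
#'   `tau_cm = 0` switches linkage off.
#' @param chrom_length_cm Length of each of the 14 chromosomes.
#' @param f_subspecies,f_population Drift parameters (Balding-Nichols beta
#'   variances) for subspecies- and population-level allele frequencies.
#' @param q_concentration,q_noise Dirichlet weights used to soften the true
#'   population indicator into an imperfect Q matrix: the accession's own
#'   population receives `q_concentration + q_noise`, every other
#'   population `q_noise`.
#' @param qtl Optional tibble of planted QTL with columns `marker`, `trait`,
#'   `subspecies` (where the effect is calibrated), `target_r2` (marker
#'   R-squared aimed for at plot level in that subspecies, against the
#'   full background variance `var_acc + var_error + var_row + var_col`) and for
#'   qualitative traits `latent_beta` instead of `target_r2`.
#' @param environments Environment codes; defaults to the four
#'   location-year combinations C, N, S, S08.
#' @param env_mean Named vector of environment means (trait units).
#' @param subsp_env_sd Standard deviation of subspecies-by-environment
#'   interaction shifts.
#' @param var_row,var_col,var_acc,var_error Variance components of the
#'   augmented-design trial model (row, column, accession, residual).
#' @param n_checks Number of repeated check entries.
#' @param n_rows,n_cols Field layout dimensions per environment.
#' @param quantitative_traits,qualitative_traits Trait names to simulate.
#' @param n_classes Number of classes for qualitative traits.
#' @param missing_marker_frac Fraction of markers into which missing calls
#'   are injected; all other markers are complete. The default rate range
#'   puts the affected markers above the 5% missing-data cutoff of the
#'   association filter, so the retained count emulates the 532-of-749
#'   post-filter panel.
#' @param missing_rate_range Range (min, max) of the per-marker
#'   missing-call probability within the affected subset.
#' @param seed Mandatory integer seed; all generator randomness derives
#'   from it.
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_durum = 132, n_turgidum = 38, n_dicoccon = 13,
                       n_markers = 749, n_mapped = 329,
                       pops_per_subspecies = c(durum = 6, turgidum = 2,
                                               dicoccon = 1),
                       mono_fraction = c(durum = 11 / 749,
                                         turgidum = 80 / 749,
                                         dicoccon = 265 / 749),
                       tau_cm = 5, chrom_length_cm = 140,
                       f_subspecies = 0.15, f_population = 0.05,
                       q_concentration = 20, q_noise = 0.25,
                       qtl = NULL,
                       environments = c("C", "N", "S", "S08"),
                       env_mean = c(C = 50, N = 48, S = 45, S08 = 46),
                       subsp_env_sd = 0.5,
                       var_row = 1, var_col = 1, var_acc = 4, var_error = 2,
                       n_checks = 4, n_rows = 14, n_cols = 16,
                       quantitative_traits = "qt1",
                       qualitative_traits = character(),
                       n_classes = 3,
                       missing_marker_frac = 0.29,
                       missing_rate_range = c(0.07, 0.15),
                       seed) {
  if (missing(seed)) abort("`seed` is mandatory")
  sizes <- c(durum = n_durum, turgidum = n_turgidum, dicoccon = n_dicoccon)
  if (any(sizes <= 0)) abort("subspecies sizes must be positive")
  if (n_mapped > n_markers) abort("n_mapped cannot exceed n_markers")
  if (any(mono_fraction < 0 | mono_fraction >= 1)) {
    abort("mono_fraction must lie in [0, 1)")
  }
  vars <- c(var_row, var_col, var_acc, var_error)
  if (any(vars < 0)) abort("variance components must be non-negative")
  if (!is.null(qtl)) {
    qtl <- as_tibble(qtl)
    if (!all(c("marker", "trait", "subspecies") %in% names(qtl))) {
      abort("`qtl` needs columns marker, trait, subspecies")
    }
    if ("target_r2" %in% names(qtl) &&
        any(!is.na(qtl$target_r2) &
            (qtl$target_r2 <= 0 | qtl$target_r2 >= 1))) {
      abort("target_r2 must lie in (0, 1)")
    }
  }
  structure(
    list(sizes = sizes, n_markers = n_markers, n_mapped = n_mapped,
         pops_per_subspecies = pops_per_subspecies,
         mono_fraction = mono_fraction, tau_cm = tau_cm,
         chrom_length_cm = chrom_length_cm, f_subspecies = f_subspecies,
         f_population = f_population, q_concentration = q_concentration,
         q_noise = q_noise, qtl = qtl, environments = environments,
         env_mean = env_mean, subsp_env_sd = subsp_env_sd,
         var_row = var_row, var_col = var_col, var_acc = var_acc,
         var_error = var_error, n_checks = n_checks, n_rows = n_rows,
         n_cols = n_cols, quantitative_traits = quantitative_traits,
         qualitative_traits = qualitative_traits, n_classes = n_classes,
         missing_marker_frac = missing_marker_frac,
         missing_rate_range = missing_rate_range,
         seed = as.integer(seed)),
    class = "sim_config")
}

wheat_chromosomes <- function() {
  paste0(rep(1:7, each = 2), rep(c("A", "B"), 7))
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# Balding-Nichols style beta draw around an ancestral frequency p with
# drift parameter f; f -> 0 degenerates to p itself.
rbeta_bn <- function(n, p, f) {
  if (f <= 0) return(rep(p, length.out = n))
  k <- (1 - f) / f
  stats::rbeta(n, shape1 = p * k, shape2 = (1 - p) * k)
}

#' Generate a synthetic marker collection with ground-truth bookkeeping
#'
#' Simulates dominant 0/1 band-presence calls for a structured collection.
#' Allele frequencies are drawn hierarchically (ancestral frequency,
#' subspecies frequency, population frequency), markers are laid out
#' uniformly on the 14 tetraploid wheat chromosomes, and linkage
#' disequilibrium is induced by a first-order Markov copying process along
#' each chromosome: an accession copies the previous marker's call with
#' probability `exp(-d / tau_cm)` and otherwise draws a fresh Bernoulli
#' call from its population frequency. Per-subspecies monomorphic marker
#' sets are planted by fixing the band state, missing calls are injected
#' marker-wise, and a Dirichlet-softened Q matrix is emitted.
#'
#' The returned truth ledger records, per marker and subspecies, the
#' *realized* monomorphic status of the completed matrix (before missing
#' calls are injected), the planted flag and fixed state, and the
#' per-marker missing-call counts, so downstream scans can be checked
#' against ground truth.
#'
#' @param config A [sim_config()].
#' @return A list with elements `dataset` (a [marker_dataset()]) and
#'   `truth` (list of tibbles: `monomorphic`, `missingness`, `populations`,
#'   `qtl`).
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  sizes <- config$sizes
  n_acc <- sum(sizes)
  n_mk <- config$n_markers
  subspecies <- rep(names(sizes), times = sizes)
  accession_ids <- sprintf("acc%03d", seq_len(n_acc))

  # populations nested in subspecies
  pops <- config$pops_per_subspecies
  pop_ids <- paste0("pop", seq_len(sum(pops)))
  pop_subsp <- rep(names(pops), times = pops)
  acc_pop <- integer(n_acc)
  for (s in names(sizes)) {
    own <- which(pop_subsp == s)
    idx <- which(subspecies == s)
    acc_pop[idx] <- sample(rep_len(own, length(idx)))
  }

  # map: n_mapped markers uniform on 14 chromosomes, rest unmapped
  marker_ids <- sprintf("mk%04d", seq_len(n_mk))
  chroms <- wheat_chromosomes()
  mapped_idx <- sort(sample.int(n_mk, config$n_mapped))
  chrom <- rep(NA_character_, n_mk)
  pos <- rep(NA_real_, n_mk)
  chrom[mapped_idx] <- sample(chroms, config$n_mapped, replace = TRUE)
  pos[mapped_idx] <- runif(config$n_mapped, 0, config$chrom_length_cm)
  map <- tibble(marker = marker_ids, chromosome = chrom, position_cm = pos)

  # hierarchical allele (band) frequencies
  p_anc <- runif(n_mk, 0.1, 0.9)
  n_pop <- length(pop_ids)
  p_pop <- matrix(0, n_pop, n_mk)
  for (s in names(sizes)) {
    p_sub <- rbeta_bn(n_mk, p_anc, config$f_subspecies)
    for (k in which(pop_subsp == s)) {
      p_pop[k, ] <- rbeta_bn(n_mk, p_sub, config$f_population)
    }
  }
  p_pop <- pmin(pmax(p_pop, 0.02), 0.98)

  # genotype calls: Markov copying along each chromosome, fresh draws
  # elsewhere; unmapped markers are linkage-free
  geno <- matrix(NA_integer_, n_acc, n_mk,
                 dimnames = list(accession_ids, marker_ids))
  draw <- function(j) rbinom(n_acc, 1L, p_pop[acc_pop, j])
  unmapped <- which(is.na(chrom))
  for (j in unmapped) geno[, j] <- draw(j)
  for (ch in chroms) {
    on_ch <- which(!is.na(chrom) & chrom == ch)
    if (!length(on_ch)) next
    on_ch <- on_ch[order(pos[on_ch])]
    geno[, on_ch[1]] <- draw(on_ch[1])
    if (length(on_ch) > 1) {
      for (i in seq(2, length(on_ch))) {
        j <- on_ch[i]; jp <- on_ch[i - 1]
        d <- pos[j] - pos[jp]
        rho <- if (config$tau_cm > 0) exp(-d / config$tau_cm) else 0
        copy <- runif(n_acc) < rho
        fresh <- draw(j)
        geno[, j] <- ifelse(copy, geno[, jp], fresh)
      }
    }
  }

  # plant per-subspecies monomorphic sets (state = rounded subspecies mean)
  qtl_markers <- if (!is.null(config$qtl)) {
    split(config$qtl$marker, config$qtl$subspecies)
  } else list()
  planted <- list()
  for (s in names(sizes)) {
    n_fix <- round(config$mono_fraction[[s]] * n_mk)
    eligible <- setdiff(marker_ids, qtl_markers[[s]])
    if (n_fix > length(eligible)) {
      abort(sprintf(
        "infeasible config: cannot fix %d markers in %s with planted QTL excluded",
        n_fix, s))
    }
    fix <- sample(eligible, n_fix)
    idx <- which(subspecies == s)
    jfix <- match(fix, marker_ids)
    states <- integer(length(jfix))
    for (kk in seq_along(jfix)) {
      j <- jfix[kk]
      state <- as.integer(mean(geno[idx, j]) >= 0.5)
      geno[idx, j] <- state
      states[kk] <- state
    }
    planted[[s]] <- tibble(subspecies = s, marker = fix,
                           planted_state = states)
  }
  planted <- dplyr::bind_rows(planted)

  # realized monomorphic status before missingness
  mono <- purrr::map_dfr(names(sizes), function(s) {
    idx <- which(subspecies == s)
    sub <- geno[idx, , drop = FALSE]
    rng <- apply(sub, 2, function(x) c(min(x), max(x)))
    tibble(subspecies = s, marker = marker_ids,
           monomorphic = rng[1, ] == rng[2, ],
           fixed_state = ifelse(rng[1, ] == rng[2, ], rng[1, ], NA_integer_))
  }) |>
    dplyr::left_join(planted, by = c("subspecies", "marker")) |>
    dplyr::mutate(planted = !is.na(.data$planted_state)) |>
    dplyr::select(-"planted_state")

  # marker-wise missingness restricted to a subset, calibrated to fail the
  # <5% association filter; all other markers stay complete
  n_miss <- round(config$missing_marker_frac * n_mk)
  subset_miss <- sample.int(n_mk, n_miss)
  rate <- rep(0, n_mk)
  rate[subset_miss] <- runif(n_miss, config$missing_rate_range[1],
                             config$missing_rate_range[2])
  n_missing <- integer(n_mk)
  if (any(rate > 0)) {
    for (j in which(rate > 0)) {
      miss <- runif(n_acc) < rate[j]
      geno[miss, j] <- NA_integer_
      n_missing[j] <- sum(miss)
    }
  }
  missingness <- tibble(marker = marker_ids, missing_rate = rate,
                        n_missing = n_missing,
                        missing_fraction = n_missing / n_acc)

  # softened Q matrix
  q <- matrix(0, n_acc, n_pop, dimnames = list(accession_ids, pop_ids))
  for (i in seq_len(n_acc)) {
    alpha <- rep(config$q_noise, n_pop)
    alpha[acc_pop[i]] <- alpha[acc_pop[i]] + config$q_concentration
    q[i, ] <- rdirichlet1(alpha)
  }

  dataset <- marker_dataset(geno, map = map, subspecies = subspecies, q = q)
  truth <- list(
    monomorphic = mono,
    missingness = missingness,
    populations = tibble(accession = accession_ids,
                         subspecies = subspecies,
                         population = pop_ids[acc_pop]),
    qtl = config$qtl)
  list(dataset = dataset, truth = truth)
}

#' Simulate an augmented-design field trial on a collection
#'
#' Lays out, for each environment, every accession in exactly one plot of an
#' `n_rows` by `n_cols` grid, fills the remaining plots by cycling through
#' the repeated checks, and generates plot values as environment mean +
#' subspecies-by-environment shift + genetic value + random row effect +
#' random column effect + residual, with the variances of the
#' configuration. Quantitative genetic values are a polygenic draw
#' (variance `var_acc`) plus planted-QTL effects whose slopes are
#' calibrated so the marker explains `target_r2` of the plot-level variance
#' within the calibration subspecies. Qualitative traits threshold a latent
#' variable (planted marker effect + standard normal noise) into classes.
#'
#' @param dataset A [marker_dataset()], typically from
#'   [generate_collection()].
#' @param config The same [sim_config()].
#' @param seed Optional integer overriding `config$seed + 1` for the trial
#'   randomness.
#' @return A list with `trial` (validated trial tibble) and `truth`
#'   (tibbles `qtl_effects` with the calibrated slopes and
#'   `qtl_realized` with per-environment realized marker R-squared, and
#'   `genetic_values`).
#' @export
generate_trial <- function(dataset, config, seed = NULL) {
  stopifnot(inherits(dataset, "marker_dataset"),
            inherits(config, "sim_config"))
  if (is.null(seed)) seed <- config$seed + 1L
  withr::local_seed(seed)
  n_acc <- length(dataset$accession_ids)
  n_plots <- config$n_rows * config$n_cols
  if (n_plots < n_acc + 2L * config$n_checks) {
    abort(sprintf("layout too small: %d plots for %d entries + %d checks x2",
                  n_plots, n_acc, config$n_checks))
  }
  checks <- sprintf("check%d", seq_len(config$n_checks))
  subsp <- setNames(dataset$subspecies, dataset$accession_ids)

  # marker columns used by QTL, mean-imputed for value generation
  qtl <- config$qtl
  marker_col <- function(mk) {
    x <- dataset$genotypes[, mk]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    x
  }
  # calibrated slope: beta^2 var(x | subspecies) = r2/(1-r2) * background
  qtl_eff <- NULL
  if (!is.null(qtl)) {
    quant <- qtl[qtl$trait %in% config$quantitative_traits, , drop = FALSE]
    if (nrow(quant)) {
      bg <- config$var_acc + config$var_error + config$var_row +
        config$var_col
      qtl_eff <- quant |>
        dplyr::rowwise() |>
        dplyr::mutate(beta = {
          x <- marker_col(.data$marker)[subsp == .data$subspecies]
          vx <- var(x)
          if (!is.finite(vx) || vx <= 0) {
            abort(sprintf("QTL marker %s is monomorphic in %s",
                          .data$marker, .data$subspecies))
          }
          sqrt(.data$target_r2 / (1 - .data$target_r2) * bg / vx)
        }) |>
        dplyr::ungroup()
    }
  }

  # genetic values: polygenic + QTL, constant across environments
  polygenic <- rnorm(n_acc, 0, sqrt(config$var_acc))
  names(polygenic) <- dataset$accession_ids
  check_gv <- rnorm(config$n_checks, 0, sqrt(config$var_acc))
  names(check_gv) <- checks
  genetic <- purrr::map(config$quantitative_traits, function(tr) {
    g <- polygenic
    if (!is.null(qtl_eff)) {
      for (i in which(qtl_eff$trait == tr)) {
        g <- g + qtl_eff$beta[i] * marker_col(qtl_eff$marker[i])
      }
    }
    g
  })
  names(genetic) <- config$quantitative_traits

  se_shift <- matrix(rnorm(3 * length(config$environments), 0,
                           config$subsp_env_sd),
                     nrow = 3,
                     dimnames = list(c("durum", "turgidum", "dicoccon"),
                                     config$environments))

  records <- list()
  realized <- list()
  for (env in config$environments) {
    plots <- tibble(row = rep(seq_len(config$n_rows), config$n_cols),
                    col = rep(seq_len(config$n_cols),
                              each = config$n_rows))
    ord <- sample.int(n_plots)
    entry <- c(dataset$accession_ids,
               rep_len(checks, n_plots - n_acc))[order(ord)]
    # order(ord) is a random permutation; every accession lands in exactly
    # one plot, checks cycle through the remainder
    plots$entry <- entry
    plots$is_check <- entry %in% checks
    row_eff <- rnorm(config$n_rows, 0, sqrt(config$var_row))
    col_eff <- rnorm(config$n_cols, 0, sqrt(config$var_col))
    mu <- config$env_mean[[env]]
    for (tr in config$quantitative_traits) {
      g <- numeric(n_plots)
      shift <- numeric(n_plots)
      nc <- !plots$is_check
      g[nc] <- genetic[[tr]][plots$entry[nc]]
      g[!nc] <- check_gv[plots$entry[!nc]]
      shift[nc] <- se_shift[cbind(subsp[plots$entry[nc]],
                                  rep(env, sum(nc)))]
      value <- mu + shift + g + row_eff[plots$row] + col_eff[plots$col] +
        rnorm(n_plots, 0, sqrt(config$var_error))
      records[[length(records) + 1L]] <- plots |>
        dplyr::mutate(environment = env, trait = tr, value = value,
                      class = NA_character_)
      if (!is.null(qtl_eff)) {
        for (i in which(qtl_eff$trait == tr)) {
          s <- qtl_eff$subspecies[i]
          keep <- !plots$is_check & subsp[plots$entry] == s
          x <- dataset$genotypes[plots$entry[keep], qtl_eff$marker[i]]
          ok <- !is.na(x)
          r2 <- if (sum(ok) > 2 && var(x[ok]) > 0) {
            cor(x[ok], value[keep][ok])^2
          } else NA_real_
          realized[[length(realized) + 1L]] <- tibble(
            marker = qtl_eff$marker[i], trait = tr, subspecies = s,
            environment = env, realized_r2 = r2)
        }
      }
    }
  }

  # qualitative traits: latent threshold model, scored once (first
  # environment) on accessions only
  if (length(config$qualitative_traits)) {
    env <- config$environments[1]
    base <- dplyr::bind_rows(records) |>
      dplyr::filter(.data$environment == env,
                    .data$trait == config$quantitative_traits[1],
                    !.data$is_check) |>
      dplyr::distinct(.data$row, .data$col, .data$entry, .data$is_check)
    for (tr in config$qualitative_traits) {
      latent <- rnorm(n_acc)
      names(latent) <- dataset$accession_ids
      if (!is.null(qtl)) {
        qq <- qtl[qtl$trait == tr, , drop = FALSE]
        for (i in seq_len(nrow(qq))) {
          b <- if ("latent_beta" %in% names(qq) &&
                   !is.na(qq$latent_beta[i])) qq$latent_beta[i] else 2
          latent <- latent + b * marker_col(qq$marker[i])
        }
      }
      cuts <- quantile(latent, probs = seq_len(config$n_classes - 1) /
                         config$n_classes)
      cls <- paste0("class", findInterval(latent, cuts) + 1L)
      names(cls) <- names(latent)
      records[[length(records) + 1L]] <- base |>
        dplyr::mutate(environment = env, trait = tr, value = NA_real_,
                      class = cls[.data$entry])
    }
  }

  trial <- dplyr::bind_rows(records) |>
    dplyr::select(dplyr::all_of(trial_columns)) |>
    validate_trial()
  truth <- list(
    qtl_effects = qtl_eff,
    qtl_realized = if (length(realized)) dplyr::bind_rows(realized) else NULL,
    genetic_values = tibble(
      accession = rep(dataset$accession_ids,
                      length(config$quantitative_traits)),
      trait = rep(config$quantitative_traits, each = n_acc),
      genetic_value = unlist(genetic, use.names = FALSE)))
  list(trial = trial, truth = truth)
}
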