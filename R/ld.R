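#' Pairwise linkage disequilibrium between dominant markers
#'
#' Computes, for every unordered pair of markers, the allele-frequency
#' correlation `r` (Pearson correlation of the two 0/1 columns over
#' pairwise-complete accessions) and `R^2 = r^2`. Pairs on the same known
#' chromosome are classed `syntenic` and carry the cM distance; pairs on
#' different known chromosomes are `unlinked`; pairs involving an unmapped
#' marker are `unknown` and enter neither class. Pairs with fewer than
#' `min_complete` pairwise-complete accessions, or with a zero-variance
#' column in the pairwise-complete subset, are kept in the table but
#' flagged non-evaluable.
#'
#' The attribute `n_grid` records the size of the full ordered pairwise
#' grid including self-pairs (`n_markers^2`), the enumeration convention
#' used for pair-count bookkeeping, while statistics are computed once per
#' unordered pair.
#'
#' @param dataset A [marker_dataset()].
#' @param mapped_only Restrict to markers with a known map position
#'   (default `TRUE`).
#' @param min_complete Minimum pairwise-complete accessions per pair.
#' @return A tibble of class `ld_pairs` with columns `marker_i`,
#'   `marker_j`, `n`, `r`, `r2`, `distance_cm`, `linkage` and `evaluable`;
#'   attributes `n_markers` and `n_grid`.
#' @export
ld_pairs <- function(dataset, mapped_only = TRUE, min_complete = 20) {
  stopifnot(inherits(dataset, "marker_dataset"))
  map <- dataset$map
  keep <- if (mapped_only) {
    !is.na(map$chromosome) & !is.na(map$position_cm)
  } else rep(TRUE, nrow(map))
  ids <- dataset$marker_ids[keep]
  m <- length(ids)
  if (m < 2) abort("need at least two markers for pairwise LD")
  geno <- dataset$genotypes[, keep, drop = FALSE]
  cmat <- suppressWarnings(cor(geno, use = "pairwise.complete.obs"))
  obs <- !is.na(geno)
  nmat <- crossprod(obs)
  chrom <- map$chromosome[keep]
  pos <- map$position_cm[keep]
  ut <- upper.tri(cmat)
  ij <- which(ut, arr.ind = TRUE)
  i <- ij[, 1]; j <- ij[, 2]
  same <- !is.na(chrom[i]) & !is.na(chrom[j]) & chrom[i] == chrom[j]
  diff <- !is.na(chrom[i]) & !is.na(chrom[j]) & chrom[i] != chrom[j]
  linkage <- dplyr::case_when(same ~ "syntenic", diff ~ "unlinked",
                              TRUE ~ "unknown")
  r <- cmat[ut]
  n <- nmat[ut]
  evaluable <- !is.na(r) & n >= min_complete
  out <- tibble(
    marker_i = ids[i], marker_j = ids[j], n = as.integer(n),
    r = ifelse(evaluable, r, NA_real_),
    r2 = ifelse(evaluable, r^2, NA_real_),
    distance_cm = ifelse(same, abs(pos[i] - pos[j]), NA_real_),
    linkage = linkage, evaluable = evaluable)
  structure(out, class = c("ld_pairs", class(out)),
            n_markers = m, n_grid = as.numeric(m)^2)
}

#' Permutation p-value for the LD of a marker pair
#'
#' Permutes one column's calls across accessions `n_perm` times and counts
#' permuted `R^2` values at least as large as the observed one:
#' `p = (1 + #{R2_perm >= R2_obs}) / (n_perm + 1)`.
#'
#' @param x,y Integer 0/1/NA call vectors over the same accessions.
#' @param n_perm Number of permutations (default 1000).
#' @param seed Integer seed making the permutation stream reproducible.
#' @return The permutation p-value in `(0, 1]`.
#' @export
ld_permutation_p <- function(x, y, n_perm = 1000, seed) {
  cc <- complete.cases(x, y)
  x <- x[cc]; y <- y[cc]
  if (sd(x) == 0 || sd(y) == 0) abort("both columns must be variable")
  withr::local_seed(seed)
  n <- length(x)
  xc <- x - mean(x)
  yc <- y - mean(y)
  denom <- sqrt(sum(xc^2) * sum(yc^2))
  obs <- (sum(xc * yc) / denom)^2
  perm_idx <- matrix(0L, n, n_perm)
  for (k in seq_len(n_perm)) perm_idx[, k] <- sample.int(n)
  cross <- crossprod(xc, matrix(yc[perm_idx], n, n_perm))
  perm <- (as.numeric(cross) / denom)^2
  (1 + sum(perm >= obs - 1e-12)) / (n_perm + 1)
}

#' Critical R-squared from unlinked marker pairs
#'
#' Square-root transforms the unlinked-pair `R^2` values to approximate
#' normality and takes the parametric 95th percentile of that distribution,
#' squared back: `(mean(sqrt(R2)) + z_0.95 * sd(sqrt(R2)))^2`. Beyond this
#' population-specific baseline, LD is taken to be due to genetic linkage
#' rather than to population structure or drift. With fewer than
#' `min_pairs` values the empirical 95th percentile is used instead, with a
#' warning.
#'
#' @param r2_unlinked Numeric vector of `R^2` values for unlinked pairs.
#' @param min_pairs Minimum sample size for the parametric estimate.
#' @return The critical `R^2` threshold.
#' @export
critical_r2 <- function(r2_unlinked, min_pairs = 30) {
  r2_unlinked <- r2_unlinked[!is.na(r2_unlinked)]
  if (length(r2_unlinked) == 0) abort("no unlinked R^2 values")
  if (length(r2_unlinked) < min_pairs) {
    warn(sprintf(
      "only %d unlinked pairs; falling back to the empirical 95th percentile",
      length(r2_unlinked)))
    return(unname(quantile(r2_unlinked, 0.95, type = 7)))
  }
  s <- sqrt(r2_unlinked)
  (mean(s) + qnorm(0.95) * sd(s))^2
}

#' Extent of linkage disequilibrium from a smoothed decay curve
#'
#' Fits a locally weighted polynomial smoother (loess, tricube weights) of
#' syntenic `R^2` on cM distance, evaluates it on a distance grid and takes
#' the first downward crossing of the critical-`R^2` baseline, linearly
#' interpolated between grid points, as the extent of LD. A curve that
#' starts below the baseline gives extent 0; a curve that never crosses
#' (or a non-positive threshold) is flagged not estimable, with the fitted
#' curve returned for inspection.
#'
#' @param distance_cm,r2 Syntenic pair distances and `R^2` values.
#' @param threshold Critical `R^2` baseline (see [critical_r2()]).
#' @param span Loess span (default 0.5).
#' @param degree Local polynomial degree (default 2).
#' @param grid_step Evaluation grid step in cM (default 0.1).
#' @param family Loess fitting family; `"symmetric"` (default) adds
#'   robustness iterations against outlying pairs.
#' @param min_pairs Minimum number of pairs (default 50).
#' @return A list of class `ld_extent`: `extent_cm`, `estimable`,
#'   `threshold` and `curve` (tibble `distance_cm`, `r2_fit`).
#' @export
ld_extent <- function(distance_cm, r2, threshold, span = 0.5, degree = 2,
                      grid_step = 0.1, family = "symmetric",
                      min_pairs = 50) {
  ok <- !is.na(distance_cm) & !is.na(r2)
  distance_cm <- distance_cm[ok]; r2 <- r2[ok]
  n_dist <- length(unique(distance_cm))
  if (length(r2) < min_pairs || n_dist < 2) {
    return(structure(list(extent_cm = NA_real_, estimable = FALSE,
                          threshold = threshold, curve = NULL),
                     class = "ld_extent"))
  }
  fit <- loess(r2 ~ distance_cm, span = span, degree = degree,
               family = family)
  grid <- seq(min(distance_cm), max(distance_cm), by = grid_step)
  yhat <- predict(fit, newdata = data.frame(distance_cm = grid))
  curve <- tibble(distance_cm = grid, r2_fit = yhat)
  if (threshold <= 0) {
    return(structure(list(extent_cm = max(grid), estimable = FALSE,
                          threshold = threshold, curve = curve),
                     class = "ld_extent"))
  }
  if (yhat[1] <= threshold) {
    return(structure(list(extent_cm = 0, estimable = TRUE,
                          threshold = threshold, curve = curve),
                     class = "ld_extent"))
  }
  below <- which(yhat <= threshold)
  if (!length(below)) {
    return(structure(list(extent_cm = NA_real_, estimable = FALSE,
                          threshold = threshold, curve = curve),
                     class = "ld_extent"))
  }
  k <- below[1]
  # linear interpolation between the last grid point above and the first at
  # or below the baseline
  x0 <- grid[k - 1]; x1 <- grid[k]
  y0 <- yhat[k - 1]; y1 <- yhat[k]
  extent <- x0 + (y0 - threshold) / (y0 - y1) * (x1 - x0)
  structure(list(extent_cm = extent, estimable = TRUE,
                 threshold = threshold, curve = curve),
            class = "ld_extent")
}

#' @export
print.ld_extent <- function(x, ...) {
  if (x$estimable) {
    cat(sprintf("<ld_extent> %.2f cM at critical R^2 = %.4g\n",
                x$extent_cm, x$threshold))
  } else {
    cat(sprintf("<ld_extent> not estimable (threshold %.4g)\n",
                x$threshold))
  }
  invisible(x)
}

#' Collection-level LD summary
#'
#' Convenience wrapper running [ld_pairs()], [critical_r2()] on the
#' unlinked evaluable pairs and [ld_extent()] on the syntenic ones, and
#' returning the collection-level quantities in one object.
#'
#' @inheritParams ld_pairs
#' @inheritParams ld_extent
#' @return A list of class `ld_result` with elements `pairs` (the
#'   [ld_pairs()] tibble), `extent` (the [ld_extent()] object) and
#'   `summary`, a one-row tibble: marker count, ordered-grid pair count,
#'   evaluated unordered pairs, median `R^2`, critical `R^2`, extent in cM
#'   and its estimability flag.
#' @export
ld_summary <- function(dataset, mapped_only = TRUE, min_complete = 20,
                       span = 0.5, degree = 2, grid_step = 0.1) {
  pairs <- ld_pairs(dataset, mapped_only = mapped_only,
                    min_complete = min_complete)
  unlinked <- pairs$r2[pairs$linkage == "unlinked" & pairs$evaluable]
  thr <- critical_r2(unlinked)
  syn <- pairs[pairs$linkage == "syntenic" & pairs$evaluable, ]
  ext <- ld_extent(syn$distance_cm, syn$r2, threshold = thr, span = span,
                   degree = degree, grid_step = grid_step)
  summary <- tibble(
    n_markers = attr(pairs, "n_markers"),
    n_grid = attr(pairs, "n_grid"),
    n_pairs_evaluated = sum(pairs$evaluable),
    median_r2 = median(pairs$r2[pairs$evaluable]),
    critical_r2 = thr,
    extent_cm = ext$extent_cm,
    extent_estimable = ext$estimable)
  structure(list(pairs = pairs, extent = ext, summary = summary),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat("<ld_result>\n")
  print(x$summary)
  invisible(x)
}

#' @rdname ld_summary
#' @param x An `ld_result`.
#' @param ... Unused.
#' @export
glance.ld_result <- function(x, ...) x$summary

#' @rdname ld_summary
#' @export
tidy.ld_result <- function(x, ...) as_tibble(x$pairs)
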