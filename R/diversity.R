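#' Band-presence frequency of a dominant marker
#'
#' For dominant 0/1 markers the allele frequency entering Nei gene
#' diversity is taken as the band-presence frequency among non-missing
#' calls (no Hardy-Weinberg back-correction of the absence class).
#'
#' @param calls Integer vector of 0/1/NA calls.
#' @param mask Optional logical vector selecting the group of accessions.
#' @return The frequency of 1-calls among non-missing calls, or `NA` (with
#'   a warning) when the group has no non-missing call.
#' @export
band_frequency <- function(calls, mask = NULL) {
  if (!is.null(mask)) calls <- calls[mask]
  n <- sum(!is.na(calls))
  if (n == 0L) {
    warn("all calls missing in group; band frequency undefined")
    return(NA_real_)
  }
  sum(calls == 1L, na.rm = TRUE) / n
}

#' Nei gene diversity of a biallelic locus
#'
#' `H = 1 - p^2 - (1 - p)^2 = 2 p (1 - p)`, the expected heterozygosity of
#' a biallelic locus with allele frequency `p`; at most 0.5, and exactly 0
#' for a monomorphic locus.
#'
#' @param p Numeric vector of allele (band) frequencies in `[0, 1]`.
#' @return Numeric vector of diversities.
#' @export
nei_h <- function(p) {
  if (any(!is.na(p) & (p < 0 | p > 1))) abort("`p` must lie in [0, 1]")
  2 * p * (1 - p)
}

#' Relative loss of gene diversity of a subspecies
#'
#' `delta_gd = 1 - H_subsp / H_wc`: the fraction of the whole-collection
#' gene diversity that would be lost if only the subspecies were kept.
#' Negative values mean the subspecies is more diverse than the whole
#' collection; a zero whole-collection diversity gives `NA`.
#'
#' @param h_subsp,h_wc Gene diversities of the subspecies and of the whole
#'   collection (vectors recycle).
#' @return Numeric vector of diversity-loss values.
#' @export
delta_gd <- function(h_subsp, h_wc) {
  if (any(!is.na(h_wc) & h_wc < 0) || any(!is.na(h_subsp) & h_subsp < 0)) {
    abort("gene diversities must be non-negative")
  }
  out <- 1 - h_subsp / h_wc
  out[!is.na(h_wc) & h_wc == 0] <- NA_real_
  out
}

group_masks <- function(dataset) {
  groups <- c(list(`whole collection` = rep(TRUE,
                                            length(dataset$accession_ids))),
              lapply(setNames(nm = unique(dataset$subspecies)),
                     function(s) dataset$subspecies == s))
  groups
}

#' Gene diversity table by chromosome, genome and in total
#'
#' Computes per-marker Nei diversity from band frequencies within the whole
#' collection and within each subspecies, then aggregates by unweighted
#' mean over the markers of each scope: each chromosome, genome A, genome B
#' (mapped markers whose chromosome label ends in that genome letter) and
#' the total over all markers including unmapped ones. Markers with no
#' non-missing call in a group are excluded from that group's means;
#' markers monomorphic in a group contribute `H = 0`. The relative
#' diversity loss of each subspecies is reported against the
#' whole-collection value of the same scope.
#'
#' @param dataset A [marker_dataset()].
#' @return A tibble with columns `scope_type` (`"chromosome"`, `"genome"`,
#'   `"total"`), `scope`, `group`, `n_markers`, `h`, `delta_gd` (`NA` for
#'   the whole-collection rows).
#' @export
diversity_table <- function(dataset) {
  stopifnot(inherits(dataset, "marker_dataset"))
  groups <- group_masks(dataset)
  geno <- dataset$genotypes
  per_marker <- purrr::imap(groups, function(mask, gname) {
    sub <- geno[mask, , drop = FALSE]
    n1 <- colSums(sub == 1L, na.rm = TRUE)
    nn <- colSums(!is.na(sub))
    p <- ifelse(nn > 0, n1 / nn, NA_real_)
    nei_h(p)
  })
  map <- dataset$map
  genome <- chromosome_genome(map$chromosome)
  scopes <- c(
    lapply(setNames(nm = sort(unique(map$chromosome[!is.na(map$chromosome)]))),
           function(ch) !is.na(map$chromosome) & map$chromosome == ch),
    list(`Genome A` = !is.na(genome) & genome == "A",
         `Genome B` = !is.na(genome) & genome == "B",
         Total = rep(TRUE, nrow(map))))
  scope_type <- c(rep("chromosome",
                      length(scopes) - 3L), "genome", "genome", "total")
  rows <- purrr::imap(scopes, function(in_scope, sname) {
    purrr::imap_dfr(per_marker, function(h, gname) {
      hh <- h[in_scope]
      hh <- hh[!is.na(hh)]
      tibble(scope = sname, group = gname,
             n_markers = length(hh),
             h = if (length(hh)) mean(hh) else NA_real_)
    })
  })
  out <- dplyr::bind_rows(rows, .id = "scope_id") |>
    dplyr::mutate(scope_type = rep(scope_type,
                                   each = length(groups))) |>
    dplyr::select("scope_type", "scope", "group", "n_markers", "h")
  wc <- out |>
    dplyr::filter(.data$group == "whole collection") |>
    dplyr::select("scope", h_wc = "h")
  out |>
    dplyr::left_join(wc, by = "scope") |>
    dplyr::mutate(delta_gd = dplyr::if_else(
      .data$group == "whole collection", NA_real_,
      delta_gd(.data$h, .data$h_wc))) |>
    dplyr::select(-"h_wc")
}

#' Scan for markers fixed within each subspecies
#'
#' A marker is monomorphic (fixed) in a subspecies when all its non-missing
#' calls in that subspecies are identical (and at least one call is
#' present); the definition is state-agnostic, so fixation at 0 and at 1
#' both count, and overlap counts between subspecies are on marker
#' identity, not on matching state.
#'
#' @param dataset A [marker_dataset()].
#' @return A list of class `monomorphic_report`: `markers` (tibble
#'   `subspecies`, `marker`, `fixed_state`), `counts` (per-subspecies
#'   totals), `overlaps` (pairwise and three-way intersection counts) and
#'   `union_n`, the number of markers monomorphic in at least one
#'   subspecies.
#' @export
monomorphic_scan <- function(dataset) {
  stopifnot(inherits(dataset, "marker_dataset"))
  subspecies <- unique(dataset$subspecies)
  geno <- dataset$genotypes
  markers <- purrr::map_dfr(subspecies, function(s) {
    sub <- geno[dataset$subspecies == s, , drop = FALSE]
    n1 <- colSums(sub == 1L, na.rm = TRUE)
    nn <- colSums(!is.na(sub))
    fixed <- nn > 0 & (n1 == 0L | n1 == nn)
    tibble(subspecies = s,
           marker = colnames(geno)[fixed],
           fixed_state = as.integer(n1[fixed] > 0L))
  })
  sets <- split(markers$marker, markers$subspecies)
  combos2 <- utils::combn(subspecies, 2, simplify = FALSE)
  overlaps <- purrr::map_dfr(combos2, function(pr) {
    tibble(groups = paste(pr, collapse = " & "),
           n = length(intersect(sets[[pr[1]]], sets[[pr[2]]])))
  })
  if (length(subspecies) >= 3) {
    all3 <- Reduce(intersect, sets[subspecies])
    overlaps <- dplyr::bind_rows(
      overlaps, tibble(groups = paste(subspecies, collapse = " & "),
                       n = length(all3)))
  }
  structure(
    list(markers = markers,
         counts = markers |> dplyr::count(.data$subspecies, name = "n"),
         overlaps = overlaps,
         union_n = length(unique(markers$marker))),
    class = "monomorphic_report")
}

#' @export
print.monomorphic_report <- function(x, ...) {
  cat("<monomorphic_report>\n")
  for (i in seq_len(nrow(x$counts))) {
    cat(sprintf("  %s: %d fixed markers\n",
                x$counts$subspecies[i], x$counts$n[i]))
  }
  cat(sprintf("  union: %d markers fixed in >=1 subspecies\n", x$union_n))
  print(x$overlaps)
  invisible(x)
}
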