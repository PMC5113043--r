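#' Assemble and validate a marker dataset
#'
#' A `marker_dataset` bundles everything the pipeline knows about a genotyped
#' collection: the accession-by-marker matrix of dominant band-presence calls
#' (1 = band present, 0 = absent, `NA` = missing), the genetic map, the
#' subspecies label of each accession, and the population-membership (Q)
#' matrix used to correct association tests for structure.
#'
#' @param genotypes Integer or numeric matrix, accessions in rows and markers
#'   in columns, entries in `{0, 1, NA}`. Row names are accession ids and
#'   column names marker ids (both required and unique).
#' @param map Tibble with columns `marker`, `chromosome`, `position_cm`.
#'   Unmapped markers carry `NA` chromosome and position. Markers absent from
#'   `map` are treated as unmapped.
#' @param subspecies Character vector of per-accession subspecies labels,
#'   in the order of `rownames(genotypes)` (or named by accession id).
#' @param q Numeric matrix of population-membership proportions, one row per
#'   accession (same order as `genotypes`), one column per population. Every
#'   row must sum to 1 within `1e-6`.
#'
#' @return An object of class `marker_dataset`: a list with elements
#'   `genotypes`, `map`, `subspecies`, `q`, `accession_ids`, `marker_ids`.
#' @export
marker_dataset <- function(genotypes, map = NULL, subspecies, q) {
  if (ncol(genotypes) == 0L) abort("no markers: `genotypes` has zero columns")
  if (is.null(rownames(genotypes)) || is.null(colnames(genotypes))) {
    abort("`genotypes` must have accession row names and marker column names")
  }
  accession_ids <- rownames(genotypes)
  marker_ids <- colnames(genotypes)
  if (anyDuplicated(accession_ids)) {
    abort(paste0("duplicate accession id: ",
                 accession_ids[duplicated(accession_ids)][1]))
  }
  if (anyDuplicated(marker_ids)) {
    abort(paste0("duplicate marker id: ",
                 marker_ids[duplicated(marker_ids)][1]))
  }
  storage.mode(genotypes) <- "integer"
  bad <- !(is.na(genotypes) | genotypes == 0L | genotypes == 1L)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "genotype call must be 0, 1 or NA; found %s at accession '%s', marker '%s'",
      genotypes[idx[1], idx[2]], accession_ids[idx[1]], marker_ids[idx[2]]))
  }
  if (!is.null(names(subspecies))) subspecies <- subspecies[accession_ids]
  subspecies <- as.character(subspecies)
  if (length(subspecies) != nrow(genotypes) || anyNA(subspecies)) {
    abort("`subspecies` must supply one label per accession")
  }
  if (is.null(map)) {
    map <- tibble(marker = marker_ids,
                  chromosome = NA_character_,
                  position_cm = NA_real_)
  }
  map <- as_tibble(map)
  stopifnot(all(c("marker", "chromosome", "position_cm") %in% names(map)))
  if (anyDuplicated(map$marker)) {
    abort(paste0("duplicate marker in map: ",
                 map$marker[duplicated(map$marker)][1]))
  }
  map <- dplyr::left_join(tibble(marker = marker_ids), map, by = "marker")
  map$chromosome <- as.character(map$chromosome)
  map$position_cm <- as.numeric(map$position_cm)
  mapped <- !is.na(map$chromosome) & !is.na(map$position_cm)
  if (any(mapped & (!is.finite(map$position_cm) | map$position_cm < 0))) {
    abort("mapped cM positions must be finite and non-negative")
  }
  # a position without a chromosome (or vice versa) counts as unmapped
  map$chromosome[!mapped] <- NA_character_
  map$position_cm[!mapped] <- NA_real_

  q <- as.matrix(q)
  if (nrow(q) != nrow(genotypes)) abort("Q must have one row per accession")
  if (is.null(rownames(q))) rownames(q) <- accession_ids
  q <- q[accession_ids, , drop = FALSE]
  if (is.null(colnames(q))) colnames(q) <- paste0("pop", seq_len(ncol(q)))
  rs <- rowSums(q)
  off <- abs(rs - 1) > 1e-6
  if (any(off)) {
    abort(sprintf("Q row for accession '%s' sums to %.8f, not 1",
                  accession_ids[which(off)[1]], rs[which(off)[1]]))
  }
  structure(
    list(genotypes = genotypes, map = map, subspecies = subspecies, q = q,
         accession_ids = accession_ids, marker_ids = marker_ids),
    class = "marker_dataset")
}

#' @export
print.marker_dataset <- function(x, ...) {
  n_mapped <- sum(!is.na(x$map$chromosome))
  cat(sprintf(
    "<marker_dataset> %d accessions x %d markers (%d mapped), %d populations\n",
    length(x$accession_ids), length(x$marker_ids), n_mapped, ncol(x$q)))
  tab <- table(x$subspecies)
  cat("subspecies:", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.marker_dataset <- function(x) dim(x$genotypes)

#' Genome (A/B) of a chromosome label
#'
#' The genome of a tetraploid wheat chromosome is the trailing letter of its
#' label (`"1A"` to `"7B"`, arm suffixes such as `"3BL"` are tolerated by
#' taking the first genome letter after the group digit). Labels without a
#' recognisable genome letter give `NA`.
#'
#' @param chromosome Character vector of chromosome labels.
#' @return Character vector of `"A"`, `"B"` or `NA`.
#' @export
chromosome_genome <- function(chromosome) {
  g <- sub("^[0-9]+([ABab]).*$", "\\1", chromosome)
  g <- toupper(g)
  g[!(g %in% c("A", "B"))] <- NA_character_
  g
}

read_tsv_quiet <- function(path, ...) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  na = c("NA", ""), ...)
}

#' Read a marker dataset from its tab-separated files
#'
#' Reads the four-file on-disk representation written by
#' [write_marker_dataset()]: a genotype table (`accession` column followed by
#' one 0/1/NA column per marker), a map table (`marker`, `chromosome`,
#' `position_cm`), a Q table (`accession`, `pop1`..`popK`) and a subspecies
#' table (`accession`, `subspecies`). Missing calls may be written as `NA`
#' or left empty. Malformed genotype tokens, duplicate ids and Q rows that do
#' not sum to 1 are hard errors naming the offending cell.
#'
#' @param genotype_path,map_path,q_path,subspecies_path File paths.
#' @return A validated [marker_dataset()].
#' @export
read_marker_dataset <- function(genotype_path, map_path, q_path,
                                subspecies_path) {
  geno_raw <- read_tsv_quiet(genotype_path,
                             col_types = readr::cols(.default = "c"))
  if (names(geno_raw)[1] != "accession") {
    abort("genotype file must start with an 'accession' column")
  }
  acc <- geno_raw$accession
  mk <- names(geno_raw)[-1]
  gm <- as.matrix(geno_raw[, -1, drop = FALSE])
  bad <- !is.na(gm) & !(gm %in% c("0", "1"))
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "invalid genotype token '%s' in %s at data row %d (accession '%s'), column '%s'",
      gm[idx[1], idx[2]], genotype_path, idx[1], acc[idx[1]], mk[idx[2]]))
  }
  geno <- matrix(as.integer(gm), nrow = nrow(gm),
                 dimnames = list(acc, mk))
  map <- read_tsv_quiet(map_path, col_types = readr::cols(
    marker = "c", chromosome = "c", position_cm = "d"))
  qtb <- read_tsv_quiet(q_path, col_types = readr::cols(
    accession = "c", .default = "d"))
  q <- as.matrix(qtb[, -1, drop = FALSE])
  rownames(q) <- qtb$accession
  sub <- read_tsv_quiet(subspecies_path, col_types = readr::cols(
    accession = "c", subspecies = "c"))
  subspecies <- setNames(sub$subspecies, sub$accession)
  missing_acc <- setdiff(acc, names(subspecies))
  if (length(missing_acc)) {
    abort(paste0("no subspecies label for accession '", missing_acc[1], "'"))
  }
  marker_dataset(geno, map = map, subspecies = subspecies, q = q)
}

#' Write a marker dataset as tab-separated text
#'
#' Writes `genotypes.tsv`, `map.tsv`, `q.tsv` and `subspecies.tsv` into
#' `out_dir` in a deterministic column order, with missing values as `NA`
#' and numeric columns at full precision, so that
#' `read_marker_dataset()` round-trips the object exactly.
#'
#' @param dataset A [marker_dataset()].
#' @param out_dir Output directory, created if absent.
#' @return Named character vector of the four file paths, invisibly.
#' @export
write_marker_dataset <- function(dataset, out_dir) {
  stopifnot(inherits(dataset, "marker_dataset"))
  if (length(dataset$marker_ids) == 0L) abort("no markers to write")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genotypes = file.path(out_dir, "genotypes.tsv"),
             map = file.path(out_dir, "map.tsv"),
             q = file.path(out_dir, "q.tsv"),
             subspecies = file.path(out_dir, "subspecies.tsv"))
  geno <- as_tibble(dataset$genotypes, rownames = "accession")
  readr::write_tsv(geno, paths["genotypes"], na = "NA", progress = FALSE)
  readr::write_tsv(dataset$map, paths["map"], na = "NA", progress = FALSE)
  qtb <- as_tibble(dataset$q, rownames = "accession")
  readr::write_tsv(qtb, paths["q"], na = "NA", progress = FALSE)
  readr::write_tsv(
    tibble(accession = dataset$accession_ids,
           subspecies = dataset$subspecies),
    paths["subspecies"], na = "NA", progress = FALSE)
  invisible(paths)
}

trial_columns <- c("environment", "row", "col", "entry", "is_check",
                   "trait", "value", "class")

#' Validate a plot-level field-trial table
#'
#' A trial table holds one record per plot and trait: `environment`, plot
#' `row` and `col` indices, `entry` id, `is_check` flag, `trait` name and
#' either a numeric `value` (quantitative traits) or a `class` label
#' (qualitative traits). A trait must be entirely numeric or entirely
#' categorical, plot coordinates must be unique within environment and
#' trait, and every check must appear in at least two plots per environment.
#'
#' @param trial A data frame with the columns above (`class` optional).
#' @return The validated trial as a tibble.
#' @export
validate_trial <- function(trial) {
  trial <- as_tibble(trial)
  if (!("class" %in% names(trial))) trial$class <- NA_character_
  stopifnot(all(trial_columns %in% names(trial)))
  trial <- trial[, trial_columns]
  mixed <- trial |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(num = any(!is.na(.data$value)),
                     cat = any(!is.na(.data$class))) |>
    dplyr::filter(.data$num & .data$cat)
  if (nrow(mixed)) {
    abort(paste0("trait '", mixed$trait[1],
                 "' mixes numeric values and class labels"))
  }
  dup <- trial |>
    dplyr::count(.data$environment, .data$trait, .data$row, .data$col) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(sprintf("duplicate plot (%s, row %d, col %d) for trait '%s'",
                  dup$environment[1], dup$row[1], dup$col[1], dup$trait[1]))
  }
  chk <- trial |>
    dplyr::filter(.data$is_check) |>
    dplyr::distinct(.data$environment, .data$trait, .data$entry,
                    .data$row, .data$col) |>
    dplyr::count(.data$environment, .data$trait, .data$entry) |>
    dplyr::filter(.data$n < 2)
  if (nrow(chk)) {
    abort(sprintf("check '%s' appears in fewer than 2 plots in environment %s",
                  chk$entry[1], chk$environment[1]))
  }
  trial
}

#' Read / write a trial table
#'
#' On disk the numeric `value` and categorical `class` columns are merged
#' into a single `value` column; [read_trial()] reassigns each trait to the
#' numeric or categorical slot (a trait is numeric when all its non-missing
#' tokens parse as numbers).
#'
#' @param trial A trial tibble (see [validate_trial()]).
#' @param path File path.
#' @return `write_trial()` the path invisibly; `read_trial()` a validated
#'   trial tibble.
#' @export
write_trial <- function(trial, path) {
  trial <- validate_trial(trial)
  out <- trial |>
    dplyr::mutate(value = dplyr::if_else(
      is.na(.data$value), .data$class,
      formatC(.data$value, digits = 10, format = "g"))) |>
    dplyr::select(-"class")
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_trial
#' @export
read_trial <- function(path) {
  raw <- read_tsv_quiet(path, col_types = readr::cols(
    environment = "c", row = "i", col = "i", entry = "c",
    is_check = "l", trait = "c", value = "c"))
  numeric_trait <- raw |>
    dplyr::group_by(.data$trait) |>
    dplyr::summarise(numeric = all(is.na(.data$value) |
                                     !is.na(suppressWarnings(as.numeric(.data$value)))))
  raw <- dplyr::left_join(raw, numeric_trait, by = "trait")
  trial <- raw |>
    dplyr::mutate(
      class = dplyr::if_else(.data$numeric, NA_character_, .data$value),
      value = dplyr::if_else(.data$numeric,
                             suppressWarnings(as.numeric(.data$value)),
                             NA_real_)) |>
    dplyr::select(dplyr::all_of(trial_columns))
  validate_trial(trial)
}

mta_report_columns <- c(
  "marker", "chromosome", "trait", "trait_kind", "subspecies", "environment",
  "statistic", "p_value", "r2", "scan_p", "scan_p_bonferroni",
  "cell_significant", "declared", "rule")

#' Write / read a marker-trait-association report
#'
#' One row per (marker, trait, subspecies, environment) evidence cell with
#' the confirmation statistic, raw p, marker R-squared, whole-collection
#' scan p (raw and Bonferroni-adjusted), and the declaration flag with the
#' rule that fired. Rows are sorted by trait, chromosome then marker so the
#' file is diff-stable.
#'
#' @param records Tibble with the columns listed in Details (the output of
#'   [declare_mtas()]).
#' @param path File path.
#' @return The path (write) or the records tibble (read).
#' @export
write_mta_report <- function(records, path) {
  records <- as_tibble(records)
  missing_cols <- setdiff(mta_report_columns, names(records))
  for (col in missing_cols) records[[col]] <- NA
  records <- records[, mta_report_columns] |>
    dplyr::arrange(.data$trait, .data$chromosome, .data$marker,
                   .data$subspecies, .data$environment)
  readr::write_tsv(records, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' @rdname write_mta_report
#' @export
read_mta_report <- function(path) {
  read_tsv_quiet(path, col_types = readr::cols(
    marker = "c", chromosome = "c", trait = "c", trait_kind = "c",
    subspecies = "c", environment = "c", statistic = "d", p_value = "d",
    r2 = "d", scan_p = "d", scan_p_bonferroni = "d",
    cell_significant = "l", declared = "l", rule = "c"))
}
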