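# small in-code fixtures shared across test files

toy_genotypes <- function(n_acc = 6, n_mk = 4, seed = 1) {
  withr::with_seed(seed, {
    g <- matrix(rbinom(n_acc * n_mk, 1L, 0.5), n_acc, n_mk,
                dimnames = list(sprintf("a%02d", seq_len(n_acc)),
                                sprintf("m%02d", seq_len(n_mk))))
    g
  })
}

toy_q <- function(n_acc, k = 2, seed = 2) {
  withr::with_seed(seed, {
    q <- matrix(rgamma(n_acc * k, 2), n_acc, k)
    q / rowSums(q)
  })
}

toy_dataset <- function(n_acc = 6, n_mk = 4, seed = 1,
                        subspecies = NULL, map = NULL) {
  g <- toy_genotypes(n_acc, n_mk, seed)
  if (is.null(subspecies)) {
    subspecies <- rep(c("durum", "turgidum"), length.out = n_acc)
  }
  if (is.null(map)) {
    map <- tibble::tibble(
      marker = colnames(g),
      chromosome = rep(c("1A", "1B"), length.out = n_mk),
      position_cm = seq(0, by = 10, length.out = n_mk))
  }
  marker_dataset(g, map = map, subspecies = subspecies,
                 q = toy_q(n_acc))
}

# dataset built from an explicit genotype matrix (rows = accessions)
dataset_from_matrix <- function(g, subspecies, map = NULL, q = NULL) {
  if (is.null(rownames(g))) {
    rownames(g) <- sprintf("a%02d", seq_len(nrow(g)))
  }
  if (is.null(colnames(g))) {
    colnames(g) <- sprintf("m%02d", seq_len(ncol(g)))
  }
  if (is.null(q)) q <- toy_q(nrow(g))
  marker_dataset(g, map = map, subspecies = subspecies, q = q)
}

small_sim_config <- function(seed, ...) {
  args <- list(n_durum = 30, n_turgidum = 12, n_dicoccon = 8,
               n_markers = 60, n_mapped = 40,
               pops_per_subspecies = c(durum = 2, turgidum = 1,
                                       dicoccon = 1),
               mono_fraction = c(durum = 0.05, turgidum = 0.1,
                                 dicoccon = 0.3),
               environments = c("C", "N"),
               n_rows = 6, n_cols = 10,
               missing_marker_frac = 0,
               seed = seed)
  extra <- list(...)
  args[names(extra)] <- extra
  do.call(sim_config, args)
}

# one-way balanced trial without field structure: n_acc accessions, r reps
balanced_oneway_trial <- function(n_acc, r, mu = 10, var_a = 1, var_e = 1,
                                  seed = 1) {
  withr::with_seed(seed, {
    g <- rnorm(n_acc, 0, sqrt(var_a))
    acc <- sprintf("acc%02d", seq_len(n_acc))
    tibble::tibble(
      environment = "E1",
      row = 1L, col = 1L,
      entry = rep(acc, each = r),
      is_check = FALSE,
      trait = "t",
      value = mu + rep(g, each = r) + rnorm(n_acc * r, 0, sqrt(var_e)),
      class = NA_character_)
  })
}
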