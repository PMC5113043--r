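test_that("the generator is deterministic and honours the configured structure", {
  cfg <- small_sim_config(seed = 221)
  c1 <- generate_collection(cfg)
  c2 <- generate_collection(cfg)
  expect_identical(c1$dataset$genotypes, c2$dataset$genotypes)
  expect_identical(c1$dataset$q, c2$dataset$q)
  expect_identical(c1$truth$monomorphic, c2$truth$monomorphic)

  ds <- c1$dataset
  expect_equal(as.integer(table(ds$subspecies)[c("durum", "turgidum",
                                                 "dicoccon")]),
               c(30L, 12L, 8L))
  expect_equal(length(ds$marker_ids), 60L)
  expect_equal(sum(!is.na(ds$map$chromosome)), 40L)
  expect_equal(ncol(ds$q), 4L)
  expect_true(all(abs(rowSums(ds$q) - 1) < 1e-6))
  # mapped positions live on the 14 wheat chromosomes
  expect_true(all(stats::na.omit(ds$map$chromosome) %in%
                    paste0(rep(1:7, each = 2), c("A", "B"))))
})

test_that("planted monomorphic fractions are realized within binomial noise", {
  cfg <- sim_config(n_durum = 40, n_turgidum = 15, n_dicoccon = 10,
                    n_markers = 749,
                    mono_fraction = c(durum = 0.02, turgidum = 0.1,
                                      dicoccon = 0.35),
                    missing_marker_frac = 0, seed = 231)
  coll <- generate_collection(cfg)
  truth <- coll$truth$monomorphic
  frac_dic <- mean(truth$monomorphic[truth$subspecies == "dicoccon"])
  expect_gte(frac_dic, 0.30)   # planted 0.35 plus chance fixation
  planted_dic <- sum(truth$planted[truth$subspecies == "dicoccon"])
  expect_equal(planted_dic, round(0.35 * 749))
})

test_that("the no-linkage limit removes the within-chromosome excess correlation", {
  r2_by_class <- function(tau) {
    cfg <- small_sim_config(seed = 241, tau_cm = tau, n_markers = 120,
                            n_mapped = 120, n_durum = 60)
    coll <- generate_collection(cfg)
    pairs <- ld_pairs(coll$dataset, min_complete = 10)
    list(syn = pairs$r2[pairs$linkage == "syntenic" & pairs$evaluable],
         unl = pairs$r2[pairs$linkage == "unlinked" & pairs$evaluable])
  }
  free <- r2_by_class(0)
  expect_gt(stats::t.test(free$syn, free$unl)$p.value, 0.01)
  linked <- r2_by_class(8)
  expect_lt(stats::t.test(linked$syn, linked$unl)$p.value, 0.01)
  expect_gt(mean(linked$syn), mean(linked$unl))
})

test_that("trial layouts account for every entry and check without collisions", {
  cfg <- sim_config(missing_marker_frac = 0, seed = 251)
  coll <- generate_collection(cfg)
  tr <- generate_trial(coll$dataset, cfg)
  one <- tr$trial[tr$trial$trait == "qt1" & tr$trial$environment == "C", ]
  expect_equal(nrow(one), 14 * 16)  # entries + check plots fill the grid
  expect_equal(sum(!one$is_check), 183L)
  expect_equal(anyDuplicated(one[, c("row", "col")]), 0L)
  expect_equal(sort(unique(one$entry[one$is_check])),
               sprintf("check%d", 1:4))
  counts <- table(one$entry[one$is_check])
  expect_true(all(counts >= 2))
  # every accession appears exactly once per environment
  expect_equal(anyDuplicated(one$entry[!one$is_check]), 0L)

  too_small <- small_sim_config(seed = 252, n_rows = 4, n_cols = 8)
  coll2 <- generate_collection(too_small)
  expect_error(generate_trial(coll2$dataset, too_small), "layout too small")
})

test_that("the noise-free limit returns exactly mean plus genetic value", {
  cfg <- small_sim_config(seed = 261, var_row = 0, var_col = 0,
                          var_error = 0, subsp_env_sd = 0)
  coll <- generate_collection(cfg)
  tr <- generate_trial(coll$dataset, cfg)
  truth <- tr$truth$genetic_values
  one <- tr$trial[tr$trial$trait == "qt1" & tr$trial$environment == "N" &
                    !tr$trial$is_check, ]
  g <- setNames(truth$genetic_value[truth$trait == "qt1"],
                truth$accession[truth$trait == "qt1"])
  expect_equal(one$value, unname(cfg$env_mean[["N"]] + g[one$entry]),
               tolerance = 1e-12)
})

test_that("planted QTL effects land near their target R2 across seeds", {
  qtl <- tibble::tibble(marker = "mk0005", trait = "qt1",
                        subspecies = "durum", target_r2 = 0.3)
  inside <- vapply(1:20, function(s) {
    cfg <- sim_config(n_durum = 132, n_turgidum = 10, n_dicoccon = 8,
                      n_markers = 30, n_mapped = 0, environments = "C",
                      mono_fraction = c(durum = 0, turgidum = 0,
                                        dicoccon = 0),
                      missing_marker_frac = 0, qtl = qtl, seed = 300 + s)
    coll <- generate_collection(cfg)
    # plant on the most informative marker of this seed's collection
    freq <- colMeans(coll$dataset$genotypes[
      coll$dataset$subspecies == "durum", ], na.rm = TRUE)
    cfg$qtl$marker <- names(which.min(abs(freq - 0.5)))
    tr <- generate_trial(coll$dataset, cfg)
    r2 <- tr$truth$qtl_realized$realized_r2[1]
    r2 >= 0.15 && r2 <= 0.45
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("infeasible monomorphic/QTL combinations error out", {
  qtl <- tibble::tibble(marker = "mk0001", trait = "qt1",
                        subspecies = "dicoccon", target_r2 = 0.3)
  cfg <- small_sim_config(seed = 271, qtl = qtl, n_markers = 10,
                          n_mapped = 0,
                          mono_fraction = c(durum = 0, turgidum = 0,
                                            dicoccon = 0.99))
  # 10 markers, 0.99 rounds to fixing 10 of the 9 eligible
  expect_error(generate_collection(cfg), "infeasible config")
  expect_error(sim_config(seed = 1, mono_fraction = c(durum = 1,
                                                      turgidum = 0,
                                                      dicoccon = 0)),
               "mono_fraction")
  expect_error(sim_config(), "`seed` is mandatory")
  expect_error(sim_config(seed = 1, n_durum = 0), "positive")
  expect_error(sim_config(seed = 1,
                          qtl = tibble::tibble(marker = "m", trait = "t",
                                               subspecies = "durum",
                                               target_r2 = 1.2)),
               "target_r2")
})

test_that("qualitative traits are generated as thresholded latent classes", {
  qtl <- tibble::tibble(marker = "mk0002", trait = "ql1",
                        subspecies = "durum", target_r2 = NA_real_,
                        latent_beta = 3)
  cfg <- small_sim_config(seed = 281, qtl = qtl,
                          qualitative_traits = "ql1", n_classes = 3)
  coll <- generate_collection(cfg)
  tr <- generate_trial(coll$dataset, cfg)
  qual <- tr$trial[tr$trial$trait == "ql1", ]
  expect_equal(nrow(qual), 50L)   # one record per accession
  expect_true(all(!is.na(qual$class)))
  expect_true(all(is.na(qual$value)))
  expect_lte(dplyr::n_distinct(qual$class), 3L)
  # the planted marker separates the classes
  cls <- setNames(qual$class, qual$entry)
  calls <- coll$dataset$genotypes[names(cls), "mk0002"]
  res <- chisq_confirm(cls, calls)
  expect_true(res$testable)
  expect_lt(res$p_value, 0.01)
})
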