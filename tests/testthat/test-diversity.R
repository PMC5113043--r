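test_that("band frequency counts 1-calls among non-missing calls", {
  expect_equal(band_frequency(c(1L, 1L, 1L, 1L)), 1)
  expect_equal(band_frequency(c(1L, 0L, NA, 0L)), 1 / 3)
  expect_warning(p <- band_frequency(c(NA_integer_, NA_integer_)),
                 "all calls missing")
  expect_true(is.na(p))
  # brute-force agreement on random vectors with masks
  withr::with_seed(11, {
    for (i in 1:20) {
      x <- sample(c(0L, 1L, NA), 30, replace = TRUE)
      mask <- sample(c(TRUE, FALSE), 30, replace = TRUE)
      if (sum(!is.na(x[mask])) == 0) next
      expect_equal(band_frequency(x, mask),
                   sum(x[mask] %in% 1L) / sum(!is.na(x[mask])))
    }
  })
})

test_that("Nei H follows 2p(1-p) with its extremes", {
  expect_equal(nei_h(0), 0)
  expect_equal(nei_h(1), 0)
  expect_equal(nei_h(0.5), 0.5)
  expect_equal(nei_h(0.2), 0.32)
  expect_error(nei_h(1.2), "\\[0, 1\\]")
  p <- seq(0, 1, by = 0.01)
  expect_true(all(nei_h(p) >= 0 & nei_h(p) <= 0.5))
})

test_that("diversity loss reproduces the published overall table cells", {
  # overall diversity table of the landrace panel: full-precision values
  # behind the printed two-decimal cells
  expect_equal(delta_gd(0.16, 0.36), 1 - 0.16 / 0.36)
  expect_equal(round(delta_gd(0.16, 0.36), 2), 0.56)
  expect_equal(round(delta_gd(0.28, 0.36), 2), 0.22)
  expect_equal(delta_gd(0.4, 0.4), 0)
  expect_true(is.na(delta_gd(0.1, 0)))
  expect_lt(delta_gd(0.45, 0.4), 0)  # subspecies can exceed the collection
  expect_error(delta_gd(-0.1, 0.3), "non-negative")
})

test_that("scope aggregation is the unweighted mean of per-marker H", {
  g <- rbind(a1 = c(1L, 1L, 1L, 0L), a2 = c(1L, 0L, 0L, 1L),
             a3 = c(0L, 0L, 1L, 1L), a4 = c(1L, 0L, 0L, 0L),
             a5 = c(1L, 1L, 0L, NA))
  map <- tibble::tibble(marker = c("m01", "m02", "m03", "m04"),
                        chromosome = c("1A", "1A", "3B", NA),
                        position_cm = c(0, 5, 2, NA))
  ds <- dataset_from_matrix(g, subspecies = rep(c("durum", "turgidum"),
                                                c(3, 2)),
                            map = map, q = toy_q(5))
  dt <- diversity_table(ds)
  wc_1a <- dt$h[dt$scope == "1A" & dt$group == "whole collection"]
  p1 <- mean(g[, 1]); p2 <- mean(g[, 2])
  expect_equal(wc_1a, mean(c(2 * p1 * (1 - p1), 2 * p2 * (1 - p2))))
  # unmapped marker contributes only to the Total scope
  tot <- dt$n_markers[dt$scope == "Total" & dt$group == "whole collection"]
  expect_equal(tot, 4L)
  gen_a <- dt$n_markers[dt$scope == "Genome A" &
                          dt$group == "whole collection"]
  expect_equal(gen_a, 2L)
  # explicit two-marker mean example
  h <- c(0.2, 0.4)
  expect_equal(mean(h), 0.3)
})

test_that("diversity table equals a brute-force recomputation on random data", {
  withr::with_seed(21, {
    for (rep in 1:5) {
      n <- sample(8:15, 1); m <- sample(6:12, 1)
      g <- matrix(sample(c(0L, 1L, NA), n * m, replace = TRUE,
                         prob = c(0.45, 0.45, 0.1)), n, m)
      rownames(g) <- sprintf("a%02d", 1:n)
      colnames(g) <- sprintf("m%02d", 1:m)
      subsp <- sample(c("durum", "dicoccon"), n, replace = TRUE)
      if (length(unique(subsp)) < 2) subsp[1:2] <- c("durum", "dicoccon")
      map <- tibble::tibble(marker = colnames(g),
                            chromosome = sample(c("2A", "5B", NA), m,
                                                replace = TRUE),
                            position_cm = runif(m, 0, 100))
      map$position_cm[is.na(map$chromosome)] <- NA
      ds <- dataset_from_matrix(g, subspecies = subsp, map = map,
                                q = toy_q(n, seed = rep))
      dt <- diversity_table(ds)
      # oracle: loop over markers, groups and scopes directly
      for (grp in c("whole collection", unique(subsp))) {
        mask <- if (grp == "whole collection") rep(TRUE, n)
                else subsp == grp
        hs <- vapply(seq_len(m), function(j) {
          x <- g[mask, j]
          nn <- sum(!is.na(x))
          if (nn == 0) return(NA_real_)
          p <- sum(x == 1L, na.rm = TRUE) / nn
          2 * p * (1 - p)
        }, numeric(1))
        expected_total <- mean(hs, na.rm = TRUE)
        got <- dt$h[dt$scope == "Total" & dt$group == grp]
        expect_equal(got, expected_total, tolerance = 1e-12)
        for (ch in unique(stats::na.omit(map$chromosome))) {
          sel <- !is.na(map$chromosome) & map$chromosome == ch
          exp_ch <- mean(hs[sel], na.rm = TRUE)
          got_ch <- dt$h[dt$scope == ch & dt$group == grp]
          expect_equal(got_ch, exp_ch, tolerance = 1e-12)
        }
      }
      expect_true(all(dt$h >= 0 & dt$h <= 0.5, na.rm = TRUE))
    }
  })
})

test_that("monomorphic scan is state-agnostic and matches the definition", {
  g <- rbind(a1 = c(1L, 1L, 1L), a2 = c(1L, 0L, 1L), a3 = c(1L, 1L, 0L),
             b1 = c(1L, 0L, 0L), b2 = c(0L, 1L, 0L))
  ds <- dataset_from_matrix(g, subspecies = c("dicoccon", "dicoccon",
                                              "dicoccon", "turgidum",
                                              "turgidum"),
                            q = toy_q(5))
  rep <- monomorphic_scan(ds)
  dic <- rep$markers[rep$markers$subspecies == "dicoccon", ]
  expect_identical(dic$marker, "m01")
  expect_identical(dic$fixed_state, 1L)
  # m03 fixed at 0 in turgidum only
  tur <- rep$markers[rep$markers$subspecies == "turgidum", ]
  expect_identical(tur$marker, "m03")
  expect_identical(tur$fixed_state, 0L)

  # a marker fixed at 1 in one group and 0 in another counts in both sets
  # and in their intersection (state-agnostic overlap)
  g2 <- rbind(a1 = c(1L, 0L), a2 = c(1L, 1L),
              b1 = c(0L, 0L), b2 = c(0L, 1L))
  ds2 <- dataset_from_matrix(g2, subspecies = c("turgidum", "turgidum",
                                                "dicoccon", "dicoccon"),
                             q = toy_q(4))
  rep2 <- monomorphic_scan(ds2)
  expect_setequal(
    rep2$markers$subspecies[rep2$markers$marker == "m01"],
    c("turgidum", "dicoccon"))
  expect_equal(rep2$overlaps$n[grepl("&", rep2$overlaps$groups)][1], 1L)
  # overlap counts can never exceed the individual counts
  expect_true(all(rep2$overlaps$n <= max(rep2$counts$n)))
})

test_that("planted monomorphic sets are recovered exactly at zero missingness", {
  cfg <- small_sim_config(seed = 99)
  coll <- generate_collection(cfg)
  scan <- monomorphic_scan(coll$dataset)
  truth <- coll$truth$monomorphic
  for (s in unique(truth$subspecies)) {
    true_set <- truth$marker[truth$subspecies == s & truth$monomorphic]
    got_set <- scan$markers$marker[scan$markers$subspecies == s]
    expect_setequal(got_set, true_set)
    # fixed states agree too
    merged <- merge(truth[truth$subspecies == s & truth$monomorphic, ],
                    scan$markers[scan$markers$subspecies == s, ],
                    by = c("subspecies", "marker"))
    expect_equal(merged$fixed_state.x, merged$fixed_state.y)
  }
})
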