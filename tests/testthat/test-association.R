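test_that("the missing-data filter uses a strict 5% cutoff", {
  g <- matrix(1L, nrow = 20, ncol = 3,
              dimnames = list(sprintf("a%02d", 1:20), c("m1", "m2", "m3")))
  g[1:10, 1] <- 0L; g[1:10, 2] <- 0L; g[1:10, 3] <- 0L
  g[1, 2] <- NA      # exactly 5% missing -> dropped
  ds <- dataset_from_matrix(g, subspecies = rep("durum", 20),
                            q = toy_q(20))
  expect_setequal(association_filter(ds), c("m1", "m3"))
  # 9 of 183 missing (4.9%) stays below the cutoff
  expect_true(9 / 183 < 0.05)
  # planted missingness: retained count equals the ledger prediction
  cfg <- small_sim_config(seed = 131, missing_marker_frac = 0.3,
                          missing_rate_range = c(0.1, 0.2))
  coll <- generate_collection(cfg)
  n_acc <- length(coll$dataset$accession_ids)
  predicted <- sum(coll$truth$missingness$missing_fraction < 0.05)
  expect_equal(length(association_filter(coll$dataset)), predicted)
})

test_that("the structure-corrected scan matches a dense regression oracle", {
  y <- c(1, 2, 3, 4, 2.5)
  x <- c(0L, 0L, 1L, 1L, 0L)
  q <- rbind(c(.8, .2), c(.6, .4), c(.2, .8), c(.3, .7), c(.5, .5))
  g <- cbind(mk = x)
  rownames(g) <- sprintf("a%d", 1:5)
  ds <- dataset_from_matrix(g, subspecies = rep("durum", 5), q = q)
  res <- glm_q_scan(setNames(y, rownames(g)), ds, markers = "mk")
  # oracle: explicit extra-sum-of-squares F from lm fits
  full <- lm(y ~ q[, 1] + x)
  red <- lm(y ~ q[, 1])
  sse_f <- sum(residuals(full)^2); sse_r <- sum(residuals(red)^2)
  df2 <- 5 - 2 - 1
  f_oracle <- (sse_r - sse_f) / (sse_f / df2)
  expect_equal(res$statistic, f_oracle, tolerance = 1e-10)
  expect_equal(res$p_value, pf(f_oracle, 1, df2, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_equal(res$r2, (sse_r - sse_f) / sse_r, tolerance = 1e-10)

  # a marker whose groups coincide exactly with the Q contrast is flagged
  # as collinear rather than tested
  q2 <- rbind(c(.8, .2), c(.8, .2), c(.2, .8), c(.2, .8))
  g2 <- cbind(mk = c(0L, 0L, 1L, 1L))
  rownames(g2) <- sprintf("b%d", 1:4)
  ds2 <- dataset_from_matrix(g2, subspecies = rep("durum", 4), q = q2)
  res2 <- glm_q_scan(setNames(1:4, rownames(g2)), ds2, markers = "mk")
  expect_identical(res2$note, "collinear with Q")
  expect_true(is.na(res2$p_value))
})

test_that("the scan recognises perfect association, collinearity and monomorphism", {
  withr::with_seed(141, {
    n <- 40
    x <- rbinom(n, 1L, 0.5)
    g <- cbind(perfect = x, mono = rep(1L, n), coll = x)
    rownames(g) <- sprintf("a%02d", 1:n)
    # Q proportional to the 'coll' marker makes it collinear
    q <- cbind(0.2 + 0.6 * x, 0.8 - 0.6 * x)
    ds <- dataset_from_matrix(g, subspecies = rep("durum", n), q = q)
    res <- glm_q_scan(setNames(as.numeric(x), rownames(g)), ds,
                      markers = colnames(g))
    expect_identical(res$note[res$marker == "mono"],
                     "monomorphic in sample")
    expect_identical(res$note[res$marker == "coll"], "collinear with Q")
    # perfect marker is collinear with this Q too; use a constant-ish Q
    q2 <- matrix(0.5, n, 2)
    ds2 <- dataset_from_matrix(g[, "perfect", drop = FALSE],
                               subspecies = rep("durum", n), q = q2)
    res2 <- glm_q_scan(setNames(as.numeric(x), rownames(g)), ds2,
                       markers = "perfect")
    expect_gt(res2$r2, 0.999)
    expect_lt(res2$p_value, 1e-20)
  })
})

test_that("scan p-values are null-uniform with Q and inflated without it", {
  withr::with_seed(151, {
    n <- 120
    subsp <- rep(c("durum", "turgidum"), c(80, 40))
    # structured marker frequencies and a structured trait
    p_by <- c(durum = 0.8, turgidum = 0.2)
    shift <- c(durum = 0, turgidum = 1.5)
    p_adj <- numeric(400); p_raw <- numeric(400)
    for (i in 1:400) {
      x <- rbinom(n, 1L, p_by[subsp])
      y <- shift[subsp] + rnorm(n)
      if (var(x) == 0) x[1] <- 1L - x[1]
      g <- cbind(mk = x); rownames(g) <- sprintf("a%03d", 1:n)
      q_true <- cbind(as.numeric(subsp == "durum") * 0.9 + 0.05,
                      as.numeric(subsp == "turgidum") * 0.9 + 0.05)
      ds_q <- dataset_from_matrix(g, subspecies = subsp, q = q_true)
      ds_0 <- dataset_from_matrix(g, subspecies = subsp,
                                  q = matrix(0.5, n, 2))
      yy <- setNames(y, rownames(g))
      p_adj[i] <- glm_q_scan(yy, ds_q, markers = "mk")$p_value
      p_raw[i] <- glm_q_scan(yy, ds_0, markers = "mk")$p_value
    }
  })
  expect_gt(stats::ks.test(p_adj, "punif")$p.value, 0.01)
  expect_gt(mean(p_raw < 0.05), 0.3)  # strong structure-induced inflation
})

test_that("Bonferroni adjustment multiplies and clips", {
  expect_equal(bonferroni_adjust(0.0001, 532), 0.0532)
  expect_equal(bonferroni_adjust(0.5, 532), 1)
  expect_equal(bonferroni_adjust(c(0.2, 0.9), 1), c(0.2, 0.9))
  expect_error(bonferroni_adjust(0.1, 0), "at least 1")
})

test_that("chi-square confirmation matches the closed form and handles degeneracy", {
  cls <- rep(c("A", "B"), each = 10)
  calls <- rep(c(1L, 0L), each = 10)
  res <- chisq_confirm(cls, calls)   # table [[10,0],[0,10]]
  expect_equal(res$statistic, 20)
  expect_equal(res$df, 1L)
  expect_lt(res$p_value, 0.01)

  # proportional rows: no association
  cls2 <- rep(c("A", "B"), times = c(12, 8))
  calls2 <- rep(c(1L, 0L, 1L, 0L), times = c(6, 6, 4, 4))
  res2 <- chisq_confirm(cls2, calls2)
  expect_equal(res2$statistic, 0, tolerance = 1e-12)
  expect_equal(res2$p_value, 1, tolerance = 1e-12)

  # a statistic of 104.81 passes the P<0.01 confirmation at df <= 3
  expect_true(all(pchisq(104.81, df = 1:3, lower.tail = FALSE) < 0.01))

  # degenerate tables are not testable
  expect_false(chisq_confirm(rep("A", 10), rbinom(10, 1, 0.5))$testable)
  expect_false(chisq_confirm(cls, rep(1L, 20))$testable)
})

test_that("regression confirmation matches a normal-equations oracle", {
  withr::with_seed(161, {
    y <- rnorm(10); x <- rbinom(10, 1L, 0.5)
    if (var(x) == 0) x[1] <- 1L - x[1]
  })
  res <- regression_confirm(y, x)
  fit <- summary(lm(y ~ x))
  expect_equal(res$slope, unname(coef(fit)[2, 1]), tolerance = 1e-10)
  expect_equal(res$r2, fit$r.squared, tolerance = 1e-10)
  expect_equal(res$p_value, unname(coef(fit)[2, 4]), tolerance = 1e-10)

  # BLUPs exactly marker + constant: R2 = 1
  perfect <- regression_confirm(2 + 3 * x, x)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$p_value, 0)

  # monomorphic cell feeds the fixed-marker bookkeeping
  mono <- regression_confirm(y, rep(1L, 10))
  expect_false(mono$testable)
  expect_identical(mono$note, "monomorphic in cell")
  expect_false(regression_confirm(y[1:3], x[1:3])$testable)
})

test_that("declaration requires the scan threshold plus the spanning rule", {
  scan <- tibble::tibble(
    marker = c("mkA", "mkA", "mkB", "mkC", "mkD"),
    trait = c("DH", "DH", "DH", "DH", "GH"),
    p_value = c(1e-5, 0.2, 1e-6, 0.2, 1e-4),
    cell = c("C", "N", "C", "C", "class1"))
  confirm <- tibble::tibble(
    marker = c(rep("mkA", 4), "mkB", "mkC", "mkC", "mkD", "mkD"),
    trait = c(rep("DH", 7), "GH", "GH"),
    subspecies = c("durum", "durum", "durum", "durum", "durum",
                   "durum", "turgidum", "durum", "turgidum"),
    environment = c("C", "N", "S", "S08", "C", "C", "C", "C", "C"),
    statistic = 1, p_value = c(0.01, 0.02, 0.03, 0.04, 0.2,
                               0.01, 0.04, 0.005, 0.5),
    r2 = 0.1, testable = TRUE)
  kind <- c(DH = "quantitative", GH = "qualitative")
  rec <- declare_mtas(scan, confirm, kind)
  by_marker <- rec |> dplyr::distinct(marker, declared, rule)
  # significant in four environments within one subspecies: declared
  expect_true(by_marker$declared[by_marker$marker == "mkA"])
  # scan hit but a single significant cell: not declared
  expect_false(by_marker$declared[by_marker$marker == "mkB"])
  # significant in two subspecies within one environment: needs scan pass
  expect_false(by_marker$declared[by_marker$marker == "mkC"])
  # qualitative: scan hit plus one chi-square confirmation suffices
  expect_true(by_marker$declared[by_marker$marker == "mkD"])

  # boundary p exactly at the threshold never counts
  confirm_edge <- confirm
  confirm_edge$p_value[confirm_edge$marker == "mkA"] <- c(0.05, 0.05,
                                                          0.05, 0.01)
  rec_edge <- declare_mtas(scan, confirm_edge, kind)
  expect_false(any(rec_edge$declared[rec_edge$marker == "mkA"]))
  scan_edge <- scan
  scan_edge$p_value[scan_edge$marker == "mkD"] <- 0.0005
  rec_edge2 <- declare_mtas(scan_edge, confirm, kind)
  expect_false(any(rec_edge2$declared[rec_edge2$marker == "mkD"]))

  # a marker significant once in each of two subspecies, same environment
  scan3 <- tibble::tibble(marker = "mkE", trait = "PC", p_value = 1e-5,
                          cell = "N")
  confirm3 <- tibble::tibble(
    marker = "mkE", trait = "PC",
    subspecies = c("durum", "turgidum"), environment = "N",
    statistic = 1, p_value = c(0.03, 0.04), r2 = 0.1, testable = TRUE)
  rec3 <- declare_mtas(scan3, confirm3, c(PC = "quantitative"))
  expect_true(all(rec3$declared))
  expect_match(rec3$rule[1], ">1 subspecies")
})

test_that("fixed-marker concordance compares the fixed state with the phenotype", {
  # durum segregates; dicoccon fixed
  subsp <- rep(c("durum", "dicoccon"), c(10, 4))
  x <- c(rep(c(1L, 0L), each = 5), rep(1L, 4))
  g <- cbind(mk = x); rownames(g) <- sprintf("a%02d", 1:14)
  ds <- dataset_from_matrix(g, subspecies = subsp, q = toy_q(14))
  # allele 1 goes with higher values; dicoccon holds the highest means
  vals <- setNames(c(rep(10, 5), rep(5, 5), rep(12, 4)), rownames(g))
  res <- monomorphic_concordance("mk", ds, values = vals)
  expect_identical(res$subspecies, "dicoccon")
  expect_identical(res$fixed_state, 1L)
  expect_true(res$concordant)
  # same phenotype but fixed for the absent state: discordant
  g0 <- g; g0[11:14, 1] <- 0L
  ds0 <- dataset_from_matrix(g0, subspecies = subsp, q = toy_q(14))
  res0 <- monomorphic_concordance("mk", ds0, values = vals)
  expect_false(res0$concordant)

  # qualitative: majority-class matching
  cls <- setNames(c(rep("red", 5), rep("white", 5), rep("red", 4)),
                  rownames(g))
  resq <- monomorphic_concordance("mk", ds, classes = cls)
  expect_true(resq$concordant)
  resq0 <- monomorphic_concordance("mk", ds0, classes = cls)
  expect_false(resq0$concordant)

  # marker not fixed anywhere: empty result
  gseg <- cbind(mk = rep(c(0L, 1L), 7)); rownames(gseg) <- rownames(g)
  dseg <- dataset_from_matrix(gseg, subspecies = subsp, q = toy_q(14))
  expect_equal(nrow(monomorphic_concordance("mk", dseg, values = vals)), 0)
})

test_that("planted concordance direction is recovered on simulated collections", {
  hits <- 0L; total <- 0L
  for (s in 1:10) {
    cfg <- small_sim_config(seed = 170 + s)
    coll <- generate_collection(cfg)
    ds <- coll$dataset
    # pick a marker segregating in durum and fixed in dicoccon
    truth <- coll$truth$monomorphic
    fixed_dic <- truth$marker[truth$subspecies == "dicoccon" &
                                truth$monomorphic]
    seg_dur <- truth$marker[truth$subspecies == "durum" &
                              !truth$monomorphic]
    cand <- intersect(fixed_dic, seg_dur)
    if (!length(cand)) next
    mk <- cand[1]
    st <- truth$fixed_state[truth$subspecies == "dicoccon" &
                              truth$marker == mk]
    # build a phenotype where allele 1 adds a big positive effect, so the
    # fixed subspecies' mean is pushed in the direction of its state
    withr::with_seed(5000 + s, {
      xs <- ds$genotypes[, mk]
      xs[is.na(xs)] <- mean(xs, na.rm = TRUE)
      vals <- setNames(10 + 5 * xs + rnorm(nrow(ds$genotypes), 0, 0.5),
                       ds$accession_ids)
    })
    res <- monomorphic_concordance(mk, ds, values = vals)
    row <- res[res$subspecies == "dicoccon", ]
    if (!nrow(row) || !row$evaluable) next
    total <- total + 1L
    hits <- hits + as.integer(row$concordant)
  }
  expect_gt(total, 4)
  expect_gte(hits / total, 0.9)
})
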