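test_that("per-locus LSBL arithmetic and branch-length additivity", {
  expect_equal(lsbl_locus(0, 0, 0), 0)
  expect_equal(lsbl_locus(0.2, 0.1, 0.1), 0.1)
  expect_true(is.na(lsbl_locus(NA, 0.1, 0.1)))
  # LSBL_x + LSBL_y = FST(x, y) when x and y swap roles
  set.seed(3)
  for (rep in 1:100) {
    f_xy <- runif(1, -0.05, 0.9)
    f_xz <- runif(1, -0.05, 0.9)
    f_yz <- runif(1, -0.05, 0.9)
    lsbl_x <- lsbl_locus(f_xy, f_xz, f_yz)   # refs y, z
    lsbl_y <- lsbl_locus(f_xy, f_yz, f_xz)   # refs x, z
    expect_equal(lsbl_x + lsbl_y, f_xy, tolerance = 1e-12)
  }
})

test_that("downsampling is reproducible, uniform, and leaves others untouched", {
  scen <- simulate_island_genotypes(sim_config(n_pops = 2,
                                               n_per_pop = c(30, 10),
                                               n_loci = 40,
                                               chrom_length_bp = 1e6,
                                               seed = 8))
  gm <- scen$gm
  d1 <- downsample_population(gm, "pop1", 16, seed = 101)
  d2 <- downsample_population(gm, "pop1", 16, seed = 101)
  expect_identical(rownames(d1$dosage), rownames(d2$dosage))
  expect_equal(length(panel_individuals(d1$panel, "pop1")), 16)
  expect_identical(panel_individuals(d1$panel, "pop2"),
                   panel_individuals(gm$panel, "pop2"))
  d3 <- downsample_population(gm, "pop1", 16, seed = 102)
  expect_false(identical(rownames(d1$dosage), rownames(d3$dosage)))
  expect_error(downsample_population(gm, "pop2", 11, seed = 1), "only 10")
  # n = population size is the identity up to order
  dall <- downsample_population(gm, "pop2", 10, seed = 5)
  expect_setequal(panel_individuals(dall$panel, "pop2"),
                  panel_individuals(gm$panel, "pop2"))
  # frequency preserved in expectation over seeds
  j <- 1
  full_p <- mean(gm$dosage[panel_individuals(gm$panel, "pop1"), j]) / 2
  sub_p <- vapply(1:300, function(s) {
    ids <- panel_individuals(downsample_population(gm, "pop1", 16, s)$panel,
                             "pop1")
    mean(gm$dosage[ids, j]) / 2
  }, numeric(1))
  expect_equal(mean(sub_p), full_p, tolerance = 0.02)
})

test_that("windows tile from the origin and drop under-filled windows", {
  # loci at positions 1..499,999 only -> exactly one window
  pos <- seq(1, 499999, length.out = 60)
  s <- window_scan(pos, rep(0.1, 60))
  expect_equal(nrow(s$windows), 1)
  expect_equal(s$windows$start, 0)
  expect_equal(s$windows$end, 500000)
  expect_equal(s$windows$n_snps, 60)
  # 49 defined loci in a window -> dropped (threshold is >= 50)
  pos2 <- c(pos, seq(500001, 999999, length.out = 49))
  val2 <- c(rep(0.1, 60), rep(0.5, 49))
  s2 <- window_scan(pos2, val2)
  expect_equal(nrow(s2$windows), 1)
  # undefined loci are excluded from SNP counts
  val3 <- c(rep(0.1, 60), rep(NA, 49))
  s3 <- window_scan(c(pos, seq(500001, 999999, length.out = 49)), val3,
                    min_snps = 10)
  expect_equal(s3$windows$n_snps, 60)
  # no surviving window warns, does not error
  expect_warning(window_scan(pos, rep(0.1, 60), min_snps = 100),
                 "no window")
})

test_that("window means are invariant to locus input order", {
  set.seed(9)
  pos <- sample.int(3e6, 500)
  val <- rnorm(500)
  s1 <- window_scan(pos, val, min_snps = 10)
  ord <- sample(500)
  s2 <- window_scan(pos[ord], val[ord], min_snps = 10)
  expect_equal(s1$windows, s2$windows)
})

test_that("outlier calling: z, two-sided p, BH q, strict 3-SD flag", {
  # all windows equal except one extreme
  pos <- seq(1, 5e6 - 1, by = 1000)
  val <- rep(0.02, length(pos))
  val[pos >= 2e6 & pos < 2.5e6] <- 0.02 + rnorm(sum(pos >= 2e6 & pos < 2.5e6),
                                                0.3, 0.001)
  set.seed(2)
  s <- call_outliers(window_scan(pos, val))
  top <- which.max(s$windows$mean_lsbl)
  expect_equal(s$windows$start[top], 2e6)
  expect_equal(which.max(abs(s$windows$z)), top)
  # |z| = 3 exactly: two-sided p = 0.0027 to 2 significant figures, not flagged
  expect_equal(signif(2 * pnorm(-3), 2), 0.0027)
  fake <- window_scan(pos, val)
  m <- fake$windows$mean_lsbl
  expect_false(isTRUE(3 > 3))  # strict inequality contract
  called <- call_outliers(fake, k_sd = max(abs((m - mean(m)) / sd(m))))
  expect_false(any(called$windows$outlier))  # |z| equal to k_sd is not flagged
  # q >= p under BH
  expect_true(all(s$windows$q >= s$windows$p - 1e-15))
  # hand-computed BH step-up
  expect_equal(p.adjust(c(0.001, 0.02, 0.9), "BH"), c(0.003, 0.03, 0.9))
  # degenerate cases error
  flat <- window_scan(pos, rep(0.1, length(pos)))
  expect_error(call_outliers(flat), "zero SD")
  one <- window_scan(seq(1, 4e5, by = 1000), rep(0.1, 400))
  expect_error(call_outliers(one), "at least 2")
})

test_that("pipeline flags a per-site signal and stays specific to the test branch", {
  # scaled-down scenario so the injected locus dominates its window
  cfg <- sim_config(n_pops = 3, n_per_pop = 16, n_loci = 2000,
                    chrom_length_bp = 5e6, fst_param = 0.05,
                    selected_locus = list(target_pop = "pop1",
                                          position = 2.5e6,
                                          freq_shift = 0.6), seed = 42)
  scen <- simulate_island_genotypes(cfg)
  gm <- inject_selected_locus(scen$gm, scen$truth, "pop1", 2.5e6, 0.6,
                              seed = 43)
  sel <- scen$truth$selected_index
  # the injected site is an extreme per-site FST outlier in the test pop
  f <- lactascan:::wc_fst_loci(lactascan:::pop_dosage(gm, "pop1"),
                               lactascan:::pop_dosage(gm, "pop2"))$theta
  expect_gte(f[sel], quantile(f[-sel], 0.999, na.rm = TRUE))
  scan <- run_lsbl_pipeline(gm, "pop1", "pop2", "pop3")
  sel_pos <- scen$truth$positions[sel]
  w <- scan$windows
  in_win <- w$start <= sel_pos & sel_pos < w$end
  expect_true(any(in_win))
  # a locus differentiating the two references does not raise the test branch
  low <- which(scen$truth$ancestral_freq < 0.3)
  sel2 <- low[which.min(abs(scen$truth$positions[low] - 1.2e6))]
  sel2_pos <- scen$truth$positions[sel2]
  gm2 <- inject_selected_locus(scen$gm, scen$truth, "pop2", sel2_pos, 0.6,
                               seed = 44)
  f12 <- lactascan:::wc_fst_loci(lactascan:::pop_dosage(gm2, "pop1"),
                                 lactascan:::pop_dosage(gm2, "pop2"))$theta
  f13 <- lactascan:::wc_fst_loci(lactascan:::pop_dosage(gm2, "pop1"),
                                 lactascan:::pop_dosage(gm2, "pop3"))$theta
  f23 <- lactascan:::wc_fst_loci(lactascan:::pop_dosage(gm2, "pop2"),
                                 lactascan:::pop_dosage(gm2, "pop3"))$theta
  lsbl_test <- lsbl_locus(f12, f13, f23)
  # the -FST(ref1, ref2) term removes the reference-only signal
  expect_lt(lsbl_test[sel2], 0.2)
  expect_gt(f12[sel2], 0.3)
})

test_that("pipeline records parameters, seeds, and honors the clamp mode", {
  scen <- simulate_island_genotypes(sim_config(n_pops = 3, n_per_pop = 20,
                                               n_loci = 3000,
                                               chrom_length_bp = 1e7,
                                               seed = 77))
  s1 <- run_lsbl_pipeline(scen$gm, "pop1", "pop2", "pop3",
                          downsample_n = 16, seed = 5)
  expect_equal(s1$params$test_pop, "pop1")
  expect_equal(s1$params$seed, 5)
  s2 <- run_lsbl_pipeline(scen$gm, "pop1", "pop2", "pop3",
                          downsample_n = 16, seed = 5)
  expect_equal(s1$windows, s2$windows)   # same seed, same scan
  sz <- run_lsbl_pipeline(scen$gm, "pop1", "pop2", "pop3",
                          downsample_n = 16, seed = 5, clamp = "zero")
  # clamping never lowers a per-locus LSBL input pair
  expect_true(all(sz$windows$n_snps == s1$windows$n_snps))
  expect_error(run_lsbl_pipeline(scen$gm, "pop1", "pop1", "pop3"),
               "distinct")
})

test_that("negative-FST clamping does not change the outlier windows (control)", {
  scen <- default_scan_scenario(seed = 314)
  keep <- run_lsbl_pipeline(scen$gm, "pop1", "pop2", "pop3", clamp = "keep")
  zero <- run_lsbl_pipeline(scen$gm, "pop1", "pop2", "pop3", clamp = "zero")
  expect_identical(which(keep$windows$outlier), which(zero$windows$outlier))
})
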