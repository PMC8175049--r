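fixture_gm <- reconstruct_table2_fixture()

test_that("binomial SE matches the published table values and its properties", {
  expect_equal(round(binomial_se(0.25, 16), 3), 0.077)     # Beni Amer -13907
  expect_equal(round(binomial_se(1 / 3, 9), 3), 0.111)     # Hadendowa -14009
  expect_equal(binomial_se(0, 12), 0)
  expect_equal(binomial_se(1, 12), 0)
  expect_error(binomial_se(0.5, 0), ">= 1")
  # symmetry, maximum at 0.5, decreasing in N
  p <- seq(0.05, 0.95, by = 0.05)
  expect_equal(binomial_se(p, 10), binomial_se(1 - p, 10))
  expect_true(all(binomial_se(0.5, 10) >= binomial_se(p, 10)))
  for (pp in c(0.1, 0.3, 0.5)) {
    expect_true(all(diff(binomial_se(pp, 2:30)) < 0))
  }
})

test_that("confidence intervals clamp into [0, 1]", {
  ci <- confidence_interval(1 / 3, binomial_se(1 / 3, 9))
  expect_equal(round(unname(ci[, "low"]), 3), 0.116)
  expect_equal(round(unname(ci[, "high"]), 3), 0.551)
  ci2 <- confidence_interval(1 / 18, binomial_se(1 / 18, 9))
  expect_equal(unname(ci2[, "low"]), 0)                    # clamped at 0
  expect_equal(round(unname(ci2[, "high"]), 2), 0.16)
  expect_equal(as.vector(confidence_interval(0, 0)), c(0, 0))
})

test_that("allele frequencies come out as count / (2 x non-missing)", {
  r <- allele_frequency(fixture_gm, "Gaalien", "-13910")
  expect_equal(r$derived_count, 1L)
  expect_equal(r$allele_total, 24L)
  expect_equal(round(r$p, 3), 0.042)
  r2 <- allele_frequency(fixture_gm, "Beni Amer", "-14009")
  expect_equal(r2$derived_count, 9L)       # round(0.281 * 32)
  expect_equal(r2$p, 0.28125)
  r3 <- allele_frequency(fixture_gm, "Copt", "-13907")
  expect_equal(r3$p, 0)
  expect_equal(r3$se, 0)
  # integer closure: derived_count = round(p * allele_total) for all cells
  tab <- frequency_table(fixture_gm)
  expect_equal(tab$derived_count, as.integer(round(tab$p * tab$allele_total)))
})

test_that("a population with only missing calls at a locus is an error", {
  gm <- fixture_gm
  ids <- panel_individuals(gm$panel, "Gemar")
  gm$dosage[ids, "-13915"] <- NA
  expect_error(allele_frequency(gm, "Gemar", "-13915"), "Gemar")
  expect_error(allele_frequency(gm, "Gemar", "nope"), "not in")
})

test_that("predicted LP phenotype counts carriers of at least one LP allele", {
  expect_equal(predicted_lp_phenotype(fixture_gm, "Danagla")$percent, 25)
  expect_equal(round(predicted_lp_phenotype(fixture_gm, "Mahas")$percent, 1),
               7.1)
  # an individual heterozygous at two LP loci counts once
  d <- fixture_gm$dosage
  ids <- panel_individuals(fixture_gm$panel, "Bataheen")
  expect_equal(sum(d[ids[1], c("-13915", "-14009")]), 2)  # double het
  expect_equal(predicted_lp_phenotype(fixture_gm, "Bataheen")$carriers, 6L)
  # the -14010:A carrier does not count toward LP
  expect_equal(unname(d[ids[9], "-14010"]), 1L)
  carriers <- apply(d[ids, c("-13915", "-14009")], 1, function(x) any(x >= 1))
  expect_false(carriers[9])
})

test_that("LP phenotype is monotone under adding a derived allele", {
  set.seed(7)
  for (rep in 1:20) {
    gm <- fixture_gm
    pop <- sample(gm$panel$populations$population, 1)
    ids <- panel_individuals(gm$panel, pop)
    i <- sample(ids, 1)
    locus <- sample(lactascan:::lp_counted_loci(gm$variants), 1)
    before <- predicted_lp_phenotype(gm, pop)$percent
    if (gm$dosage[i, locus] < 2) {
      gm$dosage[i, locus] <- gm$dosage[i, locus] + 1L
      expect_gte(predicted_lp_phenotype(gm, pop)$percent, before)
    }
  }
})

test_that("a missing LP locus does not disqualify a carrier at another locus", {
  gm <- fixture_gm
  ids <- panel_individuals(gm$panel, "Shilluk")
  carrier <- ids[which(gm$dosage[ids, "-13915"] >= 1)]
  gm$dosage[carrier, "-14009"] <- NA
  expect_equal(predicted_lp_phenotype(gm, "Shilluk")$carriers, 1L)
})

test_that("exact HWE test agrees with direct enumeration on random tables", {
  set.seed(11)
  for (rep in 1:200) {
    g <- as.vector(stats::rmultinom(1, sample(2:16, 1), stats::runif(3)))
    expect_equal(hwe_exact_test(g[1], g[2], g[3])$p_value,
                 hwe_enum_oracle(g[1], g[2], g[3]), tolerance = 1e-12)
  }
  expect_equal(hwe_exact_test(12, 0, 0)$p_value, 1.0)  # monomorphic
  expect_equal(hwe_exact_test(0, 0, 7)$p_value, 1.0)
  expect_error(hwe_exact_test(0, 0, 0), "sum to >= 1")
})

test_that("HWE p-values are super-uniform under the null", {
  set.seed(23)
  n_tab <- 1000
  p_vals <- replicate(n_tab, {
    p <- runif(1, 0.1, 0.9)
    g <- as.vector(stats::rmultinom(1, 16, c((1 - p)^2, 2 * p * (1 - p), p^2)))
    hwe_exact_test(g[1], g[2], g[3])$p_value
  })
  for (alpha in c(0.01, 0.05, 0.1)) {
    mc_se <- sqrt(alpha * (1 - alpha) / n_tab)
    expect_lte(mean(p_vals < alpha), alpha + 3 * mc_se)
  }
})

test_that("no fixture LP locus deviates from HWE in simulated null panels", {
  # genotypes re-simulated under HWE at the fixture frequencies
  set.seed(31)
  freqs <- lp_frequency_table(fixture_gm)
  freqs <- freqs[freqs$p > 0, ]
  hits <- 0; total <- 0
  for (rep in 1:25) {
    for (i in seq_len(nrow(freqs))) {
      n <- freqs$allele_total[i] / 2
      p <- freqs$p[i]
      g <- as.vector(stats::rmultinom(1, n, c((1 - p)^2, 2 * p * (1 - p), p^2)))
      total <- total + 1
      if (hwe_exact_test(g[1], g[2], g[3])$p_value <= 0.05) hits <- hits + 1
    }
  }
  expect_gte(1 - hits / total, 0.95)
})

test_that("derived-allele totals reproduce the published counts", {
  counts <- aggregate_derived_counts(fixture_gm)
  expect_equal(unname(counts["-13915"]), 27L)
  expect_equal(unname(counts["-14009"]), 26L)
  gm0 <- fixture_gm
  gm0$dosage[] <- 0L
  expect_true(all(aggregate_derived_counts(gm0) == 0L))
})

test_that("rank correlation: identity, antitone, and exact permutation p", {
  x <- c(0.1, 0.3, 0.2, 0.8, 0.5, 0.4)
  expect_equal(rank_correlation(x, x)$rho, 1)
  expect_equal(rank_correlation(x, -x)$rho, -1)
  expect_error(rank_correlation(x, rep(1, 6)), "constant")
  set.seed(13)
  for (rep in 1:5) {
    y <- rnorm(6)
    r <- rank_correlation(x, y)
    expect_equal(r$p_exact, spearman_perm_oracle(x, y), tolerance = 1e-12)
  }
  # ties handled through mid-ranks in both routes
  xt <- c(1, 2, 2, 3, 4, 4)
  yt <- c(2, 1, 3, 3, 5, 4)
  expect_equal(rank_correlation(xt, yt)$p_exact,
               spearman_perm_oracle(xt, yt), tolerance = 1e-12)
  # above the exact-size cutoff only the t approximation is reported
  big <- rank_correlation(rnorm(15), rnorm(15))
  expect_true(is.na(big$p_exact))
  expect_false(is.na(big$p_approx))
})

test_that("LP frequency layer reports the canonical allele, so -14010:C is absent", {
  tab <- lp_frequency_table(fixture_gm)
  col <- tab[tab$locus_label == "-14010", ]
  expect_true(all(col$p == 0))
  # ...even though the A variant at the same position segregates once
  expect_equal(unname(aggregate_derived_counts(fixture_gm)["-14010"]), 1L)
})
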