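test_that("fixture variant panel matches the published nine-SNP region", {
  fx <- lp_fixture()
  vt <- fx$variants
  expect_equal(nrow(vt), 9)
  expect_equal(range(vt$ref_position), c(136608643L, 136608844L))
  expect_equal(sum(vt$lp_associated), 5)
  expect_setequal(vt$locus_label[vt$lp_associated],
                  c("-13907", "-13910", "-13915", "-14009", "-14010"))
  i <- match("-13915", vt$locus_label)
  expect_equal(vt$ref_position[i], 136608651L)
  expect_equal(vt$ancestral_allele[i], "T")
  expect_equal(vt$derived_allele[i], "G")
  expect_equal(vt$rsid[i], "rs41380347")
  # -14010's segregating allele is A, but the LP-associated allele is C
  j <- match("-14010", vt$locus_label)
  expect_equal(vt$derived_allele[j], "A")
  expect_equal(vt$lp_allele[j], "C")
  expect_false("-14010" %in% lactascan:::lp_counted_loci(vt))
})

test_that("fixture population panel has 18 populations and 203 individuals", {
  fx <- lp_fixture()
  expect_equal(nrow(fx$panel$populations), 18)
  expect_equal(nrow(fx$panel$individuals), 203)
  expect_equal(sum(fx$panel$populations$n), 203)
  ba <- fx$panel$populations[fx$panel$populations$population == "Beni Amer", ]
  expect_equal(ba$n, 16)
  expect_equal(ba$collective_group, "Beja")
  expect_equal(length(panel_individuals(fx$panel, "Beni Amer")), 16)
})

test_that("variant_table enforces its invariants", {
  expect_error(variant_table("a", 10, "A", "A"), "differ")
  expect_error(variant_table(c("a", "b"), c(10, 10), c("A", "C"),
                             c("G", "T")), "increasing")
  expect_error(variant_table("a", 10, "A", "N"), "single bases")
})

make_vcf <- function(lines) {
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  path
}

vcf_header <- c(
  "##fileformat=VCFv4.2",
  '##INFO=<ID=AA,Number=1,Type=String,Description="Ancestral allele">',
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1\tS2")

test_that("VCF dosages are oriented to the derived allele, with flip and missingness", {
  panel <- population_panel(c("S1", "S2"), c("p1", "p1"))
  vcf <- make_vcf(c(vcf_header,
    "2\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0/1\t1/1",   # ALT derived
    "2\t200\t.\tT\tC\t.\tPASS\tAA=C\tGT\t1/1\t./.",   # REF derived: flip
    "2\t300\t.\tG\tC\t.\tPASS\tAA=G\tGT\t0/0\t0/1"))
  gm <- read_genotypes(vcf, "vcf", panel)
  expect_equal(unname(gm$dosage["S1", ]), c(1L, 0L, 0L))
  expect_equal(unname(gm$dosage["S2", "100"]), 2L)
  expect_true(is.na(gm$dosage["S2", "200"]))       # ./. is missing, not 0
  expect_false(gm$phased)
  # missing entry reduces the allele total at that site
  expect_equal(allele_frequency(gm, "p1", "200")$allele_total, 2L)
})

test_that("flipping REF/ALT labels leaves derived dosages unchanged", {
  panel <- population_panel(c("S1", "S2"), c("p1", "p1"))
  v1 <- make_vcf(c(vcf_header, "2\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0/1\t1/1"))
  v2 <- make_vcf(c(vcf_header, "2\t100\t.\tG\tA\t.\tPASS\tAA=A\tGT\t1/0\t0/0"))
  g1 <- read_genotypes(v1, "vcf", panel)
  g2 <- read_genotypes(v2, "vcf", panel)
  expect_identical(g1$dosage, g2$dosage)
})

test_that("VCF records with unknown alleles are rejected with a warning", {
  panel <- population_panel(c("S1", "S2"), c("p1", "p1"))
  vcf <- make_vcf(c(vcf_header,
    "2\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0/1\t1/1",
    "2\t200\t.\tT\tC\t.\tPASS\tAA=G\tGT\t0/0\t0/1"))  # AA matches neither
  expect_warning(gm <- read_genotypes(vcf, "vcf", panel), "rejecting")
  expect_equal(ncol(gm$dosage), 1)
})

test_that("samples absent from the panel are an error", {
  panel <- population_panel("S1", "p1")
  vcf <- make_vcf(c(vcf_header, "2\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0/1\t1/1"))
  expect_error(read_genotypes(vcf, "vcf", panel), "absent from")
})

test_that("phased VCF input sets the phase flag and haplotypes", {
  panel <- population_panel(c("S1", "S2"), c("p1", "p1"))
  vcf <- make_vcf(c(vcf_header,
    "2\t100\t.\tA\tG\t.\tPASS\tAA=A\tGT\t0|1\t1|1",
    "2\t200\t.\tC\tT\t.\tPASS\tAA=C\tGT\t1|0\t0|0"))
  gm <- read_genotypes(vcf, "vcf", panel)
  expect_true(gm$phased)
  expect_equal(unname(gm$hap1["S1", ]), c(0L, 1L))
  expect_equal(unname(gm$hap2["S1", ]), c(1L, 0L))
})

test_that("TSV dialect round-trips dosages, missingness, and phase", {
  fx <- lp_fixture()
  gm <- reconstruct_table2_fixture()
  gm$dosage[3, 2] <- NA  # introduce missingness
  path <- tempfile(fileext = ".tsv")
  write_genotypes(gm, path)
  back <- read_genotypes(path, "tsv", fx$panel, variants = fx$variants)
  expect_identical(back$dosage, gm$dosage)
  expect_false(back$phased)

  ph <- simulate_phased_haplotypes(8, 5, 3, sweep = FALSE, seed = 42)
  path2 <- tempfile(fileext = ".tsv")
  write_genotypes(ph, path2)
  back2 <- read_genotypes(path2, "tsv", ph$panel, variants = ph$variants)
  expect_true(back2$phased)
  expect_identical(back2$hap1, ph$hap1)
  expect_identical(back2$hap2, ph$hap2)
  expect_identical(back2$dosage, ph$dosage)
})

test_that("write_results emits a deterministic TSV and refuses empty tables", {
  tab <- data.frame(population = "x", locus = "-13915", count = 5L,
                    total = 18L, p = 5 / 18, se = sqrt(5 / 18 * 13 / 18 / 18))
  f1 <- tempfile(); f2 <- tempfile()
  write_results(tab, f1)
  write_results(tab, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  header <- readLines(f1, n = 1)
  expect_match(header, "population\tlocus\tcount\ttotal\tp\tse")
  expect_error(write_results(tab[0, ], tempfile()), "empty")
})

test_that("genotype_matrix rejects inconsistent phased input and bad dosages", {
  fx <- lp_fixture()
  dos <- matrix(0L, 203, 9,
                dimnames = list(fx$panel$individuals$individual_id,
                                fx$variants$locus_label))
  expect_silent(genotype_matrix(dos, fx$variants, fx$panel))
  bad <- dos; bad[1, 1] <- 3L
  expect_error(genotype_matrix(bad, fx$variants, fx$panel), "0, 1, 2")
  h <- dos; h[] <- 0L
  h1 <- h; h1[1, 1] <- 1L   # hap sum 1 but dosage 0
  expect_error(genotype_matrix(dos, fx$variants, fx$panel, phased = TRUE,
                               hap1 = h1, hap2 = h), "sum to the dosage")
})
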