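# Bundled study fixture: the nine SNPs segregating in the 316-bp MCM6
# enhancer amplicon (chr2:136608643-136608844, hg19) and the 18-population
# Sudanese / South Sudanese panel of 203 fully-called individuals.

#' The LCT/MCM6 enhancer-region fixture
#'
#' Returns the nine-SNP variant panel of the 316-bp enhancer region together
#' with the 18-population sample panel (203 individuals). Five positions are
#' LP-associated (-13907, -13910, -13915, -14009, -14010); the observed
#' variant at -14010 is G>A, which is *not* the LP-associated C allele, so
#' its `lp_allele` is `"C"` and it never contributes to predicted phenotype.
#' Alleles are stored on the hg19 forward strand; -13910 is presented as
#' `C>T` in the LCT-upstream reading but stored as `G>A` (the strands are
#' complementary at that position).
#'
#' @return list with elements `variants` ([variant_table()]) and `panel`
#'   ([population_panel()]).
#' @export
lp_fixture <- function() {
  variants <- variant_table(
    locus_label = c("-13907", "-13910", "-13913", "-13915", "-14009",
                    "-14010", "-14011", "-14107", "-14108"),
    ref_position = c(136608643L, 136608646L, 136608649L, 136608651L,
                     136608745L, 136608746L, 136608747L, 136608843L,
                     136608844L),
    ancestral_allele = c("C", "G", "C", "T", "T", "G", "G", "C", "G"),
    derived_allele   = c("G", "A", "T", "G", "G", "A", "A", "T", "A"),
    rsid = c("rs41525747", "rs4988235", "rs41456145", "rs41380347",
             "rs869051967", "rs145946881", "rs4988233", "rs574071884",
             "rs56150605"),
    lp_associated = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, FALSE, FALSE,
                      FALSE),
    lp_allele = c("G", "A", NA, "G", "G", "C", NA, NA, NA),
    label_alleles = c("C>G", "C>T", "C>T", "T>G", "T>G", "G>A", "G>A",
                      "C>T", "G>A"),
    chrom = "2", build = "hg19"
  )

  pops <- fixture_population_meta()
  ids <- unlist(lapply(seq_len(nrow(pops)), function(i) {
    sprintf("%s_%02d", gsub(" ", "", pops$population[i]), seq_len(pops$n[i]))
  }))
  pop_of <- rep(pops$population, pops$n)
  panel <- population_panel(
    ids, pop_of,
    collective_group = stats::setNames(pops$collective_group, pops$population),
    subsistence = stats::setNames(pops$subsistence, pops$population),
    language_family = stats::setNames(pops$language_family, pops$population)
  )
  list(variants = variants, panel = panel)
}

fixture_population_meta <- function() {
  data.frame(
    population = c("Bataheen", "Gaalien", "Messiria", "Shaigia", "Copt",
                   "Hausa", "Beni Amer", "Hadendowa", "Danagla",
                   "Halfawieen", "Mahas", "Baria", "Dinka", "Nuer",
                   "Shilluk", "Gemar", "Zaghawa", "Nuba"),
    collective_group = c("Sudanese Arab", "Sudanese Arab", "Sudanese Arab",
                         "Sudanese Arab", "Copt", "Hausa", "Beja", "Beja",
                         "Nubian", "Nubian", "Nubian", "Nilotic", "Nilotic",
                         "Nilotic", "Nilotic", "Gemar", "Zaghawa", "Nuba"),
    n = c(9L, 12L, 8L, 12L, 11L, 5L, 16L, 9L, 12L, 9L, 14L, 5L, 14L, 15L,
          16L, 5L, 15L, 16L),
    language_family = c("Afro-Asiatic", "Afro-Asiatic", "Afro-Asiatic",
                        "Afro-Asiatic", "Afro-Asiatic", "Afro-Asiatic",
                        "Afro-Asiatic", "Afro-Asiatic", "Nilo-Saharan",
                        "Nilo-Saharan", "Nilo-Saharan", "Nilo-Saharan",
                        "Nilo-Saharan", "Nilo-Saharan", "Nilo-Saharan",
                        "Nilo-Saharan", "Nilo-Saharan",
                        "Nilo-Saharan and Niger-Congo"),
    subsistence = c("Agro-pastoralist", "Agriculturalist", "Pastoralist",
                    "Agriculturalist", "Agriculturalist", "Agriculturalist",
                    "Pastoralist", "Pastoralist", "Agriculturalist",
                    "Agriculturalist", "Agriculturalist", "Agro-pastoralist",
                    "Agro-pastoralist", "Agro-pastoralist",
                    "Agro-pastoralist", "Agro-pastoralist",
                    "Agro-pastoralist",
                    "Agriculturalist and Agro-pastoralist"),
    stringsAsFactors = FALSE
  )
}

# Per-population derived-allele counts and LP-carrier counts behind the
# published frequency table. LP-locus counts are round(freq * 2n); carrier
# counts are round(LP% * n / 100); the non-LP singletons are the reported
# individual observations.
fixture_allele_counts <- function() {
  list(
    "Bataheen"   = list(counts = c("-13915" = 5L, "-14009" = 3L,
                                   "-14010" = 1L, "-14011" = 1L),
                        carriers = 6L),
    "Gaalien"    = list(counts = c("-13910" = 1L, "-13915" = 1L,
                                   "-14009" = 3L), carriers = 5L),
    "Messiria"   = list(counts = c("-13915" = 2L), carriers = 1L),
    "Shaigia"    = list(counts = c("-13907" = 1L, "-13915" = 2L,
                                   "-14009" = 3L), carriers = 5L),
    "Copt"       = list(counts = c("-13913" = 1L), carriers = 0L),
    "Hausa"      = list(counts = integer(0), carriers = 0L),
    "Beni Amer"  = list(counts = c("-13907" = 8L, "-13915" = 8L,
                                   "-14009" = 9L, "-14107" = 1L),
                        carriers = 14L),
    "Hadendowa"  = list(counts = c("-13907" = 1L, "-13915" = 4L,
                                   "-14009" = 6L), carriers = 8L),
    "Danagla"    = list(counts = c("-13907" = 1L, "-13915" = 1L,
                                   "-14009" = 1L, "-14108" = 1L),
                        carriers = 3L),
    "Halfawieen" = list(counts = c("-13915" = 2L), carriers = 2L),
    "Mahas"      = list(counts = c("-13913" = 1L, "-14009" = 1L),
                        carriers = 1L),
    "Baria"      = list(counts = integer(0), carriers = 0L),
    "Dinka"      = list(counts = integer(0), carriers = 0L),
    "Nuer"       = list(counts = integer(0), carriers = 0L),
    "Shilluk"    = list(counts = c("-13915" = 1L), carriers = 1L),
    "Gemar"      = list(counts = c("-13915" = 1L), carriers = 1L),
    "Zaghawa"    = list(counts = integer(0), carriers = 0L),
    "Nuba"       = list(counts = integer(0), carriers = 0L)
  )
}

#' Reconstruct the study genotype matrix from the published summary layer
#'
#' Builds the 203-individual x 9-SNP genotype matrix whose per-population
#' derived-allele counts, frequencies, standard errors, and predicted-LP
#' percentages reproduce the published per-population table, and whose
#' per-locus totals reproduce the published derived-allele counts
#' (11, 1, 2, 27, 26, 1, 1, 1, 1).
#'
#' Individual heterozygote/homozygote configurations are under-determined by
#' the summary layer, so a fixed, documented allocation is used: within each
#' population the first `C` individuals are the LP carriers
#' (`C = round(LP% * n / 100)`); LP-locus derived alleles are dealt to them
#' round-robin in ascending position order (two alleles landing on the same
#' individual at one locus make a homozygote — e.g. the single Messiria
#' carrier is homozygous -13915:G); non-LP singleton alleles are placed as
#' heterozygotes in the highest-index individuals. The configuration is
#' deterministic, never random.
#'
#' @return an unphased [genotype_matrix()] of the full fixture.
#' @export
reconstruct_table2_fixture <- function() {
  fx <- lp_fixture()
  alloc <- fixture_allele_counts()
  ids <- fx$panel$individuals$individual_id
  dos <- matrix(0L, nrow = length(ids), ncol = nrow(fx$variants),
                dimnames = list(ids, fx$variants$locus_label))
  lp_loci <- lp_counted_loci(fx$variants)
  for (pop in names(alloc)) {
    pop_ids <- panel_individuals(fx$panel, pop)
    spec <- alloc[[pop]]
    lp_counts <- spec$counts[names(spec$counts) %in% lp_loci]
    # deal LP alleles round-robin across the carrier block
    k <- 0L
    for (locus in names(lp_counts)) {
      for (a in seq_len(lp_counts[[locus]])) {
        ind <- pop_ids[(k %% spec$carriers) + 1L]
        dos[ind, locus] <- dos[ind, locus] + 1L
        k <- k + 1L
      }
    }
    # non-LP singletons: heterozygotes in the highest-index individuals
    other <- spec$counts[!names(spec$counts) %in% lp_loci]
    slot <- length(pop_ids)
    for (locus in names(other)) {
      for (a in seq_len(other[[locus]])) {
        dos[pop_ids[slot], locus] <- dos[pop_ids[slot], locus] + 1L
        slot <- slot - 1L
      }
    }
  }
  genotype_matrix(dos, fx$variants, fx$panel)
}
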