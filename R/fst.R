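# Weir & Cockerham (1984) two-population per-site FST.
#
# Variance components for a biallelic site over r = 2 populations:
#   a  among populations, b  among individuals within populations,
#   c  within individuals (half the average observed heterozygosity).
# theta = a / (a + b + c). Observed heterozygote counts feed c directly
# (no HWE assumption). When a + b + c = 0 (both populations monomorphic for
# the same allele) the estimator is undefined and reported as such, never
# as 0.

# vectorized core over loci; each argument is a vector of genotype counts
wc_components <- function(nAA_a, nAa_a, naa_a, nAA_b, nAa_b, naa_b) {
  n1 <- nAA_a + nAa_a + naa_a
  n2 <- nAA_b + nAa_b + naa_b
  p1 <- (nAa_a + 2 * naa_a) / (2 * n1)
  p2 <- (nAa_b + 2 * naa_b) / (2 * n2)
  h1 <- nAa_a / n1
  h2 <- nAa_b / n2
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Weir-Cockerham FST at a single site
#'
#' Two-population Weir & Cockerham (1984) estimator from genotype counts.
#' `theta` may be slightly negative for undifferentiated populations; it is
#' exactly 1 iff the two populations are fixed for different alleles.
#'
#' @param counts_a,counts_b length-3 vectors
#'   `(hom_ancestral, het, hom_derived)` for the two populations; each
#'   population needs at least one non-missing individual.
#' @return one-row data frame: `theta`, components `a`, `b`, `c`, and
#'   `defined` (FALSE, with `theta = NA`, when both populations are
#'   monomorphic for the same allele).
#' @export
wc_fst_site <- function(counts_a, counts_b) {
  stopifnot(length(counts_a) == 3, length(counts_b) == 3,
            all(counts_a >= 0), all(counts_b >= 0))
  if (sum(counts_a) < 1 || sum(counts_b) < 1) {
    stop("wc_fst_site: each population needs >= 1 non-missing individual")
  }
  comp <- wc_components(counts_a[1], counts_a[2], counts_a[3],
                        counts_b[1], counts_b[2], counts_b[3])
  denom <- comp$a + comp$b + comp$c
  defined <- is.finite(denom) && denom != 0
  data.frame(theta = if (defined) comp$a / denom else NA_real_,
             a = comp$a, b = comp$b, c = comp$c, defined = defined)
}

# per-locus genotype counts of one population from a dosage matrix
genotype_counts <- function(dos) {
  cbind(nAA = colSums(dos == 0, na.rm = TRUE),
        nAa = colSums(dos == 1, na.rm = TRUE),
        naa = colSums(dos == 2, na.rm = TRUE))
}

# vectorized per-locus theta for one population pair; loci where either
# population has zero calls, or where the estimator is 0/0, give NA
wc_fst_loci <- function(dos_a, dos_b) {
  ga <- genotype_counts(dos_a)
  gb <- genotype_counts(dos_b)
  n_a <- rowSums(ga)
  n_b <- rowSums(gb)
  comp <- wc_components(ga[, 1], ga[, 2], ga[, 3], gb[, 1], gb[, 2], gb[, 3])
  denom <- comp$a + comp$b + comp$c
  theta <- ifelse(n_a >= 1 & n_b >= 1 & is.finite(denom) & denom != 0,
                  comp$a / denom, NA_real_)
  list(theta = theta, a = comp$a, b = comp$b, c = comp$c,
       defined = !is.na(theta))
}

#' Per-locus FST for every population pair
#'
#' Computes the per-site Weir-Cockerham estimator for every unordered pair
#' of the requested populations, in deterministic order (lexicographic
#' pairs, ascending position within a pair). A site where a population has
#' zero non-missing calls is undefined for that pair, not 0.
#'
#' @param gm a [genotype_matrix()].
#' @param pops populations to compare (default: all, `>= 2`).
#' @return data frame: `locus_label`, `ref_position`, `pop_a`, `pop_b`,
#'   `theta`, `defined`.
#' @export
fst_all_pairs <- function(gm, pops = NULL) {
  if (is.null(pops)) pops <- gm$panel$populations$population
  if (length(pops) < 2) stop("fst_all_pairs: need at least 2 populations")
  pops <- sort(unique(pops))
  dosages <- lapply(pops, function(p) pop_dosage(gm, p))
  names(dosages) <- pops
  pairs <- utils::combn(pops, 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    pa <- pairs[1, k]; pb <- pairs[2, k]
    res <- wc_fst_loci(dosages[[pa]], dosages[[pb]])
    data.frame(locus_label = gm$variants$locus_label,
               ref_position = gm$variants$ref_position,
               pop_a = pa, pop_b = pb,
               theta = res$theta, defined = res$defined,
               stringsAsFactors = FALSE, row.names = NULL)
  }))
}

#' Clamp negative FST estimates
#'
#' Control analysis mirroring the common practice of setting negative
#' single-site FST estimates to zero. `mode = "keep"` is the identity;
#' `mode = "zero"` maps `theta < 0` to 0 while undefined sites stay
#' undefined.
#'
#' @param values a data frame with a `theta` column (e.g. from
#'   [fst_all_pairs()]), or a numeric vector.
#' @param mode `"keep"` or `"zero"`.
#' @return same shape as `values`.
#' @export
clamp_negative <- function(values, mode = c("keep", "zero")) {
  mode <- match.arg(mode)
  if (mode == "keep") return(values)
  if (is.data.frame(values)) {
    values$theta <- pmax(values$theta, 0)
    values
  } else {
    pmax(values, 0)
  }
}

#' Multi-locus ratio-of-sums FST
#'
#' Reporting-level average over loci: sum of `a` components over the sum of
#' `a + b + c`, the standard way to combine Weir-Cockerham components
#' across sites. (Per-locus estimates, not this average, feed the LSBL
#' scan.)
#'
#' @param gm a [genotype_matrix()].
#' @param pop_a,pop_b population names.
#' @return single numeric value.
#' @export
fst_ratio_of_sums <- function(gm, pop_a, pop_b) {
  res <- wc_fst_loci(pop_dosage(gm, pop_a), pop_dosage(gm, pop_b))
  ok <- res$defined
  sum(res$a[ok]) / sum(res$a[ok] + res$b[ok] + res$c[ok])
}
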