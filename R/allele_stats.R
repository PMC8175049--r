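#' Binomial standard error of an allele frequency
#'
#' `SE = sqrt(p (1 - p) / (2 N))` where `p` is the derived-allele frequency
#' and `N` the number of diploid samples (so `2N` chromosomes). Symmetric in
#' `p <-> 1 - p` and zero at the boundaries.
#'
#' @param p allele frequency in \[0, 1\] (vectorized).
#' @param n_individuals number of diploid individuals, `>= 1`.
#' @return standard error(s).
#' @export
binomial_se <- function(p, n_individuals) {
  if (any(n_individuals < 1)) stop("binomial_se: n_individuals must be >= 1")
  if (any(p < 0 | p > 1)) stop("binomial_se: p must be in [0, 1]")
  sqrt(p * (1 - p) / (2 * n_individuals))
}

#' Clamped 95% confidence interval for an allele frequency
#'
#' `p +/- 1.96 SE`, clamped into \[0, 1\] (a frequency cannot leave the unit
#' interval, so a lower bound below 0 is reported as 0).
#'
#' @param p allele frequency.
#' @param se standard error, `>= 0`.
#' @param z critical value (default 1.96 for 95%).
#' @return a two-column matrix with columns `low`, `high`.
#' @export
confidence_interval <- function(p, se, z = 1.96) {
  if (any(se < 0)) stop("confidence_interval: se must be >= 0")
  cbind(low = pmax(0, p - z * se), high = pmin(1, p + z * se))
}

#' Per-population derived-allele frequency at one locus
#'
#' Counts derived alleles over the non-missing individuals of one
#' population; missing genotypes reduce the allele total (they are never
#' counted as ancestral). SE and CI follow [binomial_se()] and
#' [confidence_interval()], with `N` the number of non-missing individuals.
#'
#' @param gm a [genotype_matrix()].
#' @param population population name.
#' @param locus locus label.
#' @return one-row data frame: `population`, `locus_label`, `derived_count`,
#'   `allele_total`, `p`, `se`, `ci_low`, `ci_high`.
#' @export
allele_frequency <- function(gm, population, locus) {
  j <- locus_index(gm, locus)
  d <- pop_dosage(gm, population)[, j]
  n_called <- sum(!is.na(d))
  if (n_called == 0) {
    stop(sprintf("no non-missing genotypes for population '%s' at locus '%s'",
                 population, locus))
  }
  count <- sum(d, na.rm = TRUE)
  total <- 2L * n_called
  p <- count / total
  se <- binomial_se(p, n_called)
  ci <- confidence_interval(p, se)
  data.frame(population = population, locus_label = locus,
             derived_count = as.integer(count), allele_total = total,
             p = p, se = se, ci_low = ci[, "low"], ci_high = ci[, "high"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Frequency table over populations and loci
#'
#' @param gm a [genotype_matrix()].
#' @param populations populations to include (default: all, panel order).
#' @param loci loci to include (default: all, position order).
#' @return data frame, one row per population x locus, columns as in
#'   [allele_frequency()].
#' @export
frequency_table <- function(gm, populations = NULL, loci = NULL) {
  if (is.null(populations)) populations <- gm$panel$populations$population
  if (is.null(loci)) loci <- gm$variants$locus_label
  do.call(rbind, lapply(populations, function(pop) {
    do.call(rbind, lapply(loci, function(l) allele_frequency(gm, pop, l)))
  }))
}

#' The five-column LP frequency layer
#'
#' Frequencies of the five canonical LP-associated alleles per population.
#' At a position where the segregating derived allele is not the canonical
#' LP allele (the -14010 G>A case), the LP-allele frequency is 0 by
#' construction: nobody carries it.
#'
#' @param gm a [genotype_matrix()].
#' @param populations populations (default all).
#' @return data frame as [frequency_table()], restricted to LP positions,
#'   with LP-allele orientation.
#' @export
lp_frequency_table <- function(gm, populations = NULL) {
  if (is.null(populations)) populations <- gm$panel$populations$population
  vt <- gm$variants
  lp <- vt[vt$lp_associated, , drop = FALSE]
  counted <- lp_counted_loci(vt)
  do.call(rbind, lapply(populations, function(pop) {
    do.call(rbind, lapply(lp$locus_label, function(l) {
      row <- allele_frequency(gm, pop, l)
      if (!l %in% counted) {
        # canonical LP allele absent from the data: frequency is zero
        row$derived_count <- 0L
        row$p <- 0; row$se <- 0; row$ci_low <- 0; row$ci_high <- 0
      }
      row
    }))
  }))
}

#' Predicted lactase-persistence phenotype of one population
#'
#' The fraction of individuals carrying at least one LP-associated derived
#' allele, expressed as a percentage. An individual is a carrier if its
#' dosage is `>= 1` at any LP-counted locus; a missing genotype at one locus
#' does not disqualify an individual whose other loci show a derived allele.
#' Only canonical LP alleles count (the -14010:A allele does not).
#'
#' @param gm a [genotype_matrix()].
#' @param population population name.
#' @return one-row data frame: `population`, `carriers`, `n`, `percent`.
#' @export
predicted_lp_phenotype <- function(gm, population) {
  loci <- lp_counted_loci(gm$variants)
  if (length(loci) == 0) stop("no LP-associated loci in the variant table")
  d <- pop_dosage(gm, population)[, loci, drop = FALSE]
  if (nrow(d) == 0) stop(sprintf("population '%s' is empty", population))
  carriers <- sum(apply(d, 1, function(x) any(x >= 1, na.rm = TRUE)))
  data.frame(population = population, carriers = as.integer(carriers),
             n = nrow(d), percent = 100 * carriers / nrow(d),
             stringsAsFactors = FALSE)
}

#' Predicted LP phenotype for every population
#' @param gm a [genotype_matrix()].
#' @param populations populations (default all).
#' @return data frame, one row per population.
#' @export
lp_phenotype_table <- function(gm, populations = NULL) {
  if (is.null(populations)) populations <- gm$panel$populations$population
  do.call(rbind, lapply(populations, function(p) predicted_lp_phenotype(gm, p)))
}

#' Exact Hardy-Weinberg test
#'
#' Two-sided exact conditional test: given the observed allele counts, all
#' heterozygote counts of the same parity are enumerated, and the p-value is
#' the total probability of configurations no more probable than the
#' observed one. Appropriate for the small samples (n <= 16) typical of
#' field panels. A monomorphic site returns p = 1 by convention.
#'
#' @param hom_anc,het,hom_der non-negative genotype counts (ancestral
#'   homozygote, heterozygote, derived homozygote).
#' @return list with `p_value`, `counts`, and the enumerated heterozygote
#'   distribution (`het_values`, `het_probs`).
#' @export
hwe_exact_test <- function(hom_anc, het, hom_der) {
  counts <- c(hom_anc = hom_anc, het = het, hom_der = hom_der)
  if (any(counts < 0) || sum(counts) < 1) {
    stop("hwe_exact_test: counts must be non-negative and sum to >= 1")
  }
  n <- sum(counts)
  n_der <- het + 2 * hom_der            # derived allele count
  n_anc <- 2 * n - n_der
  if (n_der == 0 || n_anc == 0) {
    return(list(p_value = 1.0, counts = counts,
                het_values = het, het_probs = 1.0))
  }
  rare <- min(n_der, n_anc)
  hets <- seq(rare %% 2, rare, by = 2)   # feasible het counts share parity
  # log P(het = h | allele counts): multinomial over genotypes with 2^h
  logp <- vapply(hets, function(h) {
    homd <- (n_der - h) / 2
    homa <- n - h - homd
    h * log(2) + lgamma(n + 1) - lgamma(homa + 1) - lgamma(h + 1) -
      lgamma(homd + 1) +
      lgamma(n_der + 1) + lgamma(n_anc + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  # normalize in log space for numerical safety
  probs <- exp(logp - max(logp))
  probs <- probs / sum(probs)
  obs <- probs[match(het, hets)]
  p <- sum(probs[probs <= obs * (1 + 1e-12)])
  list(p_value = min(1, p), counts = counts,
       het_values = hets, het_probs = probs)
}

#' Hardy-Weinberg table over populations and loci
#'
#' @param gm a [genotype_matrix()].
#' @param populations populations (default all).
#' @param loci loci (default all).
#' @return data frame: `population`, `locus_label`, genotype counts, and the
#'   exact `p_value`.
#' @export
hwe_table <- function(gm, populations = NULL, loci = NULL) {
  if (is.null(populations)) populations <- gm$panel$populations$population
  if (is.null(loci)) loci <- gm$variants$locus_label
  do.call(rbind, lapply(populations, function(pop) {
    d <- pop_dosage(gm, pop)
    do.call(rbind, lapply(loci, function(l) {
      x <- d[, locus_index(gm, l)]
      x <- x[!is.na(x)]
      cc <- c(sum(x == 0), sum(x == 1), sum(x == 2))
      p <- if (sum(cc) == 0) NA_real_ else hwe_exact_test(cc[1], cc[2], cc[3])$p_value
      data.frame(population = pop, locus_label = l,
                 hom_ancestral = cc[1], het = cc[2], hom_derived = cc[3],
                 p_value = p, stringsAsFactors = FALSE)
    }))
  }))
}

#' Per-locus derived-allele totals
#'
#' Sums derived dosages over all individuals per locus, skipping missing
#' genotypes — the sample-wide derived-allele count layer.
#'
#' @param gm a [genotype_matrix()].
#' @return named integer vector (locus label -> derived-allele count).
#' @export
aggregate_derived_counts <- function(gm) {
  stats::setNames(as.integer(colSums(gm$dosage, na.rm = TRUE)),
                  colnames(gm$dosage))
}

#' Spearman rank correlation with exact permutation p-value
#'
#' Spearman's rho with mid-rank ties. For `n <= 10` paired observations the
#' permutation p-value is exact (all `n!` pairings enumerated, two-sided on
#' `|rho|`); for larger `n` the t approximation
#' `t = rho sqrt((n-2)/(1-rho^2))` is used. Both p-values are reported when
#' available.
#'
#' @param x,y paired numeric vectors, length >= 3.
#' @return list with `rho`, `p_value` (exact if available, else
#'   approximate), `p_exact`, `p_approx`, `n`.
#' @export
rank_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("rank_correlation: need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("rank_correlation: rho is undefined for a constant vector")
  }
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry)
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p_approx <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p_exact <- NA_real_
  if (n <= 10) {
    # statistic sum(rx * ry_perm) is monotone in rho for fixed marginals
    crx <- rx - mean(rx); cry <- ry - mean(ry)
    denom <- sqrt(sum(crx^2) * sum(cry^2))
    obs <- abs(sum(crx * cry) / denom)
    hits <- 0; total <- 0
    # enumerate chunked by the first element to bound memory at 10!
    sub <- all_permutations(n - 1L)
    for (first in seq_len(n)) {
      restidx <- setdiff(seq_len(n), first)
      perm_mat <- cbind(first, matrix(restidx[sub], nrow = nrow(sub)))
      stat <- abs(matrix(cry[perm_mat], nrow = nrow(perm_mat)) %*% crx) / denom
      hits <- hits + sum(stat >= obs - 1e-12)
      total <- total + nrow(perm_mat)
    }
    p_exact <- hits / total
  }
  list(rho = rho,
       p_value = if (!is.na(p_exact)) p_exact else p_approx,
       p_exact = p_exact, p_approx = p_approx, n = n)
}

# all permutations of 1..n as a matrix (n! rows); recursion is fine for the
# n <= 9 sizes reached via the chunked caller above
all_permutations <- function(n) {
  if (n <= 1L) return(matrix(1L, nrow = 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(first) {
    rest <- setdiff(seq_len(n), first)
    cbind(first, matrix(rest[sub], nrow = nrow(sub)))
  }))
}
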