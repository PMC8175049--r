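# Independent reference implementations used as oracles. Each is coded
# directly from the textbook definition, separately from the package's
# vectorized implementations.

# Weir & Cockerham (1984) theta for r populations, loop/sum transcription.
# counts: list of length-3 vectors (hom_anc, het, hom_der) per population.
wc84_oracle <- function(counts) {
  r <- length(counts)
  n <- vapply(counts, sum, numeric(1))
  p <- vapply(counts, function(g) (g[2] + 2 * g[3]) / (2 * sum(g)), numeric(1))
  h <- vapply(counts, function(g) g[2] / sum(g), numeric(1))
  nbar <- sum(n) / r
  nc <- (sum(n) - sum(n^2) / sum(n)) / (r - 1)
  pbar <- sum(n * p) / (r * nbar)
  s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(n * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) * (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 - ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  if (a + b + cc == 0) return(NA_real_)
  a / (a + b + cc)
}

# Exact HWE p-value by direct enumeration with factorial(); conditional on
# the observed allele counts, sums probabilities of all heterozygote counts
# no more probable than the observed one.
hwe_enum_oracle <- function(hom_anc, het, hom_der) {
  n <- hom_anc + het + hom_der
  n_der <- het + 2 * hom_der
  n_anc <- 2 * n - n_der
  if (n_der == 0 || n_anc == 0) return(1.0)
  rare <- min(n_der, n_anc)
  hets <- seq(rare %% 2, rare, by = 2)
  prob <- sapply(hets, function(h) {
    homd <- (n_der - h) / 2
    homa <- n - h - homd
    2^h * factorial(n) / (factorial(homa) * factorial(h) * factorial(homd)) *
      factorial(n_der) * factorial(n_anc) / factorial(2 * n)
  })
  prob <- prob / sum(prob)
  obs <- prob[match(het, hets)]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

# Exhaustive two-sided Spearman permutation p-value; permutations generated
# recursively, rho recomputed per permutation with stats::cor on ranks.
spearman_perm_oracle <- function(x, y) {
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  rx <- rank(x); ry <- rank(y)
  obs <- abs(cor(rx, ry))
  stats <- vapply(perms(seq_along(y)),
                  function(idx) abs(cor(rx, ry[idx])), numeric(1))
  mean(stats >= obs - 1e-12)
}

# random two-population genotype table (returns list of two length-3 counts)
random_geno_pair <- function(max_n = 20) {
  repeat {
    na <- sample(2:max_n, 1); nb <- sample(2:max_n, 1)
    ga <- as.vector(stats::rmultinom(1, na, prob = stats::runif(3)))
    gb <- as.vector(stats::rmultinom(1, nb, prob = stats::runif(3)))
    return(list(a = ga, b = gb))
  }
}

# tiny deterministic phased matrix builder for haplotype tests:
# haps is a matrix of 0/1 rows = chromosomes (even count), cols = markers
phased_gm_from_haps <- function(haps, positions = NULL) {
  stopifnot(nrow(haps) %% 2 == 0)
  n_ind <- nrow(haps) / 2
  if (is.null(positions)) positions <- 1000L * seq_len(ncol(haps))
  ids <- sprintf("ind%02d", seq_len(n_ind))
  labels <- sprintf("M%03d", seq_len(ncol(haps)))
  h1 <- haps[seq(1, nrow(haps), 2), , drop = FALSE]
  h2 <- haps[seq(2, nrow(haps), 2), , drop = FALSE]
  dimnames(h1) <- dimnames(h2) <- list(ids, labels)
  vt <- variant_table(labels, positions, rep("A", ncol(haps)),
                      rep("G", ncol(haps)), chrom = "sim", build = "sim")
  panel <- population_panel(ids, rep("tpop", n_ind))
  genotype_matrix(h1 + h2, vt, panel, phased = TRUE, hap1 = h1, hap2 = h2)
}
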