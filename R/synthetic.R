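# Balding-Nichols island-model genotype simulator with an injectable
# selected locus, plus a phased-haplotype generator for the bifurcation
# module. Every generator is a pure function of its seed and configuration.

#' Simulation configuration
#'
#' @param n_pops number of populations.
#' @param n_per_pop individuals per population (scalar or vector of length
#'   `n_pops`).
#' @param n_loci number of biallelic loci.
#' @param chrom_length_bp chromosome length; positions are drawn uniformly
#'   without replacement and sorted.
#' @param fst_param island-model differentiation F in (0, 1): subpopulation
#'   frequencies are Beta(p(1-F)/F, (1-p)(1-F)/F) around the ancestral
#'   frequency p.
#' @param ancestral_freq_range range (lo, hi) for the per-locus ancestral
#'   frequency, drawn uniformly.
#' @param selected_locus optional list
#'   `(target_pop, position, freq_shift, base_freq)` describing one
#'   high-differentiation locus: the locus nearest `position` has its
#'   ancestral frequency pinned to `base_freq` (default 0.2) so the shift
#'   stays in \[0, 1\]; [inject_selected_locus()] applies the shift.
#' @param seed integer seed.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_pops = 3L, n_per_pop = 16L, n_loci = 20000L,
                       chrom_length_bp = 50e6, fst_param = 0.05,
                       ancestral_freq_range = c(0.05, 0.95),
                       selected_locus = NULL, seed = 1L) {
  if (fst_param <= 0 || fst_param >= 1) {
    stop("sim_config: fst_param must be strictly inside (0, 1)")
  }
  n_per_pop <- rep_len(as.integer(n_per_pop), n_pops)
  stopifnot(all(n_per_pop >= 1), n_loci >= 1,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] < ancestral_freq_range[2])
  if (!is.null(selected_locus)) {
    if (is.null(selected_locus$base_freq)) selected_locus$base_freq <- 0.2
    shifted <- selected_locus$base_freq + selected_locus$freq_shift
    if (shifted < 0 || shifted > 1) {
      stop("sim_config: freq_shift must keep the shifted frequency in [0, 1]")
    }
  }
  structure(list(n_pops = as.integer(n_pops), n_per_pop = n_per_pop,
                 n_loci = as.integer(n_loci),
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 fst_param = fst_param,
                 ancestral_freq_range = ancestral_freq_range,
                 selected_locus = selected_locus, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate island-model genotypes (Balding-Nichols)
#'
#' Per locus: ancestral frequency `p ~ U(lo, hi)`; per population,
#' frequency `~ Beta(p(1-F)/F, (1-p)(1-F)/F)` independently; per diploid
#' individual, dosage `~ Binomial(2, pop frequency)`. Positions are sorted
#' draws without replacement over the chromosome. Bit-reproducible from
#' `cfg$seed`. The true per-population frequencies are returned for oracle
#' tests.
#'
#' @param cfg a [sim_config()].
#' @return list with `gm` (a [genotype_matrix()], populations named
#'   `pop1..popK`) and `truth` (list: `ancestral_freq`, `pop_freq`
#'   loci x pops matrix, `positions`, `selected_index` or NA).
#' @export
simulate_island_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  F <- cfg$fst_param
  with_seed(cfg$seed, {
    L <- cfg$n_loci
    positions <- sort(sample.int(cfg$chrom_length_bp, L))
    panc <- stats::runif(L, cfg$ancestral_freq_range[1],
                         cfg$ancestral_freq_range[2])
    sel_idx <- NA_integer_
    if (!is.null(cfg$selected_locus)) {
      sel_idx <- which.min(abs(positions - cfg$selected_locus$position))
      panc[sel_idx] <- cfg$selected_locus$base_freq
    }
    pop_freq <- matrix(NA_real_, nrow = L, ncol = cfg$n_pops)
    dos_blocks <- vector("list", cfg$n_pops)
    for (k in seq_len(cfg$n_pops)) {
      pk <- stats::rbeta(L, panc * (1 - F) / F, (1 - panc) * (1 - F) / F)
      pop_freq[, k] <- pk
      nk <- cfg$n_per_pop[k]
      dos_blocks[[k]] <- matrix(stats::rbinom(L * nk, 2L, rep(pk, each = nk)),
                                nrow = nk, ncol = L, byrow = FALSE)
    }
    dos <- do.call(rbind, dos_blocks)
    pops <- sprintf("pop%d", seq_len(cfg$n_pops))
    ids <- unlist(lapply(seq_len(cfg$n_pops), function(k) {
      sprintf("%s_i%03d", pops[k], seq_len(cfg$n_per_pop[k]))
    }))
    labels <- sprintf("L%06d", seq_len(L))
    dimnames(dos) <- list(ids, labels)
    vt <- variant_table(labels, positions, rep("A", L), rep("G", L),
                        chrom = "sim", build = "sim")
    panel <- population_panel(ids, rep(pops, cfg$n_per_pop))
    colnames(pop_freq) <- pops
    list(gm = genotype_matrix(dos, vt, panel),
         truth = list(ancestral_freq = panc, pop_freq = pop_freq,
                      positions = positions, selected_index = sel_idx))
  })
}

#' Inject a high-differentiation locus
#'
#' Redraws the target population's genotypes at the locus nearest
#' `position` from `Binomial(2, p + freq_shift)`, where `p` is the locus'
#' true ancestral frequency; all other populations are untouched. Emulates
#' a strongly selected site private to one lineage.
#'
#' @param gm a [genotype_matrix()] from [simulate_island_genotypes()].
#' @param truth the matching `truth` list.
#' @param target_pop population receiving the shift.
#' @param position bp position of the locus (nearest locus is used).
#' @param freq_shift shift added to the ancestral frequency; the result
#'   must stay in \[0, 1\].
#' @param seed integer seed for the redraw.
#' @return the modified [genotype_matrix()].
#' @export
inject_selected_locus <- function(gm, truth, target_pop, position,
                                  freq_shift, seed = 1L) {
  j <- which.min(abs(truth$positions - position))
  p_new <- truth$ancestral_freq[j] + freq_shift
  if (p_new < 0 || p_new > 1) {
    stop(sprintf("inject_selected_locus: shifted frequency %.3f outside [0, 1]",
                 p_new))
  }
  ids <- panel_individuals(gm$panel, target_pop)
  gm$dosage[ids, j] <- with_seed(seed,
                                 stats::rbinom(length(ids), 2L, p_new))
  gm
}

#' Simulate phased haplotypes around a core SNP
#'
#' Neutral mode: every marker is drawn independently with a frequency
#' uniform on `freq_range`. Sweep mode: haplotypes carrying the derived
#' core allele copy a single founder haplotype walking outward from the
#' core, flipping each marker with probability `mut_rate` and, with
#' per-interval probability `recomb_rate`, recombining onto a random
#' neutral background for the rest of that direction. Non-carriers are
#' neutral in both modes. Markers are evenly spaced 1 kb apart;
#' `n_haplotypes` must be even (haplotypes pair into diploid individuals).
#'
#' @param n_haplotypes even number of chromosomes, `>= 2`.
#' @param n_markers number of SNPs (the core included).
#' @param core_index column index of the core SNP.
#' @param sweep logical: sweep mode or neutral mode.
#' @param seed integer seed.
#' @param core_freq derived-allele frequency at the core (default 0.5).
#' @param mut_rate per-marker mutation probability in sweep mode (0.02).
#' @param recomb_rate per-interval recombination probability (0.05).
#' @param freq_range marker frequency range for neutral draws (0.2-0.8).
#' @return a phased [genotype_matrix()] with one population `"simpop"`.
#' @export
simulate_phased_haplotypes <- function(n_haplotypes, n_markers, core_index,
                                       sweep = FALSE, seed = 1L,
                                       core_freq = 0.5, mut_rate = 0.02,
                                       recomb_rate = 0.05,
                                       freq_range = c(0.2, 0.8)) {
  stopifnot(n_haplotypes >= 2, n_haplotypes %% 2 == 0,
            core_index >= 1, core_index <= n_markers)
  with_seed(seed, {
    q <- stats::runif(n_markers, freq_range[1], freq_range[2])
    H <- matrix(stats::rbinom(n_haplotypes * n_markers, 1L,
                              rep(q, each = n_haplotypes)),
                nrow = n_haplotypes)
    carrier <- stats::rbinom(n_haplotypes, 1L, core_freq) == 1L
    H[, core_index] <- as.integer(carrier)
    if (sweep && any(carrier)) {
      founder <- stats::rbinom(n_markers, 1L, q)
      founder[core_index] <- 1L
      background <- which(!carrier)
      for (i in which(carrier)) {
        for (dir in c(-1L, 1L)) {
          m <- core_index
          on_founder <- TRUE
          donor <- NULL
          repeat {
            m <- m + dir
            if (m < 1 || m > n_markers) break
            if (on_founder && stats::runif(1) < recomb_rate) {
              on_founder <- FALSE
              donor <- if (length(background))
                H[sample(background, 1), ] else stats::rbinom(n_markers, 1L, q)
            }
            allele <- if (on_founder) founder[m] else donor[m]
            if (stats::runif(1) < mut_rate) allele <- 1L - allele
            H[i, m] <- allele
          }
        }
      }
    }
    ids <- sprintf("sim_i%03d", seq_len(n_haplotypes / 2))
    h1 <- H[seq(1, n_haplotypes, by = 2), , drop = FALSE]
    h2 <- H[seq(2, n_haplotypes, by = 2), , drop = FALSE]
    labels <- sprintf("M%04d", seq_len(n_markers))
    dimnames(h1) <- dimnames(h2) <- list(ids, labels)
    vt <- variant_table(labels, 1000L * seq_len(n_markers),
                        rep("A", n_markers), rep("G", n_markers),
                        chrom = "sim", build = "sim")
    panel <- population_panel(ids, rep("simpop", length(ids)))
    genotype_matrix(h1 + h2, vt, panel, phased = TRUE, hap1 = h1, hap2 = h2)
  })
}

#' Default selection-scan scenario
#'
#' The bundled desk-scale scenario: 3 populations x 16 diploid individuals,
#' 20,000 loci over 50 Mb at island-model F = 0.05, with one locus near the
#' chromosome midpoint shifted by +0.6 in `pop1` (ancestral frequency
#' pinned at 0.2, so the target population sits near 0.8 while the
#' references stay near 0.2).
#'
#' @param seed integer seed.
#' @param inject logical; `FALSE` gives the matching null scenario (no
#'   shifted locus).
#' @return list with `gm`, `truth`, and `cfg`.
#' @export
default_scan_scenario <- function(seed = 1L, inject = TRUE) {
  sel <- if (inject) {
    list(target_pop = "pop1", position = 25e6, freq_shift = 0.6,
         base_freq = 0.2)
  } else NULL
  cfg <- sim_config(n_pops = 3L, n_per_pop = 16L, n_loci = 20000L,
                    chrom_length_bp = 50e6, fst_param = 0.05,
                    selected_locus = sel, seed = seed)
  sim <- simulate_island_genotypes(cfg)
  if (inject) {
    sim$gm <- inject_selected_locus(sim$gm, sim$truth, "pop1", 25e6, 0.6,
                                    seed = seed + 1L)
  }
  c(sim, list(cfg = cfg))
}
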