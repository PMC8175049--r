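# Locus-specific branch length (LSBL) selection scan.
#
# For a test population and two reference populations (one African, one
# non-African in the original design), the per-locus branch length of the
# test population on the three-population star tree is
#   LSBL_pop = (FST(ref1, pop) + FST(ref2, pop) - FST(ref1, ref2)) / 2.
# Window means over non-overlapping windows are converted to Z scores,
# two-sided normal p-values, and Benjamini-Hochberg q-values; windows more
# than k standard deviations from the mean are flagged.

#' Per-locus LSBL from three pairwise FST values
#'
#' @param fst_ref1_pop,fst_ref2_pop,fst_ref1_ref2 pairwise FST values
#'   (vectorized); an undefined (NA) input makes the locus LSBL undefined.
#' @return the half-difference branch length; may be negative.
#' @export
lsbl_locus <- function(fst_ref1_pop, fst_ref2_pop, fst_ref1_ref2) {
  (fst_ref1_pop + fst_ref2_pop - fst_ref1_ref2) / 2
}

#' Downsample one population to a fixed size
#'
#' Uniform sample of individuals without replacement, reproducible from the
#' seed; all other populations are untouched. Used to put reference panels
#' on the same footing as small field samples (e.g. n = 16).
#'
#' @param gm a [genotype_matrix()].
#' @param population population to downsample.
#' @param n target number of individuals (`<=` current size).
#' @param seed integer seed for the draw.
#' @return a [genotype_matrix()] with the reduced population.
#' @export
downsample_population <- function(gm, population, n, seed) {
  ids <- panel_individuals(gm$panel, population)
  if (n > length(ids)) {
    stop(sprintf("cannot downsample '%s' to %d: only %d individuals",
                 population, n, length(ids)))
  }
  keep_pop <- with_seed(seed, sort(sample(ids, n)))
  all_ids <- rownames(gm$dosage)
  keep <- all_ids[all_ids %in% c(setdiff(all_ids, ids), keep_pop)]
  gm_subset(gm, keep)
}

# evaluate expr under a local RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Windowed mean LSBL
#'
#' Tiles the chromosome with non-overlapping windows anchored at coordinate
#' 0 and averages the defined per-locus LSBL values in each window. Windows
#' holding fewer than `min_snps` defined loci are dropped.
#'
#' @param positions locus positions (bp).
#' @param lsbl per-locus LSBL values (NA = undefined, excluded from means
#'   and SNP counts).
#' @param window_bp window width in bp (default 500 kb).
#' @param min_snps minimum defined loci per retained window (default 50).
#' @return an `lsbl_scan` object: list with `loci` (position, lsbl) and
#'   `windows` (start, end half-open, n_snps, mean_lsbl, z, p, q, outlier —
#'   the last four filled by [call_outliers()]).
#' @export
window_scan <- function(positions, lsbl, window_bp = 500000L, min_snps = 50L) {
  stopifnot(length(positions) == length(lsbl))
  ord <- order(positions)
  positions <- positions[ord]; lsbl <- lsbl[ord]
  ok <- !is.na(lsbl)
  win <- floor(positions / window_bp)
  idx <- sort(unique(win[ok]))
  n_snps <- vapply(idx, function(w) sum(ok & win == w), integer(1))
  mean_lsbl <- vapply(idx, function(w) mean(lsbl[ok & win == w]), numeric(1))
  keep <- n_snps >= min_snps
  if (!any(keep)) {
    warning("window_scan: no window holds the minimum number of SNPs; empty scan")
  }
  nk <- sum(keep)
  windows <- data.frame(start = idx[keep] * window_bp,
                        end = (idx[keep] + 1) * window_bp,
                        n_snps = n_snps[keep],
                        mean_lsbl = mean_lsbl[keep],
                        z = rep(NA_real_, nk), p = rep(NA_real_, nk),
                        q = rep(NA_real_, nk), outlier = rep(NA, nk))
  structure(list(loci = data.frame(position = positions, lsbl = lsbl),
                 windows = windows,
                 params = list(window_bp = window_bp, min_snps = min_snps)),
            class = "lsbl_scan")
}

#' @export
print.lsbl_scan <- function(x, ...) {
  cat(sprintf("lsbl_scan: %d loci, %d retained windows (%g kb, >= %d SNPs)",
              nrow(x$loci), nrow(x$windows),
              x$params$window_bp / 1000, x$params$min_snps))
  if (!all(is.na(x$windows$outlier))) {
    cat(sprintf(", %d outlier window(s)", sum(x$windows$outlier)))
  }
  cat("\n")
  invisible(x)
}

#' Flag outlier windows
#'
#' Standardizes window means over the retained windows
#' (`z = (mean - grand mean) / SD`), converts to two-sided normal tail
#' probabilities, applies Benjamini-Hochberg correction across the windows
#' of the scanned chromosome, and flags windows with `|z| > k_sd` (strict
#' inequality; at 3 SD the two-sided p is 0.0027).
#'
#' @param scan an `lsbl_scan` from [window_scan()].
#' @param k_sd the SD multiple for the outlier flag (default 3).
#' @return the scan with `z`, `p`, `q`, `outlier` filled.
#' @export
call_outliers <- function(scan, k_sd = 3) {
  stopifnot(inherits(scan, "lsbl_scan"))
  w <- scan$windows
  if (nrow(w) < 2) stop("call_outliers: need at least 2 retained windows")
  s <- stats::sd(w$mean_lsbl)
  if (s == 0) stop("call_outliers: zero SD across windows (all means identical)")
  w$z <- (w$mean_lsbl - mean(w$mean_lsbl)) / s
  w$p <- 2 * stats::pnorm(-abs(w$z))
  w$q <- stats::p.adjust(w$p, method = "BH")
  w$outlier <- abs(w$z) > k_sd
  scan$windows <- w
  scan$params$k_sd <- k_sd
  scan
}

#' Run the full LSBL scan pipeline
#'
#' Composes optional downsampling, per-site Weir-Cockerham FST for the
#' three population pairs, per-locus LSBL for the test population, window
#' averaging, and outlier calling. Seed and parameters are recorded in the
#' result.
#'
#' @param gm a [genotype_matrix()].
#' @param test_pop the population whose branch is scanned.
#' @param ref1,ref2 the two reference populations.
#' @param window_bp,min_snps,k_sd see [window_scan()] and [call_outliers()].
#' @param downsample_n if set, every one of the three populations larger
#'   than this is downsampled to it.
#' @param seed seed for downsampling (required when `downsample_n` is set).
#' @param clamp `"keep"` (default) or `"zero"`: treatment of negative
#'   per-site FST before the LSBL arithmetic.
#' @return an `lsbl_scan` with `z/p/q/outlier` filled and a `params` record.
#' @export
run_lsbl_pipeline <- function(gm, test_pop, ref1, ref2,
                              window_bp = 500000L, min_snps = 50L, k_sd = 3,
                              downsample_n = NULL, seed = NULL,
                              clamp = c("keep", "zero")) {
  clamp <- match.arg(clamp)
  pops <- c(test_pop, ref1, ref2)
  if (anyDuplicated(pops)) stop("test and reference populations must be distinct")
  if (!is.null(downsample_n)) {
    if (is.null(seed)) stop("downsampling requires a seed")
    for (i in seq_along(pops)) {
      sz <- length(panel_individuals(gm$panel, pops[i]))
      if (sz > downsample_n) {
        gm <- downsample_population(gm, pops[i], downsample_n, seed + i)
      }
    }
  }
  f_r1_pop <- wc_fst_loci(pop_dosage(gm, ref1), pop_dosage(gm, test_pop))$theta
  f_r2_pop <- wc_fst_loci(pop_dosage(gm, ref2), pop_dosage(gm, test_pop))$theta
  f_r1_r2 <- wc_fst_loci(pop_dosage(gm, ref1), pop_dosage(gm, ref2))$theta
  if (clamp == "zero") {
    f_r1_pop <- clamp_negative(f_r1_pop, "zero")
    f_r2_pop <- clamp_negative(f_r2_pop, "zero")
    f_r1_r2 <- clamp_negative(f_r1_r2, "zero")
  }
  lsbl <- lsbl_locus(f_r1_pop, f_r2_pop, f_r1_r2)
  scan <- window_scan(gm$variants$ref_position, lsbl,
                      window_bp = window_bp, min_snps = min_snps)
  scan <- call_outliers(scan, k_sd = k_sd)
  scan$params <- c(scan$params,
                   list(test_pop = test_pop, ref1 = ref1, ref2 = ref2,
                        downsample_n = downsample_n, seed = seed,
                        clamp = clamp))
  scan
}
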