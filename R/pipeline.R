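# End-to-end driver: frequencies -> predicted phenotype -> HWE -> pairwise
# FST -> LSBL scan -> haplotype outputs, with a reproducibility manifest.

#' Run the full analysis pipeline
#'
#' Drives every stage over one genotype source and writes the result tables
#' as TSV into `out_dir`, together with a JSON run manifest recording the
#' tool version, the configuration snapshot, input file digests, all seeds,
#' and per-stage counts. Re-running with the same configuration and seeds
#' reproduces every output byte-identically (the manifest's timestamp is
#' the only field that differs).
#'
#' @param config named list (or path to a key-value config file readable by
#'   [read_config()]). Recognized keys: `mode` one of `"fixture"`,
#'   `"simulate"`, `"files"`; for `"files"`: `genotypes`, `format`
#'   (`vcf`/`tsv`), `panel_individuals` (TSV: individual_id, population),
#'   `variants` (variant table TSV); optional `admixture` (TSV for the rank
#'   correlation, with `locus` naming the frequency column); `out_dir`
#'   (default `"lactascan_out"`); `seed` (default 1); LSBL keys `test_pop`,
#'   `ref1`, `ref2`, `window_bp`, `min_snps`, `k_sd`, `downsample`,
#'   `clamp`; haplotype keys `core_positions` (comma-separated bp),
#'   `flank_bp`.
#' @return invisibly, a list with the computed tables and the manifest.
#' @export
run_full_analysis <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- read_config(config)
  }
  cfg <- function(key, default = NULL) {
    if (!is.null(config[[key]])) config[[key]] else default
  }
  mode <- cfg("mode", "fixture")
  out_dir <- cfg("out_dir", "lactascan_out")
  seed <- as.integer(cfg("seed", 1))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  digests <- character(0)

  log_stage <- function(...) message(sprintf(...))

  if (mode == "fixture") {
    gm <- reconstruct_table2_fixture()
  } else if (mode == "simulate") {
    scen <- default_scan_scenario(seed = seed)
    gm <- scen$gm
    truth_path <- file.path(out_dir, "truth.tsv")
    write_results(data.frame(position = scen$truth$positions,
                             ancestral_freq = scen$truth$ancestral_freq,
                             scen$truth$pop_freq,
                             selected = seq_along(scen$truth$positions) ==
                               scen$truth$selected_index),
                  truth_path)
  } else if (mode == "files") {
    vt <- read_variant_table(cfg("variants"))
    ind <- utils::read.table(cfg("panel_individuals"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
    panel <- population_panel(ind$individual_id, ind$population)
    gm <- read_genotypes(cfg("genotypes"), format = cfg("format", "vcf"),
                         panel = panel, variants = vt)
    digests <- tools::md5sum(unlist(config[c("genotypes", "variants",
                                             "panel_individuals")]))
  } else {
    stop(sprintf("unknown mode '%s'", mode))
  }
  log_stage("pipeline: %d individuals, %d loci, %d populations",
            nrow(gm$dosage), ncol(gm$dosage), nrow(gm$panel$populations))

  bundle <- list()
  bundle$frequencies <- frequency_table(gm)
  write_results(bundle$frequencies, file.path(out_dir, "frequencies.tsv"))
  if (any(gm$variants$lp_associated)) {
    bundle$lp_frequencies <- lp_frequency_table(gm)
    write_results(bundle$lp_frequencies,
                  file.path(out_dir, "lp_frequencies.tsv"))
    bundle$lp_phenotype <- lp_phenotype_table(gm)
    write_results(bundle$lp_phenotype,
                  file.path(out_dir, "lp_phenotype.tsv"))
  }
  bundle$hwe <- hwe_table(gm)
  write_results(bundle$hwe, file.path(out_dir, "hwe.tsv"))

  if (nrow(gm$panel$populations) >= 2 && ncol(gm$dosage) <= 1000) {
    bundle$fst <- fst_all_pairs(gm)
    write_results(bundle$fst, file.path(out_dir, "fst_pairs.tsv"))
    log_stage("pipeline: FST for %d population pairs",
              nrow(unique(bundle$fst[c("pop_a", "pop_b")])))
  }

  test_pop <- cfg("test_pop", if (mode == "simulate") "pop1")
  ref1 <- cfg("ref1", if (mode == "simulate") "pop2")
  ref2 <- cfg("ref2", if (mode == "simulate") "pop3")
  if (!is.null(test_pop) && !is.null(ref1) && !is.null(ref2)) {
    scan <- run_lsbl_pipeline(
      gm, test_pop, ref1, ref2,
      window_bp = as.integer(cfg("window_bp", 500000)),
      min_snps = as.integer(cfg("min_snps", 50)),
      k_sd = as.numeric(cfg("k_sd", 3)),
      downsample_n = if (!is.null(cfg("downsample")))
        as.integer(cfg("downsample")),
      seed = seed,
      clamp = cfg("clamp", "keep"))
    bundle$lsbl <- scan
    write_results(scan$windows, file.path(out_dir, "lsbl_windows.tsv"))
    log_stage("pipeline: LSBL scan kept %d windows, %d outlier(s)",
              nrow(scan$windows), sum(scan$windows$outlier))
  }

  if (gm$phased && !is.null(cfg("core_positions"))) {
    core <- as.numeric(strsplit(cfg("core_positions"), ",")[[1]])
    hm <- extract_haplotype_matrix(gm, core,
                                   flank_bp = as.integer(cfg("flank_bp", 30000)))
    bundle$haplotype_matrix <- hm
    hm_df <- data.frame(attr(hm, "rows"), unclass(hm),
                        check.names = FALSE)
    write_results(hm_df, file.path(out_dir, "haplotype_matrix.tsv"))
  }

  if (!is.null(cfg("admixture")) && !is.null(cfg("admixture_locus"))) {
    adm <- read_admixture(cfg("admixture"))
    locus <- cfg("admixture_locus")
    freqs <- vapply(adm$population, function(p)
      allele_frequency(gm, p, locus)$p, numeric(1))
    keep <- freqs > 0   # restrict to carriers of the allele
    rc <- rank_correlation(freqs[keep], adm$proportion[keep])
    bundle$correlation <- data.frame(locus = locus, rho = rc$rho,
                                     p_value = rc$p_value,
                                     p_exact = rc$p_exact,
                                     p_approx = rc$p_approx, n = rc$n)
    write_results(bundle$correlation, file.path(out_dir, "correlation.tsv"))
  }

  manifest <- list(
    tool = "lactascan",
    version = as.character(utils::packageVersion("lactascan")),
    timestamp = format(Sys.time(), tz = "UTC"),
    config = config,
    seed = seed,
    input_digests = as.list(digests),
    stages = list(
      individuals = nrow(gm$dosage),
      loci = ncol(gm$dosage),
      populations = nrow(gm$panel$populations),
      lsbl_windows = if (!is.null(bundle$lsbl)) nrow(bundle$lsbl$windows)
    )
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
  bundle$manifest <- manifest
  invisible(bundle)
}

#' Write a variant table as TSV
#' @param vt a [variant_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_variant_table <- function(vt, path) {
  out <- as.data.frame(vt)
  out$chrom <- attr(vt, "chrom")
  out$build <- attr(vt, "build")
  write_results(out, path)
}

#' Read a variant table from TSV
#' @param path file written by [write_variant_table()].
#' @return a [variant_table()].
#' @export
read_variant_table <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  variant_table(tab$locus_label, as.integer(tab$ref_position),
                tab$ancestral_allele, tab$derived_allele,
                rsid = tab$rsid,
                lp_associated = as.logical(tab$lp_associated),
                lp_allele = ifelse(tab$lp_allele %in% c("NA", ""),
                                   NA_character_, tab$lp_allele),
                label_alleles = tab$label_alleles,
                chrom = tab$chrom[1], build = tab$build[1])
}
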