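#' Construct a genotype matrix
#'
#' The central genotype container: an individuals x variants matrix of
#' derived-allele dosages in `{0, 1, 2}` with `NA` as the missing marker.
#' Missing entries are excluded from every downstream count — they are never
#' treated as dosage 0. Optionally phased: two haplotype matrices of
#' `{0, 1}` alleles whose sum must reproduce the dosage wherever it is
#' non-missing.
#'
#' @param dosage integer matrix, rows = individuals (rownames are ids),
#'   columns = variants (colnames are locus labels), entries in
#'   `{0, 1, 2, NA}`.
#' @param variants a [variant_table()] whose locus labels match the columns.
#' @param panel a [population_panel()] covering every row.
#' @param phased logical; if `TRUE`, `hap1` and `hap2` are required.
#' @param hap1,hap2 haplotype allele matrices (`{0, 1, NA}`), same dimnames
#'   as `dosage`.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, panel, phased = FALSE,
                            hap1 = NULL, hap2 = NULL) {
  stopifnot(is.matrix(dosage), inherits(panel, "population_panel"),
            inherits(variants, "variant_table"))
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop("genotype_matrix: dosage needs individual rownames and locus colnames")
  }
  if (!identical(colnames(dosage), variants$locus_label)) {
    stop("genotype_matrix: dosage columns must match variant table locus labels (same order)")
  }
  unknown <- setdiff(rownames(dosage), panel$individuals$individual_id)
  if (length(unknown)) {
    stop(sprintf("genotype_matrix: individuals absent from panel: %s",
                 paste(utils::head(unknown, 5), collapse = ", ")))
  }
  storage.mode(dosage) <- "integer"
  ok <- dosage %in% c(0L, 1L, 2L) | is.na(dosage)
  if (!all(ok)) stop("genotype_matrix: dosages must be 0, 1, 2 or NA")
  if (phased) {
    stopifnot(is.matrix(hap1), is.matrix(hap2),
              identical(dim(hap1), dim(dosage)),
              identical(dim(hap2), dim(dosage)))
    storage.mode(hap1) <- "integer"
    storage.mode(hap2) <- "integer"
    dimnames(hap1) <- dimnames(dosage)
    dimnames(hap2) <- dimnames(dosage)
    s <- hap1 + hap2
    bad <- !is.na(dosage) & (is.na(s) | s != dosage)
    if (any(bad)) {
      stop("genotype_matrix: phased haplotypes must sum to the dosage at every non-missing entry")
    }
  } else {
    hap1 <- hap2 <- NULL
  }
  structure(list(dosage = dosage, variants = variants, panel = panel,
                 phased = isTRUE(phased), hap1 = hap1, hap2 = hap2),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d variants (%s), %d populations, %.2f%% missing\n",
              nrow(x$dosage), ncol(x$dosage),
              if (x$phased) "phased" else "unphased",
              nrow(x$panel$populations),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

# dosage submatrix of one population (keeps all columns)
pop_dosage <- function(gm, population) {
  ids <- panel_individuals(gm$panel, population)
  gm$dosage[ids, , drop = FALSE]
}

locus_index <- function(gm, locus) {
  i <- match(locus, gm$variants$locus_label)
  if (is.na(i)) stop(sprintf("locus '%s' not in variant table", locus))
  i
}

#' Restrict a genotype matrix to a subset of individuals
#'
#' @param gm a `genotype_matrix`.
#' @param ids individual ids to keep (order preserved as given).
#' @return a `genotype_matrix` over the same variants; the panel is subset
#'   accordingly.
#' @export
gm_subset <- function(gm, ids) {
  stopifnot(inherits(gm, "genotype_matrix"))
  missing_ids <- setdiff(ids, rownames(gm$dosage))
  if (length(missing_ids)) {
    stop(sprintf("unknown individuals: %s", paste(utils::head(missing_ids, 5), collapse = ", ")))
  }
  ind <- gm$panel$individuals
  ind <- ind[match(ids, ind$individual_id), , drop = FALSE]
  meta <- gm$panel$populations
  panel <- population_panel(
    ind$individual_id, ind$population,
    collective_group = stats::setNames(meta$collective_group, meta$population),
    subsistence = stats::setNames(meta$subsistence, meta$population),
    language_family = stats::setNames(meta$language_family, meta$population)
  )
  genotype_matrix(gm$dosage[ids, , drop = FALSE], gm$variants, panel,
                  phased = gm$phased,
                  hap1 = if (gm$phased) gm$hap1[ids, , drop = FALSE],
                  hap2 = if (gm$phased) gm$hap2[ids, , drop = FALSE])
}

#' Read genotypes from VCF or the package TSV dialect
#'
#' Dosages are always oriented to the *derived* allele, not the ALT allele:
#' at a site where REF is the derived allele the ALT count is flipped.
#' Ancestral/derived metadata comes from a sidecar [variant_table()] matched
#' by position or, failing that, from the `AA` INFO tag. A record whose
#' REF/ALT alleles do not match the known ancestral/derived pair is rejected
#' with a warning. Genotypes are taken as phased iff every non-missing call
#' uses the `|` separator.
#'
#' @param path input file.
#' @param format `"vcf"` (VCF 4.x, diploid GT field) or `"tsv"` (the dialect
#'   written by [write_genotypes()]).
#' @param panel a [population_panel()]; every sample in the file must be in
#'   it.
#' @param variants optional [variant_table()] providing ancestral/derived
#'   alleles (required for `"tsv"`; recommended for `"vcf"`).
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "tsv"), panel,
                           variants = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (format == "vcf") {
    read_genotypes_vcf(path, panel, variants)
  } else {
    if (is.null(variants)) stop("the TSV dialect requires a sidecar variant_table")
    read_genotypes_tsv(path, panel, variants)
  }
}

read_genotypes_vcf <- function(path, panel, variants) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  pos <- as.integer(fix[, "POS"])
  ref <- toupper(fix[, "REF"])
  alt <- toupper(fix[, "ALT"])
  info <- v@fix[, "INFO"]
  aa <- sub(".*AA=([ACGTacgt]).*", "\\1", info)
  aa[!grepl("AA=", info)] <- NA
  aa <- toupper(aa)

  gt <- v@gt[, -1, drop = FALSE]
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  samples <- colnames(v@gt)[-1]
  unknown <- setdiff(samples, panel$individuals$individual_id)
  if (length(unknown)) {
    stop(sprintf("samples absent from population panel: %s",
                 paste(unknown, collapse = ", ")))
  }
  gt <- sub(":.*", "", gt)  # GT is the leading field

  keep <- logical(length(pos))
  anc <- der <- character(length(pos))
  for (i in seq_along(pos)) {
    if (!is.null(variants)) {
      j <- match(pos[i], variants$ref_position)
      if (!is.na(j)) {
        anc[i] <- variants$ancestral_allele[j]
        der[i] <- variants$derived_allele[j]
      } else if (!is.na(aa[i])) {
        anc[i] <- aa[i]
        der[i] <- if (aa[i] == ref[i]) alt[i] else ref[i]
      }
    } else if (!is.na(aa[i])) {
      anc[i] <- aa[i]
      der[i] <- if (aa[i] == ref[i]) alt[i] else ref[i]
    }
    keep[i] <- nzchar(anc[i]) &&
      setequal(c(ref[i], alt[i]), c(anc[i], der[i]))
    if (!keep[i]) {
      warning(sprintf("rejecting VCF record at position %d: alleles %s/%s do not match known ancestral/derived pair",
                      pos[i], ref[i], alt[i]))
    }
  }
  if (!any(keep)) stop("no usable VCF records")

  pos <- pos[keep]; ref <- ref[keep]; alt <- alt[keep]
  anc <- anc[keep]; der <- der[keep]
  gt <- gt[keep, , drop = FALSE]

  if (!is.null(variants)) {
    j <- match(pos, variants$ref_position)
    labels <- ifelse(is.na(j), as.character(pos), variants$locus_label[j])
    vt_rows <- !is.na(j)
  } else {
    labels <- as.character(pos)
  }
  ord <- order(pos)
  pos <- pos[ord]; anc <- anc[ord]; der <- der[ord]; alt <- alt[ord]
  labels <- labels[ord]; gt <- gt[ord, , drop = FALSE]

  vt <- variant_table(labels, pos, anc, der,
                      rsid = if (!is.null(variants))
                        variants$rsid[match(pos, variants$ref_position)] else NA,
                      lp_associated = if (!is.null(variants))
                        variants$lp_associated[match(pos, variants$ref_position)] %in% TRUE
                      else FALSE,
                      lp_allele = if (!is.null(variants))
                        variants$lp_allele[match(pos, variants$ref_position)] else NULL,
                      chrom = if (!is.null(variants)) attr(variants, "chrom") else "NA",
                      build = if (!is.null(variants)) attr(variants, "build") else "NA")

  parse_allele <- function(x) ifelse(x %in% c("0", "1"), as.integer(x), NA_integer_)
  a1 <- substr(gt, 1, 1)
  sep <- substr(gt, 2, 2)
  a2 <- substr(gt, 3, 3)
  h1 <- matrix(parse_allele(a1), nrow = nrow(gt))
  h2 <- matrix(parse_allele(a2), nrow = nrow(gt))
  phased <- all(sep[!is.na(h1) & !is.na(h2)] == "|") && any(!is.na(h1))
  # orient to the derived allele: ALT count only when ALT is derived
  flip <- alt != der
  h1[flip, ] <- 1L - h1[flip, ]
  h2[flip, ] <- 1L - h2[flip, ]
  dos <- h1 + h2
  dos <- t(dos); h1 <- t(h1); h2 <- t(h2)
  dimnames(dos) <- dimnames(h1) <- dimnames(h2) <- list(samples, labels)
  genotype_matrix(dos, vt, panel, phased = phased,
                  hap1 = if (phased) h1, hap2 = if (phased) h2)
}

#' Write genotypes in the package TSV dialect
#'
#' Tab-separated with a mandatory header; first column `individual_id`, one
#' column per locus. Unphased cells hold the dosage `0/1/2`; phased cells
#' hold `a|b` haplotype alleles; missing is `.`. The dialect round-trips
#' dosage, missingness, and phase exactly.
#'
#' @param gm a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (gm$phased) {
    cells <- matrix(paste0(gm$hap1, "|", gm$hap2), nrow = nrow(gm$dosage))
    cells[is.na(gm$hap1) | is.na(gm$hap2)] <- "."
  } else {
    cells <- matrix(as.character(gm$dosage), nrow = nrow(gm$dosage))
    cells[is.na(gm$dosage)] <- "."
  }
  out <- cbind(individual_id = rownames(gm$dosage), cells)
  colnames(out) <- c("individual_id", colnames(gm$dosage))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_genotypes_tsv <- function(path, panel, variants) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           colClasses = "character", check.names = FALSE)
  if (!identical(colnames(tab)[1], "individual_id")) {
    stop("TSV dialect: first column must be 'individual_id'")
  }
  loci <- colnames(tab)[-1]
  if (!all(loci %in% variants$locus_label)) {
    stop("TSV dialect: columns not present in the variant table")
  }
  vt <- variants[match(loci, variants$locus_label), , drop = FALSE]
  class(vt) <- c("variant_table", "data.frame")
  attr(vt, "chrom") <- attr(variants, "chrom")
  attr(vt, "build") <- attr(variants, "build")
  ids <- tab$individual_id
  unknown <- setdiff(ids, panel$individuals$individual_id)
  if (length(unknown)) {
    stop(sprintf("samples absent from population panel: %s",
                 paste(unknown, collapse = ", ")))
  }
  cells <- as.matrix(tab[, -1, drop = FALSE])
  phased <- any(grepl("|", cells, fixed = TRUE))
  if (phased) {
    a1 <- suppressWarnings(as.integer(substr(cells, 1, 1)))
    a2 <- suppressWarnings(as.integer(substr(cells, 3, 3)))
    h1 <- matrix(a1, nrow = nrow(cells), dimnames = list(ids, loci))
    h2 <- matrix(a2, nrow = nrow(cells), dimnames = list(ids, loci))
    dos <- h1 + h2
    genotype_matrix(dos, vt, panel, phased = TRUE, hap1 = h1, hap2 = h2)
  } else {
    dos <- matrix(suppressWarnings(as.integer(cells)),
                  nrow = nrow(cells), dimnames = list(ids, loci))
    genotype_matrix(dos, vt, panel)
  }
}
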