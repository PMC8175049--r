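#' Construct a variant table
#'
#' A `variant_table` holds per-SNP metadata for a single chromosome: the
#' LCT-upstream locus label (e.g. `"-13915"`), the 1-based position on the
#' stated reference build (authoritative for windowing), forward-strand
#' ancestral and derived alleles, the rsid, and whether the position is one of
#' the five known lactase-persistence (LP) associated sites. Because the
#' observed derived allele at a position need not be the LP-associated one
#' (the -14010 G>A case), the canonical LP allele is carried separately in
#' `lp_allele`; phenotype prediction and the LP frequency layer count that
#' allele, never the merely co-located one.
#'
#' @param locus_label character, e.g. `"-13910"` for upstream sites or any
#'   unique label for simulated loci.
#' @param ref_position integer, 1-based bp position; must be strictly
#'   increasing.
#' @param ancestral_allele,derived_allele single bases in `A,C,G,T`, on the
#'   forward strand of `build`; must differ per record.
#' @param rsid character rs identifiers (`NA` allowed).
#' @param lp_associated logical, `TRUE` for positions known to harbor an
#'   LP-associated allele.
#' @param lp_allele the canonical LP-associated derived allele at the
#'   position (forward strand), `NA` for non-LP sites. Defaults to
#'   `derived_allele` where `lp_associated` is `TRUE`.
#' @param label_alleles presentation-layer allele string (e.g. `"C>T"` for
#'   -13910, which is reverse-complemented relative to the forward strand).
#' @param chrom chromosome name, single value.
#' @param build reference build label, single value.
#' @return a data frame of class `variant_table`.
#' @export
variant_table <- function(locus_label, ref_position, ancestral_allele,
                          derived_allele, rsid = NA_character_,
                          lp_associated = FALSE, lp_allele = NULL,
                          label_alleles = NULL, chrom = "2", build = "hg19") {
  n <- length(locus_label)
  ref_position <- as.integer(ref_position)
  stopifnot(length(ref_position) == n, length(ancestral_allele) == n,
            length(derived_allele) == n)
  rsid <- rep_len(as.character(rsid), n)
  lp_associated <- rep_len(as.logical(lp_associated), n)
  if (is.null(lp_allele)) {
    lp_allele <- ifelse(lp_associated, derived_allele, NA_character_)
  }
  if (is.null(label_alleles)) {
    label_alleles <- paste0(ancestral_allele, ">", derived_allele)
  }
  vt <- data.frame(
    locus_label = as.character(locus_label),
    ref_position = ref_position,
    ancestral_allele = toupper(ancestral_allele),
    derived_allele = toupper(derived_allele),
    rsid = rsid,
    lp_associated = lp_associated,
    lp_allele = as.character(lp_allele),
    label_alleles = as.character(label_alleles),
    stringsAsFactors = FALSE
  )
  attr(vt, "chrom") <- as.character(chrom[1])
  attr(vt, "build") <- as.character(build[1])
  class(vt) <- c("variant_table", "data.frame")
  validate_variant_table(vt)
  vt
}

validate_variant_table <- function(vt) {
  bases <- c("A", "C", "G", "T")
  if (anyDuplicated(vt$locus_label)) {
    stop("variant_table: locus labels must be unique")
  }
  if (any(diff(vt$ref_position) <= 0)) {
    stop("variant_table: ref_position must be strictly increasing within the chromosome")
  }
  if (!all(vt$ancestral_allele %in% bases) || !all(vt$derived_allele %in% bases)) {
    stop("variant_table: alleles must be single bases in {A,C,G,T}")
  }
  if (any(vt$ancestral_allele == vt$derived_allele)) {
    stop("variant_table: ancestral and derived allele must differ")
  }
  invisible(vt)
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d SNPs on chr%s (%s), %d LP-associated\n",
              nrow(x), attr(x, "chrom"), attr(x, "build"),
              sum(x$lp_associated)))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

# loci whose stored derived allele is the canonical LP allele; only these
# contribute to carrier status and LP frequency columns
lp_counted_loci <- function(vt) {
  vt$locus_label[vt$lp_associated & !is.na(vt$lp_allele) &
                   vt$derived_allele == vt$lp_allele]
}
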