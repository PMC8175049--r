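# Haplotype-structure summaries around core LP alleles: the per-chromosome
# allele matrix over a flank (one line per chromosome, only polymorphic
# columns) and the bifurcation tree tracking how haplotypes carrying a core
# allele diversify marker by marker away from the core.

#' Extract a haplotype matrix around core positions
#'
#' One row per chromosome (two per diploid individual), one column per SNP
#' within `flank_bp` of any core position that is polymorphic in the
#' selected populations. Rows are stably sorted by (carried LP allele,
#' population, individual) so chromosomes sharing a derived LP allele
#' cluster together. Column labels are reference positions, except LP loci
#' which keep their upstream labels plus alleles.
#'
#' @param gm a *phased* [genotype_matrix()].
#' @param core_positions reference positions of the core alleles.
#' @param flank_bp flank width on each side (default 30 kb).
#' @param populations populations to include (default all).
#' @return a `haplotype_matrix`: 0/1 matrix with attributes `positions`
#'   (per column) and `rows` (data frame: individual, population, hap,
#'   lp_allele).
#' @export
extract_haplotype_matrix <- function(gm, core_positions, flank_bp = 30000L,
                                     populations = NULL) {
  if (!gm$phased) {
    stop("extract_haplotype_matrix: phased input required (provide phased data)")
  }
  if (!all(core_positions %in% gm$variants$ref_position)) {
    stop("core position(s) absent from the variant table")
  }
  if (is.null(populations)) populations <- gm$panel$populations$population
  ids <- unlist(lapply(populations, function(p) panel_individuals(gm$panel, p)))
  pos <- gm$variants$ref_position
  in_flank <- Reduce(`|`, lapply(core_positions, function(cp) {
    pos >= cp - flank_bp & pos <= cp + flank_bp
  }))
  h1 <- gm$hap1[ids, in_flank, drop = FALSE]
  h2 <- gm$hap2[ids, in_flank, drop = FALSE]
  rows <- rbind(h1, h2)
  hap_no <- rep(c(1L, 2L), each = length(ids))
  ind <- rep(ids, 2)
  pop <- gm$panel$individuals$population[match(ind, gm$panel$individuals$individual_id)]
  # drop columns monomorphic in the selected populations
  poly <- apply(rows, 2, function(x) {
    u <- unique(x[!is.na(x)]); length(u) > 1
  })
  rows <- rows[, poly, drop = FALSE]
  vt <- gm$variants[in_flank, , drop = FALSE][poly, , drop = FALSE]
  labels <- ifelse(vt$lp_associated | grepl("^-", vt$locus_label),
                   paste0(vt$locus_label, ":", vt$label_alleles),
                   as.character(vt$ref_position))
  colnames(rows) <- labels
  # carried LP allele (first LP-counted locus with a derived allele, if any)
  lp_cols <- which(vt$locus_label %in% lp_counted_loci(gm$variants))
  carried <- rep(NA_character_, nrow(rows))
  for (j in rev(lp_cols)) {
    hit <- !is.na(rows[, j]) & rows[, j] == 1
    carried[hit] <- vt$locus_label[j]
  }
  ord <- order(!is.na(carried), carried, pop, ind, hap_no,
               method = "radix", decreasing = c(TRUE, FALSE, FALSE, FALSE, FALSE))
  rows <- rows[ord, , drop = FALSE]
  meta <- data.frame(individual = ind[ord], population = pop[ord],
                     hap = hap_no[ord], lp_allele = carried[ord],
                     stringsAsFactors = FALSE)
  rownames(rows) <- paste0(meta$individual, "_h", meta$hap)
  structure(rows, positions = vt$ref_position, rows = meta,
            class = c("haplotype_matrix", class(rows)))
}

#' @export
print.haplotype_matrix <- function(x, ...) {
  cat(sprintf("haplotype_matrix: %d chromosomes x %d polymorphic SNPs\n",
              nrow(x), ncol(x)))
  invisible(x)
}

#' Build a haplotype bifurcation tree from a core allele
#'
#' The root holds every haplotype carrying `core_allele` at `core_marker`
#' (optionally excluding haplotypes that carry a derived allele at any of
#' `exclude_derived_at` — the ancestral-core construction). Markers are then
#' consumed one SNP at a time outward in the chosen direction, in physical
#' order; at each marker every node splits by the allele observed, so
#' branches with identical prefixes merge by construction. Construction
#' stops after `max_steps` markers, when markers run out, or when every node
#' is a singleton. Haplotypes with a missing allele in the traversed flank
#' are dropped (with a message).
#'
#' @param gm a *phased* [genotype_matrix()].
#' @param core_marker locus label of the core SNP.
#' @param core_allele 0 (ancestral) or 1 (derived).
#' @param direction `"left"` (decreasing position) or `"right"`.
#' @param max_steps maximum markers to traverse, `>= 1`.
#' @param populations restrict to these populations (default all).
#' @param exclude_derived_at locus labels; haplotypes carrying allele 1 at
#'   any of them are excluded from the root.
#' @return a `bifurcation_tree`: list with `core`, `n` (root count),
#'   `nodes` (data frame: id, parent, depth, allele, count), `markers`.
#' @export
build_bifurcation_tree <- function(gm, core_marker, core_allele,
                                   direction = c("left", "right"),
                                   max_steps = 10L, populations = NULL,
                                   exclude_derived_at = NULL) {
  direction <- match.arg(direction)
  if (!gm$phased) stop("build_bifurcation_tree: phased input required")
  stopifnot(max_steps >= 1, core_allele %in% c(0L, 1L))
  j <- locus_index(gm, core_marker)
  if (is.null(populations)) populations <- gm$panel$populations$population
  ids <- unlist(lapply(populations, function(p) panel_individuals(gm$panel, p)))
  haps <- rbind(gm$hap1[ids, , drop = FALSE], gm$hap2[ids, , drop = FALSE])

  root <- !is.na(haps[, j]) & haps[, j] == core_allele
  if (!is.null(exclude_derived_at)) {
    for (l in exclude_derived_at) {
      k <- locus_index(gm, l)
      root <- root & !(is.na(haps[, k])) & haps[, k] != 1
    }
  }
  if (!any(root)) {
    stop(sprintf("no haplotype carries allele %d at %s (count 0)",
                 core_allele, core_marker))
  }
  haps <- haps[root, , drop = FALSE]

  pos <- gm$variants$ref_position
  core_pos <- pos[j]
  if (direction == "left") {
    steps <- order(pos, decreasing = TRUE)
    steps <- steps[pos[steps] < core_pos]
  } else {
    steps <- order(pos)
    steps <- steps[pos[steps] > core_pos]
  }
  steps <- utils::head(steps, max_steps)

  # drop haplotypes missing anywhere on the traversed flank
  if (length(steps)) {
    complete <- rowSums(is.na(haps[, steps, drop = FALSE])) == 0
    if (any(!complete)) {
      message(sprintf("bifurcation tree: dropped %d haplotype(s) with missing alleles in the flank",
                      sum(!complete)))
      haps <- haps[complete, , drop = FALSE]
      if (nrow(haps) == 0) stop("all haplotypes dropped for missingness (count 0)")
    }
  }

  nodes <- data.frame(id = 0L, parent = NA_integer_, depth = 0L,
                      allele = NA_integer_, count = nrow(haps))
  groups <- list(`0` = seq_len(nrow(haps)))  # node id -> haplotype rows
  next_id <- 1L
  for (d in seq_along(steps)) {
    marker <- steps[d]
    new_groups <- list()
    split_any <- FALSE
    for (gid in names(groups)) {
      g <- groups[[gid]]
      alleles <- haps[g, marker]
      for (a in sort(unique(alleles))) {
        sub <- g[alleles == a]
        nodes <- rbind(nodes, data.frame(id = next_id,
                                         parent = as.integer(gid),
                                         depth = d, allele = a,
                                         count = length(sub)))
        new_groups[[as.character(next_id)]] <- sub
        next_id <- next_id + 1L
      }
      if (length(unique(alleles)) > 1) split_any <- TRUE
    }
    groups <- new_groups
    if (all(lengths(groups) == 1L)) break  # all singletons: fully resolved
  }
  structure(list(core = list(marker = core_marker, allele = core_allele,
                             direction = direction),
                 n = nrow(haps), nodes = nodes,
                 markers = pos[utils::head(steps, max(nodes$depth))]),
            class = "bifurcation_tree")
}

#' Node counts per depth of a bifurcation tree
#'
#' @param tree a `bifurcation_tree`.
#' @return data frame: `depth`, `n_nodes` (distinct branches), `total`
#'   (haplotypes, which equals the root n at every depth).
#' @export
tree_depth_counts <- function(tree) {
  stopifnot(inherits(tree, "bifurcation_tree"))
  ag <- stats::aggregate(count ~ depth, data = tree$nodes, FUN = sum)
  nn <- stats::aggregate(id ~ depth, data = tree$nodes, FUN = length)
  data.frame(depth = ag$depth, n_nodes = nn$id, total = ag$count)
}

#' @export
print.bifurcation_tree <- function(x, ...) {
  cat(sprintf("bifurcation_tree: core %s allele %d, direction %s, n = %d, depth %d\n",
              x$core$marker, x$core$allele, x$core$direction, x$n,
              max(x$nodes$depth)))
  invisible(x)
}

#' Serialize a bifurcation tree as indented text
#'
#' @param x a `bifurcation_tree`.
#' @param ... unused.
#' @return character vector, one line per node, indentation = depth.
#' @export
format.bifurcation_tree <- function(x, ...) {
  n <- x$nodes
  lines <- character(0)
  emit <- function(id) {   # depth-first so indentation nests correctly
    i <- match(id, n$id)
    lab <- if (is.na(n$allele[i])) sprintf("root n=%d", n$count[i])
    else sprintf("allele %d n=%d", n$allele[i], n$count[i])
    lines <<- c(lines, paste0(strrep("  ", n$depth[i]), lab))
    for (kid in n$id[!is.na(n$parent) & n$parent == id]) emit(kid)
  }
  emit(n$id[is.na(n$parent)])
  lines
}

#' Write a bifurcation tree edge list as TSV
#'
#' @param tree a `bifurcation_tree`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bifurcation_tsv <- function(tree, path) {
  write_results(tree$nodes, path)
}

#' Plot a bifurcation tree
#'
#' Simple base-graphics rendering: depth on x, branches fanned on y, line
#' width proportional to the number of haplotypes sharing the branch.
#'
#' @param x a `bifurcation_tree`.
#' @param lwd_scale line width per haplotype (default scaled to root n).
#' @param ... passed to [graphics::plot()].
#' @export
plot.bifurcation_tree <- function(x, lwd_scale = 8 / x$n, ...) {
  n <- x$nodes
  # assign y coordinates: leaves evenly spaced, parents at child mean
  y <- rep(NA_real_, nrow(n))
  maxd <- max(n$depth)
  leaves <- which(!(n$id %in% n$parent))
  y[leaves] <- seq_along(leaves)
  for (d in rev(seq_len(maxd)) - 1L) {
    at <- which(n$depth == d & is.na(y))
    for (i in at) {
      kids <- which(n$parent == n$id[i])
      y[i] <- mean(y[kids])
    }
  }
  graphics::plot(NA, xlim = c(0, maxd), ylim = range(y, na.rm = TRUE),
                 xlab = "markers from core", ylab = "", yaxt = "n",
                 main = sprintf("core %s (%s), n = %d", x$core$marker,
                                x$core$direction, x$n), ...)
  for (i in which(!is.na(n$parent))) {
    p <- match(n$parent[i], n$id)
    graphics::segments(n$depth[p], y[p], n$depth[i], y[i],
                       lwd = pmax(0.5, n$count[i] * lwd_scale))
  }
  invisible(x)
}
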