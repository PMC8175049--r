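#' Write a result table as TSV
#'
#' All result writers emit tab-separated text with a mandatory header row.
#' Floating-point values are formatted at a fixed number of significant
#' digits so that identical inputs always produce byte-identical files.
#'
#' @param results a nonempty data frame.
#' @param path output file.
#' @param digits significant digits for numeric columns (default 6).
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, digits = 6) {
  if (!is.data.frame(results)) results <- as.data.frame(results)
  if (nrow(results) == 0 || ncol(results) == 0) {
    stop("write_results: refusing to write an empty result table")
  }
  out <- results
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      x <- signif(out[[j]], digits)
      s <- trimws(formatC(x, digits = digits, format = "g"))
      s[is.na(x)] <- "NA"
      out[[j]] <- s
    }
  }
  con <- file(path, open = "wb")  # binary: fixed newline across platforms
  on.exit(close(con))
  writeLines(paste(colnames(out), collapse = "\t"), con)
  body <- do.call(paste, c(lapply(out, as.character), sep = "\t"))
  if (length(body)) writeLines(body, con)
  invisible(path)
}

#' Read a per-population admixture-proportion table
#'
#' Plain TSV with columns `population` and `proportion` (a value in
#' \[0, 1\]); used as the second vector of [rank_correlation()]. No ancestry
#' inference is performed here — the proportions are an input.
#'
#' @param path TSV file.
#' @return data frame with columns `population`, `proportion`.
#' @export
read_admixture <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("population", "proportion") %in% colnames(tab))) {
    stop("admixture table needs columns 'population' and 'proportion'")
  }
  tab$proportion <- as.numeric(tab$proportion)
  if (any(is.na(tab$proportion)) ||
      any(tab$proportion < 0 | tab$proportion > 1)) {
    stop("admixture proportions must be numeric in [0, 1]")
  }
  tab
}

#' Read a key-value configuration file
#'
#' One `key = value` pair per line; `#` starts a comment; values are kept as
#' character and interpreted by the consuming stage. CLI flags override
#' config values.
#'
#' @param path config file.
#' @return named list of character values.
#' @export
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- vapply(kv, length, 1L) != 2L
  if (any(bad)) stop(sprintf("malformed config line: '%s'", lines[bad][1]))
  stats::setNames(lapply(kv, `[[`, 2), vapply(kv, `[[`, "", 1))
}
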