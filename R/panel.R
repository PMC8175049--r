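#' Construct a population panel
#'
#' Maps every sampled individual to exactly one population and keeps
#' per-population metadata (collective group, sample size, subsistence
#' pattern). The per-population `n` is always recomputed from the individual
#' assignments, so it cannot drift out of sync.
#'
#' @param individual_id character vector of unique sample identifiers.
#' @param population character vector, same length, population of each
#'   individual.
#' @param collective_group optional named character vector
#'   (population -> group label).
#' @param subsistence optional named character vector
#'   (population -> subsistence pattern).
#' @param language_family optional named character vector.
#' @return an object of class `population_panel` with elements `individuals`
#'   (data frame: individual_id, population) and `populations` (data frame:
#'   population, collective_group, n, subsistence, language_family).
#' @export
population_panel <- function(individual_id, population,
                             collective_group = NULL, subsistence = NULL,
                             language_family = NULL) {
  individual_id <- as.character(individual_id)
  population <- as.character(population)
  stopifnot(length(individual_id) == length(population))
  if (anyDuplicated(individual_id)) {
    stop("population_panel: individual ids must be unique (each individual maps to exactly one population)")
  }
  pops <- unique(population)
  meta <- function(v) {
    if (is.null(v)) return(rep(NA_character_, length(pops)))
    as.character(v[pops])
  }
  panel <- list(
    individuals = data.frame(individual_id = individual_id,
                             population = population,
                             stringsAsFactors = FALSE),
    populations = data.frame(
      population = pops,
      collective_group = meta(collective_group),
      n = as.integer(table(factor(population, levels = pops))),
      subsistence = meta(subsistence),
      language_family = meta(language_family),
      stringsAsFactors = FALSE
    )
  )
  class(panel) <- "population_panel"
  panel
}

#' @export
print.population_panel <- function(x, ...) {
  cat(sprintf("population_panel: %d individuals in %d populations\n",
              nrow(x$individuals), nrow(x$populations)))
  print.data.frame(x$populations, row.names = FALSE)
  invisible(x)
}

#' Individuals belonging to one population
#' @param panel a `population_panel`.
#' @param population population name.
#' @return character vector of individual ids.
#' @export
panel_individuals <- function(panel, population) {
  stopifnot(inherits(panel, "population_panel"))
  if (!population %in% panel$populations$population) {
    stop(sprintf("population '%s' not in panel", population))
  }
  panel$individuals$individual_id[panel$individuals$population == population]
}
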