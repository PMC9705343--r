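# Semi-quantitative histology: ordinal-to-percent conversion and
# area-weighted per-animal means, plus the synthetic score generator.

histoVariables <- c("fibrosis", "cx43_quantity", "cx43_polarity",
                    "viability", "vascularization")

#' Convert an ordinal histology level to a percentage
#'
#' The five-level semi-quantitative scale (+ to +++++) maps to 20, 40, 60,
#' 80 and 100%.
#'
#' @param level integer vector of levels in 1..5.
#' @return percentage values (20 * level).
#' @examples
#' ordinalToPercent(1:5)
#' @export
ordinalToPercent <- function(level) {
  if (any(!is.finite(level)) || any(level != round(level)) ||
      any(level < 1) || any(level > 5))
    stop("ordinal levels must be integers in 1..5")
  20 * level
}

#' Area-weighted per-animal histology means
#'
#' Each section's ordinal score is converted to a percentage and weighted
#' by the heterogeneous-tissue extent of the section, producing one mean
#' per animal and compartment:
#' `sum(extent_i * percent_i) / sum(extent_i)`.
#'
#' Extents may be given in mm^2 or as transparent-grid square counts
#' (0.64 mm^2 each); the weighting is invariant to the unit.
#'
#' @param sections data.frame with columns `animal_id`, `section_id`,
#'   `compartment` ("endo"/"epi"), `ht_extent`, `variable`,
#'   `ordinal_level`.
#' @param variable which variable to summarise (one of the five score
#'   variables).
#' @param extentUnit `"mm2"` (default) or `"squares"`.
#' @return data.frame with `animal_id`, `compartment`, `mean_percent`.
#' @export
weightedAnimalMean <- function(sections, variable,
                               extentUnit = c("mm2", "squares")) {
  extentUnit <- match.arg(extentUnit)
  sec <- sections[sections$variable == variable, , drop = FALSE]
  if (nrow(sec) == 0L) stop("no sections for variable ", variable)
  ext <- sec$ht_extent * if (extentUnit == "squares") 0.64 else 1
  if (any(ext <= 0)) stop("ht_extent must be > 0")
  pct <- ordinalToPercent(sec$ordinal_level)
  key <- paste(sec$animal_id, sec$compartment, sep = "\r")
  num <- tapply(ext * pct, key, sum)
  den <- tapply(ext, key, sum)
  if (any(den == 0)) stop("zero total extent")
  parts <- do.call(rbind, strsplit(names(num), "\r", fixed = TRUE))
  out <- data.frame(animal_id = parts[, 1L], compartment = parts[, 2L],
                    mean_percent = as.numeric(num / den),
                    row.names = NULL)
  out[order(out$animal_id, out$compartment), , drop = FALSE]
}

#' Synthetic histology specification
#'
#' Per-compartment ordinal level distributions for the five score
#' variables, with per-section heterogeneous-tissue extents.
#'
#' @slot animalId character id used in the output table.
#' @slot nSections number of sections (> 0).
#' @slot extentRange min/max section HT extent (mm^2, > 0).
#' @slot levelProbs named list: variable -> list(endo = p5, epi = p5),
#'   each a length-5 probability vector over levels 1..5.
#' @slot seed integer RNG seed.
#' @exportClass SyntheticHistoSpec
setClass("SyntheticHistoSpec",
  slots = c(animalId = "character", nSections = "integer",
            extentRange = "numeric", levelProbs = "list", seed = "integer"))

setValidity("SyntheticHistoSpec", function(object) {
  if (object@nSections < 1L) return("zero sections rejected")
  if (any(object@extentRange <= 0)) return("extents must be > 0")
  if (!all(histoVariables %in% names(object@levelProbs)))
    return("levelProbs must cover all five score variables")
  for (v in histoVariables) {
    lp <- object@levelProbs[[v]]
    if (!all(c("endo", "epi") %in% names(lp)))
      return("levelProbs entries need endo and epi vectors")
    if (any(vapply(lp, length, integer(1)) != 5L))
      return("level probabilities must have 5 entries (levels 1..5)")
  }
  TRUE
})

# uniform mid-scale defaults: most mass on levels 2-4
defaultLevelProbs <- function() {
  p <- c(0.1, 0.25, 0.3, 0.25, 0.1)
  stats::setNames(lapply(histoVariables, function(v)
    list(endo = p, epi = p)), histoVariables)
}

#' @describeIn SyntheticHistoSpec constructor.
#' @param animalId,nSections,extentRange,levelProbs,seed see slots.
#' @return a `SyntheticHistoSpec`.
#' @export
syntheticHistoSpec <- function(animalId = "A1", nSections = 6L,
                               extentRange = c(5, 50),
                               levelProbs = defaultLevelProbs(),
                               seed = 1L) {
  new("SyntheticHistoSpec", animalId = animalId,
      nSections = as.integer(nSections), extentRange = extentRange,
      levelProbs = levelProbs, seed = as.integer(seed))
}

#' Generate a synthetic histology score table
#'
#' One row per section, compartment and variable, in the long CSV layout
#' consumed by [weightedAnimalMean()]. Same seed, same table.
#'
#' @param spec a [SyntheticHistoSpec-class].
#' @return data.frame with `animal_id`, `section_id`, `compartment`,
#'   `ht_extent` (mm^2), `variable`, `ordinal_level`.
#' @export
generateHistology <- function(spec) {
  methods::validObject(spec)
  withSeed(spec@seed, {
    rows <- list()
    for (comp in c("endo", "epi")) {
      ext <- stats::runif(spec@nSections, spec@extentRange[1L],
                          spec@extentRange[2L])
      for (v in histoVariables) {
        lv <- sample.int(5L, spec@nSections, replace = TRUE,
                         prob = spec@levelProbs[[v]][[comp]])
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = spec@animalId,
          section_id = seq_len(spec@nSections),
          compartment = comp, ht_extent = ext,
          variable = v, ordinal_level = lv)
      }
    }
    do.call(rbind, rows)
  })
}
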