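#' @import methods
#' @importFrom Biostrings DNAStringSet width
NULL

#' DemographicModel: a multi-deme isolation-with-migration demography
#'
#' A rooted bifurcating deme tree with divergence times (generations before
#' present), diploid effective sizes for every extant and ancestral deme, and
#' an ordered list of migration epochs tiling \code{[0, rootTime]}. Each epoch
#' carries a backward per-generation migration matrix: entry \code{M[x, y]} is
#' the probability per generation that a lineage currently in deme \code{x}
#' traces back to deme \code{y}. Models are normally built with
#' \code{\link{buildScenario}}, which encodes one of the four canonical
#' gene-flow scenarios (zero, historical, constant, recent).
#'
#' @slot demeNames character, extant deme names (tree tip labels).
#' @slot allDemes character, extant followed by ancestral deme names.
#' @slot demeSizes named numeric, diploid N_e per deme (extant and ancestral).
#' @slot nodeTimes named numeric, origin time of each deme (0 for extant,
#'   the divergence time for ancestral demes).
#' @slot topology \code{ape::phylo} deme tree; node labels name ancestral
#'   demes.
#' @slot mergeTable data.frame with columns \code{time}, \code{a}, \code{b},
#'   \code{parent}: at \code{time}, demes \code{a} and \code{b} merge
#'   (backward in time) into \code{parent}.
#' @slot epochs list of \code{list(start, end, M)} tiling
#'   \code{[0, rootTime]}.
#' @slot scenario one of \code{"zero"}, \code{"historical"},
#'   \code{"constant"}, \code{"recent"}.
#' @slot rate2Nm numeric, the scaled population migration rate 2Nm implied by
#'   a nonzero matrix entry (split equally between the two directions).
#' @slot epochFraction numeric in (0,1), the fraction of each divergence
#'   interval over which historical/recent migration acts.
#'
#' @seealso \code{\link{buildScenario}}, \code{\link{simulateGenealogy}}
#' @export
setClass("DemographicModel",
  representation(
    demeNames = "character",
    allDemes = "character",
    demeSizes = "numeric",
    nodeTimes = "numeric",
    topology = "ANY",
    mergeTable = "data.frame",
    epochs = "list",
    scenario = "character",
    rate2Nm = "numeric",
    epochFraction = "numeric"
  )
)

setValidity("DemographicModel", function(object) {
  msg <- character()
  nd <- object@nodeTimes
  if (any(nd < 0)) msg <- c(msg, "divergence times must be >= 0")
  if (!setequal(names(object@demeSizes), object@allDemes))
    msg <- c(msg, "demeSizes must be named by every deme")
  if (any(object@demeSizes <= 0)) msg <- c(msg, "deme sizes must be positive")
  mt <- object@mergeTable
  if (nrow(mt) && is.unsorted(mt$time))
    msg <- c(msg, "merge events must be in increasing time order")
  rootT <- if (nrow(mt)) max(mt$time) else 0
  for (ep in object@epochs) {
    if (any(ep$M < 0)) msg <- c(msg, "migration rates must be >= 0")
    if (object@scenario == "zero" && any(ep$M != 0))
      msg <- c(msg, "scenario 'zero' admits no migration")
  }
  if (length(object@epochs)) {
    ss <- vapply(object@epochs, function(e) e$start, 0)
    ee <- vapply(object@epochs, function(e) e$end, 0)
    if (abs(ss[1]) > 1e-9 || abs(ee[length(ee)] - rootT) > 1e-9 * max(rootT, 1) ||
        (length(ss) > 1 && any(abs(ss[-1] - ee[-length(ee)]) > 1e-9 * max(rootT, 1))))
      msg <- c(msg, "epochs must tile [0, rootTime] without gaps or overlap")
  }
  if (!object@scenario %in% c("zero", "historical", "constant", "recent"))
    msg <- c(msg, "unknown scenario tag")
  if (length(msg)) msg else TRUE
})

#' HaplotypeAlignment: phased sequences for one locus
#'
#' Aligned haplotype sequences (one row per phased allele copy) with
#' individual, copy and deme labels. Sequences are stored as a
#' \code{Biostrings::DNAStringSet}; all members must share one width.
#'
#' @slot locusId single character, locus identifier.
#' @slot seqs \code{DNAStringSet}, one entry per haplotype.
#' @slot individual character, individual id per haplotype.
#' @slot copy integer in \{1, 2\}, allele copy per haplotype.
#' @slot deme character, deme (population or species) per haplotype.
#' @export
setClass("HaplotypeAlignment",
  representation(
    locusId = "character",
    seqs = "ANY",
    individual = "character",
    copy = "integer",
    deme = "character"
  )
)

setValidity("HaplotypeAlignment", function(object) {
  msg <- character()
  n <- length(object@seqs)
  if (length(object@individual) != n || length(object@copy) != n ||
      length(object@deme) != n)
    msg <- c(msg, "individual, copy and deme must each have one entry per haplotype")
  if (n && length(unique(Biostrings::width(object@seqs))) > 1)
    msg <- c(msg, "all haplotypes must have equal length (aligned)")
  if (n && !all(object@copy %in% c(1L, 2L)))
    msg <- c(msg, "copy labels must be 1 or 2")
  if (length(object@locusId) != 1) msg <- c(msg, "locusId must be a single string")
  if (length(msg)) msg else TRUE
})

#' GenotypeMatrix: diploid SNP calls with a population map
#'
#' Individuals by loci matrix of unordered diploid genotype calls
#' (\code{"A/G"} style, \code{NA} for missing) together with the
#' individual-to-population-to-species-to-lineage map.
#'
#' @slot calls character matrix, rows individuals, columns loci.
#' @slot popmap data.frame with columns \code{individual},
#'   \code{population}, \code{species}, \code{lineage}, one row per
#'   individual in matrix row order.
#' @export
setClass("GenotypeMatrix",
  representation(calls = "matrix", popmap = "data.frame")
)

setValidity("GenotypeMatrix", function(object) {
  msg <- character()
  pm <- object@popmap
  need <- c("individual", "population", "species", "lineage")
  if (!all(need %in% names(pm)))
    msg <- c(msg, "popmap needs columns individual, population, species, lineage")
  else {
    if (anyDuplicated(pm$individual))
      msg <- c(msg, "each individual must appear once in the popmap")
    if (nrow(pm) != nrow(object@calls))
      msg <- c(msg, "popmap must have one row per genotype matrix row")
    else if (!is.null(rownames(object@calls)) &&
             !identical(rownames(object@calls), as.character(pm$individual)))
      msg <- c(msg, "genotype row names must match popmap individuals in order")
    sp <- unique(pm[, c("population", "species")])
    if (anyDuplicated(sp$population))
      msg <- c(msg, "every population must map to exactly one species")
    ln <- unique(pm[, c("species", "lineage")])
    if (anyDuplicated(ln$species))
      msg <- c(msg, "every species must map to exactly one lineage")
  }
  ok <- is.na(object@calls) | grepl("^[ACGT]/[ACGT]$", object@calls)
  if (!all(ok)) msg <- c(msg, "genotype calls must look like 'A/G' or be NA")
  if (length(msg)) msg else TRUE
})

#' TraitMatrix: repeated floral measurements with population nesting
#'
#' Flower-level trait measurements, up to five replicate flowers per
#' individual, each individual mapped to a population (and optionally a
#' species/lineage).
#'
#' @slot data data.frame with columns \code{individual}, \code{population},
#'   \code{flower} plus one numeric column per trait.
#' @slot traitNames character, the trait column names.
#' @export
setClass("TraitMatrix",
  representation(data = "data.frame", traitNames = "character")
)

setValidity("TraitMatrix", function(object) {
  msg <- character()
  d <- object@data
  need <- c("individual", "population", "flower")
  if (!all(need %in% names(d)))
    msg <- c(msg, "trait data needs columns individual, population, flower")
  if (!all(object@traitNames %in% names(d)))
    msg <- c(msg, "traitNames must name columns of the data")
  else {
    raw <- object@traitNames[!startsWith(object@traitNames, "log_")]
    vals <- as.matrix(d[, raw, drop = FALSE])
    if (length(raw) && (!is.numeric(vals) || any(!is.na(vals) & vals <= 0)))
      msg <- c(msg, "all trait measurements must be positive numbers")
  }
  if (all(need %in% names(d))) {
    reps <- table(d$individual)
    if (length(reps) && max(reps) > 5)
      msg <- c(msg, "at most 5 flower replicates per individual")
    ip <- unique(d[, c("individual", "population")])
    if (anyDuplicated(ip$individual))
      msg <- c(msg, "every individual must map to exactly one population")
  }
  if (length(msg)) msg else TRUE
})
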