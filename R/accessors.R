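#' @include AllClasses.R
NULL

#' Accessors for speciflow data classes
#'
#' Small accessor generics: \code{demeNames} (extant deme labels of a
#' demographic model), \code{demeSizes}, \code{rootTime} (oldest divergence,
#' generations), \code{scenarioTag}, \code{popmap}, \code{traitNames},
#' \code{locusId} and \code{nHaplotypes}.
#'
#' @param x a speciflow object.
#' @return the corresponding slot value (see each generic's description).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("demeNames", function(x) standardGeneric("demeNames"))
#' @rdname accessors
#' @export
setMethod("demeNames", "DemographicModel", function(x) x@demeNames)

#' @rdname accessors
#' @export
setGeneric("demeSizes", function(x) standardGeneric("demeSizes"))
#' @rdname accessors
#' @export
setMethod("demeSizes", "DemographicModel", function(x) x@demeSizes)

#' @rdname accessors
#' @export
setGeneric("rootTime", function(x) standardGeneric("rootTime"))
#' @rdname accessors
#' @export
setMethod("rootTime", "DemographicModel", function(x)
  if (nrow(x@mergeTable)) max(x@mergeTable$time) else 0)

#' @rdname accessors
#' @export
setGeneric("scenarioTag", function(x) standardGeneric("scenarioTag"))
#' @rdname accessors
#' @export
setMethod("scenarioTag", "DemographicModel", function(x) x@scenario)

#' @rdname accessors
#' @export
setGeneric("migrationEpochs", function(x) standardGeneric("migrationEpochs"))
#' @rdname accessors
#' @export
setMethod("migrationEpochs", "DemographicModel", function(x) x@epochs)

#' @rdname accessors
#' @export
setGeneric("popmap", function(x) standardGeneric("popmap"))
#' @rdname accessors
#' @export
setMethod("popmap", "GenotypeMatrix", function(x) x@popmap)

#' @rdname accessors
#' @export
setGeneric("genotypeCalls", function(x) standardGeneric("genotypeCalls"))
#' @rdname accessors
#' @export
setMethod("genotypeCalls", "GenotypeMatrix", function(x) x@calls)

#' @rdname accessors
#' @export
setGeneric("traitNames", function(x) standardGeneric("traitNames"))
#' @rdname accessors
#' @export
setMethod("traitNames", "TraitMatrix", function(x) x@traitNames)

#' @rdname accessors
#' @export
setGeneric("traitData", function(x) standardGeneric("traitData"))
#' @rdname accessors
#' @export
setMethod("traitData", "TraitMatrix", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("locusId", function(x) standardGeneric("locusId"))
#' @rdname accessors
#' @export
setMethod("locusId", "HaplotypeAlignment", function(x) x@locusId)

#' @rdname accessors
#' @export
setGeneric("haplotypeDemes", function(x) standardGeneric("haplotypeDemes"))
#' @rdname accessors
#' @export
setMethod("haplotypeDemes", "HaplotypeAlignment", function(x) x@deme)

#' @rdname accessors
#' @export
setGeneric("nHaplotypes", function(x) standardGeneric("nHaplotypes"))
#' @rdname accessors
#' @export
setMethod("nHaplotypes", "HaplotypeAlignment", function(x) length(x@seqs))

#' Character-matrix view of an alignment
#'
#' @param x a \code{HaplotypeAlignment}.
#' @param ... unused.
#' @return character matrix, haplotypes by sites, with row names
#'   \code{<deme>_<individual>_<copy>}.
#' @export
setMethod("as.matrix", "HaplotypeAlignment", function(x, ...) {
  m <- as.matrix(x@seqs)
  rownames(m) <- haplotypeLabels(x)
  m
})

#' @rdname accessors
#' @export
setGeneric("haplotypeLabels", function(x) standardGeneric("haplotypeLabels"))
#' @rdname accessors
#' @export
setMethod("haplotypeLabels", "HaplotypeAlignment", function(x)
  paste(x@individual, x@copy, sep = "_"))

setMethod("show", "DemographicModel", function(object) {
  cat("DemographicModel:", length(object@demeNames), "extant demes (",
      paste(object@demeNames, collapse = ", "), ")\n")
  cat("  scenario:", object@scenario,
      "| rate 2Nm:", object@rate2Nm,
      "| epoch fraction:", object@epochFraction, "\n")
  cat("  root time:", format(rootTime(object), big.mark = ","),
      "generations;", length(object@epochs), "migration epoch(s)\n")
  invisible(NULL)
})

setMethod("show", "HaplotypeAlignment", function(object) {
  w <- if (length(object@seqs)) Biostrings::width(object@seqs)[1] else 0
  cat("HaplotypeAlignment '", object@locusId, "': ", length(object@seqs),
      " haplotypes x ", w, " bp, ", length(unique(object@deme)),
      " deme(s)\n", sep = "")
  invisible(NULL)
})

setMethod("show", "GenotypeMatrix", function(object) {
  cat("GenotypeMatrix:", nrow(object@calls), "individuals x",
      ncol(object@calls), "loci;",
      length(unique(object@popmap$population)), "populations,",
      length(unique(object@popmap$species)), "species,",
      length(unique(object@popmap$lineage)), "lineages\n")
  miss <- mean(is.na(object@calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(NULL)
})

setMethod("show", "TraitMatrix", function(object) {
  cat("TraitMatrix:", nrow(object@data), "flower measurements,",
      length(unique(object@data$individual)), "individuals,",
      length(unique(object@data$population)), "populations;",
      length(object@traitNames), "traits (",
      paste(object@traitNames, collapse = ", "), ")\n")
  invisible(NULL)
})
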