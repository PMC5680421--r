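#' @include abc.R
NULL

# min inter-group p-distance within one alignment; NA if a side is absent
minInterDist <- function(aln, idx1, idx2) {
  if (!length(idx1) || !length(idx2)) return(NA_real_)
  D <- seqDistMatrix(aln, scale = "persite")
  min(D[idx1, idx2])
}

#' Posterior-predictive minimum-distance test of hybridization
#'
#' Tests whether the minimum sequence distance observed between two species
#' is smaller than expected under incomplete lineage sorting alone. For each
#' locus, the observed minimum uncorrected p-distance between the species'
#' haplotypes is compared to a null distribution of minima obtained by
#' simulating datasets under demographic models with no gene flow between
#' the pair (parameters drawn across the supplied model sample, emulating
#' posterior predictive simulation). A small observed minimum - smaller than
#' nearly all simulated minima - indicates hybridization.
#'
#' The one-sided p-value per locus is
#' \code{#\{simulated minima <= observed\} / (nSims + 1)}; an observed
#' minimum above all simulated minima therefore gives p = nSims/(nSims+1).
#' A combined minimum-of-minima variant across loci is reported alongside
#' the per-locus values.
#'
#' @param observed list of \code{HaplotypeAlignment}.
#' @param pair character vector of two species names.
#' @param nullModels a \code{DemographicModel} with zero migration between
#'   the pair, or a list of such models (a parameter sample); each
#'   simulation draws one model uniformly.
#' @param theta per-locus population mutation rate(s) used for simulation:
#'   scalar or one value per locus.
#' @param nSims number of simulated datasets (default 1000).
#' @param speciesMap optional named character vector mapping deme labels of
#'   the alignments to species; default treats deme labels as species.
#' @param seed optional RNG seed.
#' @return object of class \code{"minDistanceTest"}: data.frame \code{perLocus}
#'   with locus, observed minimum, p-value; \code{combined} (observed
#'   minimum over loci, its p-value); \code{nSims}.
#' @export
minDistanceTest <- function(observed, pair, nullModels, theta, nSims = 1000,
                            speciesMap = NULL, seed = NULL) {
  abort_if(length(pair) != 2, "pair must name exactly two species")
  if (is(nullModels, "DemographicModel")) nullModels <- list(nullModels)
  for (m in nullModels) {
    for (ep in m@epochs) {
      i <- match(pair, m@allDemes)
      abort_if(!any(is.na(i)) && (ep$M[i[1], i[2]] > 0 || ep$M[i[2], i[1]] > 0),
               "null models must have zero migration between the tested pair")
    }
  }
  if (is(observed, "HaplotypeAlignment")) observed <- list(observed)
  nLoci <- length(observed)
  theta <- rep(theta, length.out = nLoci)

  spOf <- function(aln) {
    if (is.null(speciesMap)) aln@deme else unname(speciesMap[aln@deme])
  }
  obsMin <- numeric(nLoci)
  nPer <- matrix(0L, nLoci, 2)
  lens <- integer(nLoci)
  usable <- logical(nLoci)
  for (l in seq_len(nLoci)) {
    sp <- spOf(observed[[l]])
    i1 <- which(sp == pair[1]); i2 <- which(sp == pair[2])
    lens[l] <- if (length(observed[[l]]@seqs)) Biostrings::width(observed[[l]]@seqs)[1] else 0L
    if (!length(i1) || !length(i2)) {
      warning("species pair absent from locus ", observed[[l]]@locusId,
              "; locus skipped")
      obsMin[l] <- NA_real_
      next
    }
    usable[l] <- TRUE
    obsMin[l] <- minInterDist(observed[[l]], i1, i2)
    nPer[l, ] <- c(length(i1), length(i2))
  }
  abort_if(!any(usable), "no locus contains both species")

  # simulated null minima: rows sims, cols loci
  simMin <- withSeed(seed, {
    out <- matrix(NA_real_, nSims, nLoci)
    cms <- lapply(nullModels, function(m)
      lapply(seq_len(nLoci), function(l) {
        if (!usable[l]) return(NULL)
        ss <- setNames(as.integer(nPer[l, ]), pair)
        compileModel(m, ss)
      }))
    refN <- vapply(nullModels, function(m) mean(m@demeSizes[m@demeNames]), 0)
    for (s in seq_len(nSims)) {
      mi <- if (length(nullModels) > 1) sample.int(length(nullModels), 1) else 1L
      for (l in which(usable)) {
        cm <- cms[[mi]][[l]]
        u <- theta[l] / (4 * refN[mi])
        D <- .sim_locus_dist_cpp(cm$tipDeme, cm$nDemes, cm$N, cm$mergeTime,
                                 cm$mergeA, cm$mergeB, cm$mergeP, cm$epStart,
                                 cm$epEnd, cm$epM, u)
        g1 <- which(cm$demeOfTip == pair[1])
        g2 <- which(cm$demeOfTip == pair[2])
        out[s, l] <- min(D[g1, g2]) / max(lens[l], 1)
      }
    }
    out
  })

  pLocus <- vapply(seq_len(nLoci), function(l) {
    if (!usable[l]) return(NA_real_)
    sum(simMin[, l] <= obsMin[l] + 1e-12) / (nSims + 1)
  }, 0)
  combinedObs <- min(obsMin[usable])
  combinedSim <- apply(simMin[, usable, drop = FALSE], 1, min)
  pComb <- sum(combinedSim <= combinedObs + 1e-12) / (nSims + 1)

  structure(list(
    perLocus = data.frame(
      locus = vapply(observed, locusId, ""),
      observedMin = obsMin, pvalue = pLocus),
    combined = list(observedMin = combinedObs, pvalue = pComb),
    pair = pair, nSims = nSims), class = "minDistanceTest")
}

#' @export
print.minDistanceTest <- function(x, ...) {
  cat("Minimum-distance hybridization test:", x$pair[1], "vs", x$pair[2],
      "(", x$nSims, "null simulations )\n")
  print(x$perLocus, row.names = FALSE)
  cat(sprintf("combined min-of-minima: %.5f (P = %.4g)\n",
              x$combined$observedMin, x$combined$pvalue))
  invisible(x)
}
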