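#' @include amova.R
NULL

# Phi_ST between two sets of rows of a squared-distance matrix
phiSTpair <- function(D2, idx1, idx2) {
  idx <- c(idx1, idx2)
  grp <- c(rep("a", length(idx1)), rep("b", length(idx2)))
  comp <- amovaComponents(D2[idx, idx, drop = FALSE], grp)
  unname(comp$phi["PhiST"])
}

# Weir & Cockerham (1984) per-locus variance components a, b, c for one
# biallelic locus across r populations. freq/het/sample sizes from dosages.
wcComponentsLocus <- function(dosage, popFactor) {
  pops <- levels(popFactor)
  ni <- pi <- hi <- numeric(length(pops))
  for (k in seq_along(pops)) {
    x <- dosage[popFactor == pops[k]]
    x <- x[!is.na(x)]
    ni[k] <- length(x)
    if (length(x)) {
      pi[k] <- mean(x) / 2
      hi[k] <- mean(x == 1)
    }
  }
  keep <- ni > 0
  ni <- ni[keep]; pi <- pi[keep]; hi <- hi[keep]
  r <- length(ni)
  if (r < 2 || sum(ni) == 0) return(c(a = NA, b = NA, c = NA))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  pbar <- sum(ni * pi) / (r * nbar)
  s2 <- sum(ni * (pi - pbar)^2) / ((r - 1) * nbar)
  hbar <- sum(ni * hi) / (r * nbar)
  if (nbar <= 1 || nc == 0) return(c(a = NA, b = NA, c = NA))
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  c(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_ST components per locus
#'
#' @param gm a \code{GenotypeMatrix}.
#' @param populations unit label per individual (defaults to the popmap
#'   population column).
#' @return matrix with one row per locus and columns \code{a}, \code{b},
#'   \code{c}; the multilocus theta estimate is
#'   \code{sum(a) / sum(a + b + c)} over informative loci.
#' @export
wcComponents <- function(gm, populations = NULL) {
  if (is.null(populations)) populations <- gm@popmap$population
  popFactor <- factor(populations)
  dm <- dosageMatrix(gm)$dosage
  t(vapply(seq_len(ncol(dm)), function(l) wcComponentsLocus(dm[, l], popFactor),
           c(a = 0, b = 0, c = 0)))
}

wcTheta <- function(comp) {
  ok <- rowSums(is.na(comp)) == 0 & rowSums(comp) != 0
  sum(comp[ok, "a"]) / sum(comp[ok, ])
}

#' Pairwise F_ST between populations, species or lineages
#'
#' For sequence data, a distance-based Phi_ST from a two-unit AMOVA on
#' pairwise difference counts (pairwise deletion, loci summed) - the
#' convention of distance-matrix AMOVA software. For SNP genotype data, the
#' Weir-Cockerham theta averaged over loci. P-values come from permuting
#' unit labels among the pair's samples; \code{(hits + 1)/(nPerm + 1)}.
#'
#' @param data list of \code{HaplotypeAlignment}, a single alignment, or a
#'   \code{GenotypeMatrix}.
#' @param units unit label per haplotype/individual. Defaults to deme labels
#'   (alignments) or popmap populations (genotypes); alternatively the name
#'   of a popmap column (\code{"population"}, \code{"species"},
#'   \code{"lineage"}) for genotype data.
#' @param nPerm permutations per pair (default 1000; 0 disables).
#' @param seed optional RNG seed.
#' @return object of class \code{"fstMatrix"}: list with \code{fst}
#'   (symmetric matrix, diagonal 0; negative estimates kept), \code{pvalues},
#'   \code{estimator} (\code{"PhiST"} or \code{"WC"}), and \code{n} (samples
#'   per unit). Units with a single sample give NA rows (flagged pairs).
#' @export
pairwiseFst <- function(data, units = NULL, nPerm = 1000, seed = NULL) {
  if (is(data, "GenotypeMatrix")) {
    if (is.character(units) && length(units) == 1 &&
        units %in% c("population", "species", "lineage"))
      units <- data@popmap[[units]]
    if (is.null(units)) units <- data@popmap$population
    return(pairwiseFstSNP(data, units, nPerm, seed))
  }
  prep <- amovaDistance(data, units)
  D2 <- prep$D^2
  units <- prep$populations
  uu <- sort(unique(units))
  abort_if(length(uu) < 2, "need at least 2 units")
  fst <- pv <- matrix(NA_real_, length(uu), length(uu), dimnames = list(uu, uu))
  diag(fst) <- 0
  counts <- table(units)[uu]
  withSeed(seed, {
    for (i in seq_len(length(uu) - 1)) for (j in seq(i + 1, length(uu))) {
      i1 <- which(units == uu[i]); i2 <- which(units == uu[j])
      if (length(i1) < 2 || length(i2) < 2) next # flagged: stays NA
      obs <- phiSTpair(D2, i1, i2)
      fst[i, j] <- fst[j, i] <- obs
      if (nPerm > 0) {
        idx <- c(i1, i2)
        hits <- 0L
        for (b in seq_len(nPerm)) {
          per <- sample(idx)
          ph <- phiSTpair(D2, per[seq_along(i1)], per[-seq_along(i1)])
          if (ph >= obs - 1e-12) hits <- hits + 1L
        }
        pv[i, j] <- pv[j, i] <- (hits + 1) / (nPerm + 1)
      }
    }
  })
  structure(list(fst = fst, pvalues = pv, estimator = "PhiST",
                 n = as.integer(counts)), class = "fstMatrix")
}

pairwiseFstSNP <- function(gm, units, nPerm, seed) {
  uu <- sort(unique(units))
  abort_if(length(uu) < 2, "need at least 2 units")
  dm <- dosageMatrix(gm)$dosage
  fst <- pv <- matrix(NA_real_, length(uu), length(uu), dimnames = list(uu, uu))
  diag(fst) <- 0
  thetaOf <- function(dsub, fac) {
    comp <- t(vapply(seq_len(ncol(dsub)),
                     function(l) wcComponentsLocus(dsub[, l], fac),
                     c(a = 0, b = 0, c = 0)))
    wcTheta(comp)
  }
  withSeed(seed, {
    for (i in seq_len(length(uu) - 1)) for (j in seq(i + 1, length(uu))) {
      i1 <- which(units == uu[i]); i2 <- which(units == uu[j])
      if (length(i1) < 2 || length(i2) < 2) next
      idx <- c(i1, i2)
      fac <- factor(c(rep("a", length(i1)), rep("b", length(i2))))
      dsub <- dm[idx, , drop = FALSE]
      obs <- thetaOf(dsub, fac)
      fst[i, j] <- fst[j, i] <- obs
      if (nPerm > 0) {
        hits <- 0L
        for (b in seq_len(nPerm)) {
          ph <- thetaOf(dsub[sample(nrow(dsub)), , drop = FALSE], fac)
          if (!is.na(ph) && ph >= obs - 1e-12) hits <- hits + 1L
        }
        pv[i, j] <- pv[j, i] <- (hits + 1) / (nPerm + 1)
      }
    }
  })
  structure(list(fst = fst, pvalues = pv, estimator = "WC",
                 n = as.integer(table(units)[uu])), class = "fstMatrix")
}

#' @export
print.fstMatrix <- function(x, ...) {
  cat("Pairwise F_ST (", x$estimator, " estimator)\n", sep = "")
  print(round(x$fst, 4))
  off <- x$fst[upper.tri(x$fst)]
  cat(sprintf("mean = %.4f, range = [%.4f, %.4f]\n",
              mean(off, na.rm = TRUE), min(off, na.rm = TRUE),
              max(off, na.rm = TRUE)))
  invisible(x)
}

#' Multilocus global Weir-Cockerham theta
#'
#' @inheritParams wcComponents
#' @return scalar theta over all populations and loci.
#' @export
globalFst <- function(gm, populations = NULL) {
  wcTheta(wcComponents(gm, populations))
}
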