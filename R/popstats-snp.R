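#' @include AllClasses.R
NULL

# split "A/G" calls into a 2*n x L allele matrix (characters, NA for missing)
alleleMatrix <- function(gm) {
  calls <- gm@calls
  a1 <- substr(calls, 1, 1); a2 <- substr(calls, 3, 3)
  a1[is.na(calls)] <- NA; a2[is.na(calls)] <- NA
  rbind(matrix(a1, nrow(calls), ncol(calls)),
        matrix(a2, nrow(calls), ncol(calls)))
}

#' Per-locus minor allele frequency
#'
#' MAF computed on observed alleles only (missing calls excluded).
#'
#' @param gm a \code{\linkS4class{GenotypeMatrix}}.
#' @return numeric vector in [0, 0.5], one entry per locus (NaN for loci
#'   with no observed calls).
#' @export
mafs <- function(gm) {
  al <- alleleMatrix(gm)
  apply(al, 2, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) return(NaN)
    tab <- table(x)
    if (length(tab) < 2) return(0)
    min(tab) / sum(tab)
  })
}

#' Per-individual missingness fraction
#'
#' @param gm a \code{GenotypeMatrix}.
#' @return numeric vector, fraction of missing calls per individual.
#' @export
missingness <- function(gm) rowMeans(is.na(gm@calls))

#' Filter a SNP genotype matrix
#'
#' Two-stage filter: loci with minor allele frequency below \code{mafMin}
#' are removed first; then individuals whose missingness over the retained
#' loci exceeds \code{missingMax} are removed. The filter is idempotent
#' under fixed thresholds when the data are unchanged.
#'
#' @param gm a \code{\linkS4class{GenotypeMatrix}}.
#' @param mafMin minimum minor allele frequency to keep a locus
#'   (default 0.01).
#' @param missingMax maximum tolerated per-individual missing fraction over
#'   retained loci (default 0.10).
#' @return filtered \code{GenotypeMatrix}; \code{attr(x, "filterReport")}
#'   records the counts removed at each stage.
#' @export
filterGenotypes <- function(gm, mafMin = 0.01, missingMax = 0.10) {
  keepLoci <- which(mafs(gm) >= mafMin)
  abort_if(length(keepLoci) == 0, "all loci removed by the MAF filter")
  calls <- gm@calls[, keepLoci, drop = FALSE]
  missInd <- rowMeans(is.na(calls))
  keepInd <- which(missInd <= missingMax)
  abort_if(length(keepInd) == 0, "all individuals removed by the missingness filter")
  out <- new("GenotypeMatrix", calls = calls[keepInd, , drop = FALSE],
             popmap = gm@popmap[keepInd, , drop = FALSE])
  attr(out, "filterReport") <- list(
    lociIn = ncol(gm@calls), lociKept = length(keepLoci),
    individualsIn = nrow(gm@calls), individualsKept = length(keepInd),
    mafMin = mafMin, missingMax = missingMax)
  out
}

#' SNP diversity statistics
#'
#' Per-locus allele counts and heterozygosities averaged over loci:
#' A (number of alleles), Ae = 1/sum(p^2) (effective alleles),
#' Ho (observed heterozygosity, missing calls excluded),
#' He = 1 - sum(p^2) (expected heterozygosity from sample frequencies),
#' Fis = (He - Ho)/He averaged over loci with He > 0, and PPL, the
#' percentage of loci polymorphic in the stratum.
#'
#' @param gm a \code{GenotypeMatrix}.
#' @param stratum \code{NULL} for all individuals, or value(s) of the
#'   \code{by} column selecting a subset.
#' @param by popmap column defining strata: \code{"population"},
#'   \code{"species"} or \code{"lineage"}.
#' @return named list: n, PPL, A, Ae, Ho, He, Fis.
#' @export
snpDiversity <- function(gm, stratum = NULL,
                         by = c("population", "species", "lineage")) {
  by <- match.arg(by)
  idx <- if (is.null(stratum)) seq_len(nrow(gm@calls)) else
    which(gm@popmap[[by]] %in% stratum)
  abort_if(length(idx) < 2, "stratum must contain at least 2 individuals")
  calls <- gm@calls[idx, , drop = FALSE]
  a1 <- matrix(substr(calls, 1, 1), nrow(calls), ncol(calls))
  a2 <- matrix(substr(calls, 3, 3), nrow(calls), ncol(calls))
  perLocus <- lapply(seq_len(ncol(calls)), function(l) {
    obs <- which(!is.na(calls[, l]))
    if (!length(obs)) return(list(A = NA, Ae = NA, Ho = NA, He = NA, Fis = NA))
    al <- c(a1[obs, l], a2[obs, l])
    p <- table(al) / length(al)
    A <- length(p)
    Ae <- 1 / sum(p^2)
    Ho <- mean(a1[obs, l] != a2[obs, l])
    He <- 1 - sum(p^2)
    Fis <- if (He > 0) (He - Ho) / He else NA_real_
    list(A = A, Ae = Ae, Ho = Ho, He = He, Fis = Fis)
  })
  g <- function(f) vapply(perLocus, function(x) as.numeric(x[[f]]), 0)
  A <- g("A")
  list(n = length(idx),
       PPL = 100 * mean(A >= 2, na.rm = TRUE),
       A = mean(A, na.rm = TRUE),
       Ae = mean(g("Ae"), na.rm = TRUE),
       Ho = mean(g("Ho"), na.rm = TRUE),
       He = mean(g("He"), na.rm = TRUE),
       Fis = mean(g("Fis"), na.rm = TRUE))
}

#' @rdname snpDiversity
#' @return \code{snpDiversityTable}: data.frame with one row per stratum.
#' @export
snpDiversityTable <- function(gm, by = c("population", "species", "lineage")) {
  by <- match.arg(by)
  units <- sort(unique(gm@popmap[[by]]))
  do.call(rbind, lapply(units, function(u) {
    st <- snpDiversity(gm, stratum = u, by = by)
    data.frame(stratum = u, n = st$n, PPL = st$PPL, A = st$A, Ae = st$Ae,
               Ho = st$Ho, He = st$He, Fis = st$Fis)
  }))
}

# 0/1/2 dosage matrix of the (locus-wise) first-seen allele + allele labels
dosageMatrix <- function(gm) {
  calls <- gm@calls
  n <- nrow(calls); L <- ncol(calls)
  a1 <- matrix(substr(calls, 1, 1), n, L)
  a2 <- matrix(substr(calls, 3, 3), n, L)
  dos <- matrix(NA_real_, n, L, dimnames = dimnames(calls))
  ref <- character(L)
  for (l in seq_len(L)) {
    al <- c(a1[, l], a2[, l])
    obs <- al[!is.na(al)]
    if (!length(obs)) next
    ref[l] <- names(sort(table(obs), decreasing = TRUE))[1]
    dos[, l] <- (a1[, l] == ref[l]) + (a2[, l] == ref[l])
  }
  list(dosage = dos, ref = ref)
}
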