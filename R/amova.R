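#' @include popstats-seq.R popstats-snp.R
NULL

# sum of squared distances within an index set, divided by set size
ssdWithin <- function(D2, idx) {
  if (length(idx) < 2) return(0)
  sum(D2[idx, idx][upper.tri(matrix(0, length(idx), length(idx)))]) / length(idx)
}

# Core variance-component decomposition on a squared-distance matrix.
# groups: population of each row; clusters: optional population -> group map
# (named character) for the 2-level design.
amovaComponents <- function(D2, groups, clusters = NULL) {
  N <- nrow(D2)
  pops <- unique(groups)
  P <- length(pops)
  idxPop <- lapply(pops, function(p) which(groups == p))
  nP <- lengths(idxPop)
  ssdTot <- ssdWithin(D2, seq_len(N))
  ssdWP <- sum(vapply(idxPop, function(i) ssdWithin(D2, i), 0))
  if (is.null(clusters)) {
    dfAP <- P - 1
    dfWP <- N - P
    ssdAP <- ssdTot - ssdWP
    msAP <- ssdAP / dfAP
    msWP <- if (dfWP > 0) ssdWP / dfWP else NA_real_
    n0 <- (N - sum(nP^2) / N) / (P - 1)
    sigW <- msWP
    sigA <- (msAP - msWP) / n0
    tot <- sigA + sigW
    list(levels = c("among populations", "within populations"),
         df = c(dfAP, dfWP), SSD = c(ssdAP, ssdWP),
         sigma2 = c(sigA, sigW), percent = 100 * c(sigA, sigW) / tot,
         phi = c(PhiST = sigA / tot))
  } else {
    grpOf <- clusters[as.character(groups)]
    grps <- unique(unname(clusters[as.character(pops)]))
    G <- length(grps)
    abort_if(G < 2, "2-level AMOVA needs at least 2 groups")
    idxGrp <- lapply(grps, function(g) which(grpOf == g))
    nG <- lengths(idxGrp)
    ssdGrpTot <- sum(vapply(idxGrp, function(i) ssdWithin(D2, i), 0))
    ssdAG <- ssdTot - ssdGrpTot
    ssdAPWG <- ssdGrpTot - ssdWP
    dfAG <- G - 1
    dfAPWG <- P - G
    dfWP <- N - P
    msAG <- ssdAG / dfAG
    msAPWG <- if (dfAPWG > 0) ssdAPWG / dfAPWG else NA_real_
    msWP <- if (dfWP > 0) ssdWP / dfWP else NA_real_
    # unbalanced-design coefficients (Excoffier's n, n', n'')
    grpOfPop <- unname(clusters[as.character(pops)])
    sumNp2byG <- vapply(grps, function(g)
      sum(nP[grpOfPop == g]^2) / sum(nP[grpOfPop == g]), 0)
    n1 <- (N - sum(sumNp2byG)) / (P - G)
    n2 <- (sum(sumNp2byG) - sum(nP^2) / N) / (G - 1)
    n3 <- (N - sum(nG^2) / N) / (G - 1)
    sigC <- msWP
    sigB <- if (dfAPWG > 0) (msAPWG - sigC) / n1 else 0
    sigA <- (msAG - sigC - n2 * sigB) / n3
    tot <- sigA + sigB + sigC
    list(levels = c("among groups", "among populations within groups",
                    "within populations"),
         df = c(dfAG, dfAPWG, dfWP), SSD = c(ssdAG, ssdAPWG, ssdWP),
         sigma2 = c(sigA, sigB, sigC),
         percent = 100 * c(sigA, sigB, sigC) / tot,
         phi = c(PhiCT = sigA / tot,
                 PhiSC = sigB / (sigB + sigC),
                 PhiST = (sigA + sigB) / tot))
  }
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Excoffier-style variance decomposition on squared pairwise distances:
#' one level (among / within populations) or two levels (among groups,
#' among populations within groups, within populations). Significance is
#' assessed by permutation with level-appropriate schemes: whole
#' populations permuted among groups (Phi_CT), individuals among
#' populations within their group (Phi_SC), and individuals among all
#' populations (Phi_ST).
#'
#' Negative variance components are reported as computed; a clamped view
#' (components floored at 0, percentages renormalised) is attached as
#' \code{$clamped}.
#'
#' @param data list of \code{HaplotypeAlignment} (sequence AMOVA on
#'   difference counts summed over loci), a \code{GenotypeMatrix} (allele
#'   mismatch distances), or a precomputed distance matrix (not squared).
#' @param populations population label per row of the distance matrix; for
#'   alignments defaults to the haplotype deme labels, for genotype
#'   matrices to the popmap population column.
#' @param groups optional named character vector mapping population ->
#'   group for the 2-level design.
#' @param nPerm number of permutations (default 1000); 0 skips testing.
#' @param seed optional RNG seed for the permutations.
#' @return object of class \code{"amovaResult"}: a list with \code{table}
#'   (data.frame of df, SSD, variance components, percentages), \code{phi},
#'   \code{pvalues}, and \code{clamped}.
#' @export
amova <- function(data, populations = NULL, groups = NULL, nPerm = 1000,
                  seed = NULL) {
  prep <- amovaDistance(data, populations)
  D2 <- prep$D^2
  populations <- prep$populations
  tab <- table(populations)
  abort_if(any(tab < 1), "empty population")
  comp <- amovaComponents(D2, populations, groups)
  pv <- rep(NA_real_, length(comp$phi))
  names(pv) <- names(comp$phi)
  if (nPerm > 0) {
    pv <- withSeed(seed, amovaPermute(D2, populations, groups, comp, nPerm))
  }
  cl <- pmax(comp$sigma2, 0)
  res <- list(
    table = data.frame(level = comp$levels, df = comp$df, SSD = comp$SSD,
                       sigma2 = comp$sigma2, percent = comp$percent),
    phi = comp$phi, pvalues = pv,
    clamped = data.frame(level = comp$levels, sigma2 = cl,
                         percent = 100 * cl / sum(cl)),
    nPerm = nPerm)
  class(res) <- "amovaResult"
  res
}

amovaPermute <- function(D2, populations, groups, comp, nPerm) {
  obs <- comp$phi
  hits <- setNames(rep(0L, length(obs)), names(obs))
  pops <- unique(populations)
  for (b in seq_len(nPerm)) {
    # Phi_ST: individuals among all populations
    permAll <- sample(populations)
    cAll <- amovaComponents(D2, permAll, groups)
    if (cAll$phi[["PhiST"]] >= obs[["PhiST"]] - 1e-12)
      hits["PhiST"] <- hits["PhiST"] + 1L
    if (!is.null(groups)) {
      # Phi_CT: whole populations among groups
      permG <- setNames(sample(unname(groups[as.character(pops)])), pops)
      cG <- amovaComponents(D2, populations, permG)
      if (cG$phi[["PhiCT"]] >= obs[["PhiCT"]] - 1e-12)
        hits["PhiCT"] <- hits["PhiCT"] + 1L
      # Phi_SC: individuals among populations within their group
      permW <- populations
      for (g in unique(unname(groups[as.character(pops)]))) {
        idx <- which(unname(groups[as.character(populations)]) == g)
        permW[idx] <- sample(populations[idx])
      }
      cW <- amovaComponents(D2, permW, groups)
      if (cW$phi[["PhiSC"]] >= obs[["PhiSC"]] - 1e-12)
        hits["PhiSC"] <- hits["PhiSC"] + 1L
    }
  }
  (hits + 1) / (nPerm + 1)
}

# distance matrix + population labels from the accepted data types
amovaDistance <- function(data, populations) {
  if (is.matrix(data) && is.numeric(data)) {
    abort_if(is.null(populations), "populations required with a distance matrix")
    return(list(D = data, populations = populations))
  }
  if (is(data, "GenotypeMatrix")) {
    D <- snpDistMatrix(data)
    if (is.null(populations)) populations <- data@popmap$population
    return(list(D = D, populations = populations))
  }
  if (is(data, "HaplotypeAlignment")) data <- list(data)
  if (is.list(data) && all(vapply(data, is, TRUE, "HaplotypeAlignment"))) {
    labs <- Reduce(intersect, lapply(data, haplotypeLabels))
    abort_if(length(labs) < 2, "loci share fewer than 2 haplotype labels")
    D <- matrix(0, length(labs), length(labs), dimnames = list(labs, labs))
    for (a in data) {
      Di <- seqDistMatrix(a, scale = "count")
      D <- D + Di[labs, labs]
    }
    if (is.null(populations))
      populations <- data[[1]]@deme[match(labs, haplotypeLabels(data[[1]]))]
    return(list(D = D, populations = populations))
  }
  stop("unsupported data type for amova/pairwiseFst", call. = FALSE)
}

#' Allele-mismatch distance between diploid individuals
#'
#' For each locus the number of allele copies not shared between the two
#' genotypes (0, 1 or 2), summed over loci and rescaled for pairwise
#' missingness.
#'
#' @param gm a \code{GenotypeMatrix}.
#' @return symmetric numeric matrix over individuals.
#' @export
snpDistMatrix <- function(gm) {
  dm <- dosageMatrix(gm)$dosage
  n <- nrow(dm); L <- ncol(dm)
  D <- matrix(0, n, n, dimnames = list(rownames(dm), rownames(dm)))
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    ok <- !is.na(dm[i, ]) & !is.na(dm[j, ])
    nv <- sum(ok)
    d <- if (nv) sum(abs(dm[i, ok] - dm[j, ok])) * L / nv else 0
    D[i, j] <- D[j, i] <- d
  }
  D
}

#' @export
print.amovaResult <- function(x, ...) {
  cat("AMOVA (", nrow(x$table) - 1, "-level decomposition)\n", sep = "")
  tab <- x$table
  tab$percent <- sprintf("%.2f%%", tab$percent)
  print(tab, row.names = FALSE)
  cat("Phi statistics:\n")
  for (k in names(x$phi))
    cat(sprintf("  %s = %.4f (P = %s)\n", k, x$phi[[k]],
                format.pval(x$pvalues[[k]])))
  invisible(x)
}
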