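#' @include fst.R
#' @importFrom stats ks.test prcomp quantile aggregate
NULL

#' Normality screening and log-transformation of traits
#'
#' Kolmogorov-Smirnov test of each trait against a normal distribution with
#' the sample mean and standard deviation; traits failing at \code{alpha}
#' are natural-log transformed (and renamed with a \code{log_} prefix).
#' Constant traits are flagged and excluded from the returned matrix.
#'
#' @param tm a \code{\linkS4class{TraitMatrix}}.
#' @param alpha significance level of the KS screen (default 0.05).
#' @return a \code{TraitMatrix} with transformed/retained traits;
#'   \code{attr(x, "report")} is a data.frame with per-trait KS statistics,
#'   p-values and the action taken.
#' @export
preprocessTraits <- function(tm, alpha = 0.05) {
  d <- tm@data
  report <- list()
  keep <- character(0)
  for (tr in tm@traitNames) {
    x <- d[[tr]][!is.na(d[[tr]])]
    if (length(unique(x)) < 2 || sd(x) == 0) {
      report[[tr]] <- data.frame(trait = tr, ks = NA, pvalue = NA,
                                 action = "excluded (constant)")
      next
    }
    kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
    if (kt$p.value < alpha) {
      abort_if(any(x <= 0), paste0("trait ", tr,
                                   " has non-positive values; cannot log-transform"))
      d[[paste0("log_", tr)]] <- log(d[[tr]])
      d[[tr]] <- NULL
      keep <- c(keep, paste0("log_", tr))
      report[[tr]] <- data.frame(trait = tr, ks = unname(kt$statistic),
                                 pvalue = kt$p.value, action = "log-transformed")
    } else {
      keep <- c(keep, tr)
      report[[tr]] <- data.frame(trait = tr, ks = unname(kt$statistic),
                                 pvalue = kt$p.value, action = "kept")
    }
  }
  abort_if(!length(keep), "no usable traits after screening")
  out <- new("TraitMatrix", data = d, traitNames = keep)
  attr(out, "report") <- do.call(rbind, report)
  out
}

# individual means over flower replicates, one row per individual
individualMeans <- function(tm) {
  d <- tm@data
  agg <- aggregate(d[tm@traitNames], by = list(individual = d$individual),
                   FUN = mean, na.rm = TRUE)
  popOf <- unique(d[, c("individual", "population")])
  agg$population <- popOf$population[match(agg$individual, popOf$individual)]
  agg
}

#' Principal components of individual-mean trait values
#'
#' PCA on standardized (correlation-matrix) individual means; floral traits
#' share units but differ in scale, so each trait is given unit variance
#' before rotation. Use \code{correlation = FALSE} for the covariance
#' matrix.
#'
#' @param tm a \code{TraitMatrix} (ideally after
#'   \code{\link{preprocessTraits}}).
#' @param correlation standardize traits first (default TRUE).
#' @return list with \code{scores} (data.frame: individual, population,
#'   PC columns), \code{varExplained} (fraction per component),
#'   \code{loadings}, \code{rank}. Components beyond the matrix rank carry
#'   zero variance and are flagged by \code{rank}.
#' @export
traitPca <- function(tm, correlation = TRUE) {
  im <- individualMeans(tm)
  abort_if(length(tm@traitNames) < 2, "PCA needs at least 2 traits")
  abort_if(nrow(im) < 3, "PCA needs at least 3 individuals")
  X <- as.matrix(im[, tm@traitNames])
  pc <- prcomp(X, center = TRUE, scale. = correlation)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- data.frame(individual = im$individual,
                       population = im$population, pc$x)
  list(scores = scores, varExplained = ve, loadings = pc$rotation,
       rank = sum(pc$sdev > 1e-10 * pc$sdev[1]))
}

# full-design mean squares (all populations jointly) for chi-square
# resampling of the Q_ST sampling distribution
fullDesignMS <- function(x, pop) {
  pop <- factor(pop)
  ok <- !is.na(x)
  x <- x[ok]; pop <- droplevels(pop[ok])
  P <- nlevels(pop)
  n <- tabulate(pop)
  N <- length(x)
  means <- tapply(x, pop, mean)
  gm <- mean(x)
  msb <- sum(n * (means - gm)^2) / (P - 1)
  msw <- sum((x - means[pop])^2) / (N - P)
  n0 <- (N - sum(n^2) / N) / (P - 1)
  list(msb = msb, msw = msw, n0 = n0, dfB = P - 1, dfW = N - P)
}

# parametric 95% CI of Q_ST from the pivotal F ratio of the one-way
# random-effects ANOVA: MS_B/MS_W estimates (n0 sigma_B + sigma_W)/sigma_W
# times an F(dfB, dfW) pivot, so the variance ratio lambda = n0 sigma_B /
# sigma_W has exact bounds R/F_alpha - 1 (clamped at 0) and Q_ST =
# lambda / (lambda + 2 n0) maps them monotonically. Exact for balanced
# normal designs, the standard approximation otherwise.
qstParametricCI <- function(x, pop) {
  ms <- fullDesignMS(x, pop)
  if (!is.finite(ms$msw) || ms$msw <= 0) return(c(NA_real_, NA_real_))
  R <- ms$msb / ms$msw
  lamLo <- max(0, R / stats::qf(0.975, ms$dfB, ms$dfW) - 1)
  lamHi <- max(0, R / stats::qf(0.025, ms$dfB, ms$dfW) - 1)
  c(lamLo / (lamLo + 2 * ms$n0), lamHi / (lamHi + 2 * ms$n0))
}

# one-way random-effects variance components on individual values
qstComponents <- function(x, pop) {
  pop <- factor(pop)
  ok <- !is.na(x)
  x <- x[ok]; pop <- droplevels(pop[ok])
  P <- nlevels(pop)
  if (P < 2) return(c(sigmaB = NA, sigmaW = NA, qst = NA))
  n <- tabulate(pop)
  N <- length(x)
  gm <- mean(x)
  means <- tapply(x, pop, mean)
  ssb <- sum(n * (means - gm)^2)
  ssw <- sum((x - means[pop])^2)
  msb <- ssb / (P - 1)
  msw <- if (N - P > 0) ssw / (N - P) else 0
  n0 <- (N - sum(n^2) / N) / (P - 1)
  sigB <- max(0, (msb - msw) / n0)
  sigW <- msw
  qst <- if (sigB + 2 * sigW > 0) sigB / (sigB + 2 * sigW) else 0
  c(sigmaB = sigB, sigmaW = sigW, qst = qst)
}

#' Q_ST of a trait from population-structured individual values
#'
#' \deqn{Q_{ST} = \sigma_B^2 / (\sigma_B^2 + 2 \sigma_W^2)} with the
#' between-population component from a one-way random-effects ANOVA on
#' individual means (flower replicates averaged first;
#' \code{sigma_B^2 = max(0, (MS_B - MS_W)/n_0)} with the standard
#' unbalanced-design coefficient n0). A nested mode instead removes the
#' flower-level measurement variance from \eqn{\sigma_W^2} via the nested
#' ANOVA (flowers within individuals within populations).
#'
#' @param tm a \code{TraitMatrix}.
#' @param trait trait column to analyse; alternatively pass \code{values}
#'   and \code{populations} directly.
#' @param values,populations optional explicit individual values and
#'   population labels (used instead of \code{tm}/\code{trait}).
#' @param nested use the nested flower-within-individual ANOVA for
#'   \eqn{\sigma_W^2} (default FALSE: flowers averaged first).
#' @param nBoot bootstrap replicates for a 95\% CI (populations, then
#'   individuals, resampled); 0 for point estimate only.
#' @param seed optional RNG seed for the bootstrap.
#' @return list with sigmaB, sigmaW, qst and (if \code{nBoot > 0}) ciLower,
#'   ciUpper.
#' @export
estimateQst <- function(tm = NULL, trait = NULL, values = NULL,
                        populations = NULL, nested = FALSE, nBoot = 0,
                        seed = NULL) {
  if (is.null(values)) {
    abort_if(is.null(tm) || is.null(trait), "supply tm+trait or values+populations")
    im <- individualMeans(tm)
    values <- im[[trait]]
    populations <- im$population
  }
  abort_if(length(unique(populations)) < 2, "Q_ST needs at least 2 populations")
  comp0 <- if (nested && !is.null(tm) && !is.null(trait))
    nestedQst(tm@data[[trait]], tm@data$population, tm@data$individual)
  else qstComponents(values, populations)
  out <- list(sigmaB = unname(comp0["sigmaB"]), sigmaW = unname(comp0["sigmaW"]),
              qst = unname(comp0["qst"]))
  if (nBoot > 0) {
    qb <- withSeed(seed, {
      pops <- unique(populations)
      vapply(seq_len(nBoot), function(b) {
        drawn <- sample(pops, length(pops), replace = TRUE)
        xs <- list(); ps <- list()
        for (k in seq_along(drawn)) {
          idx <- which(populations == drawn[k])
          idx <- sample(idx, length(idx), replace = TRUE)
          xs[[k]] <- values[idx]
          ps[[k]] <- rep(paste0("bp", k), length(idx))
        }
        qstComponents(unlist(xs), unlist(ps))["qst"]
      }, 0)
    })
    out$ciLower <- unname(quantile(qb, 0.025, na.rm = TRUE))
    out$ciUpper <- unname(quantile(qb, 0.975, na.rm = TRUE))
  }
  out
}

# nested ANOVA: flowers within individuals within populations; sigma_W is
# the among-individual-within-population component
nestedQst <- function(x, pop, ind) {
  ok <- !is.na(x)
  x <- x[ok]; pop <- factor(pop[ok]); ind <- factor(ind[ok])
  P <- nlevels(pop)
  if (P < 2) return(c(sigmaB = NA, sigmaW = NA, qst = NA))
  indMeans <- tapply(x, ind, mean)
  indPop <- tapply(as.character(pop), ind, function(z) z[1])
  flowersPer <- tabulate(ind)
  # flower-level residual
  msF <- sum((x - indMeans[ind])^2) / (length(x) - nlevels(ind))
  compInd <- qstComponents(as.numeric(indMeans), indPop)
  fbar <- mean(flowersPer[flowersPer > 0])
  sigW <- max(0, compInd["sigmaW"] - msF / fbar)
  sigB <- compInd["sigmaB"]
  qst <- if (sigB + 2 * sigW > 0) sigB / (sigB + 2 * sigW) else 0
  c(sigmaB = unname(sigB), sigmaW = unname(sigW), qst = unname(qst))
}

# per-population count, mean and within sum of squares
popSummaries <- function(values, populations, pops) {
  n <- m <- ss <- numeric(length(pops))
  for (k in seq_along(pops)) {
    x <- values[populations == pops[k]]
    x <- x[!is.na(x)]
    n[k] <- length(x); m[k] <- mean(x); ss[k] <- sum((x - m[k])^2)
  }
  list(n = n, m = m, ss = ss)
}

# all two-population Qst values at once (vectorized pair ANOVA); mask
# excludes pairs (e.g. bootstrap copies of the same source population).
# aggregate = "components": variance components summed over pairs before the
# ratio (near-unbiased, analogous to the multilocus Weir-Cockerham theta);
# "ratios": per-pair Qst ratios averaged (each pair's sigma_B has a single
# degree of freedom, so this variant is noticeably downward-biased).
qstPairMean <- function(n, m, ss, mask = NULL,
                        aggregate = c("components", "ratios")) {
  aggregate <- match.arg(aggregate)
  P <- length(n)
  N <- outer(n, n, "+")
  nm <- n * m
  GM <- outer(nm, nm, "+") / N
  Mi <- matrix(m, P, P)
  nI <- matrix(n, P, P)
  t1 <- nI * (Mi - GM)^2
  ssb <- t1 + t(t1)                      # MS_B (df = 1)
  msw <- outer(ss, ss, "+") / (N - 2)
  n0 <- N - outer(n^2, n^2, "+") / N
  keep <- upper.tri(N) & (N - 2 > 0)
  if (!is.null(mask)) keep <- keep & mask
  if (aggregate == "components") {
    sB <- sum(((ssb - msw) / n0)[keep], na.rm = TRUE)
    sW <- sum(msw[keep], na.rm = TRUE)
    sB <- max(0, sB)
    if (sB + 2 * sW <= 0) return(NaN)
    sB / (sB + 2 * sW)
  } else {
    sigB <- pmax(0, (ssb - msw) / n0)
    q <- sigB / (sigB + 2 * msw)
    mean(q[keep], na.rm = TRUE)
  }
}

# mean pairwise Qst over distinct population pairs
meanPairwiseQst <- function(values, populations,
                            aggregate = c("components", "ratios")) {
  pops <- unique(populations)
  s <- popSummaries(values, populations, pops)
  qstPairMean(s$n, s$m, s$ss, aggregate = match.arg(aggregate))
}

#' Q_ST - F_ST comparison across populations
#'
#' Computes, for every trait (and the leading principal components), the
#' mean pairwise Q_ST across populations with a bootstrap 95\% CI
#' (populations and individuals resampled), the mean pairwise
#' Weir-Cockerham F_ST from the SNP data with a locus-bootstrap 95\% CI,
#' and a verdict: \code{"exceeds"} when the Q_ST CI lies entirely above the
#' F_ST CI (divergent selection), \code{"below"} for the reverse (uniform
#' selection), \code{"overlap"} otherwise (consistent with drift).
#'
#' @param tm a \code{TraitMatrix} (after \code{\link{preprocessTraits}}).
#' @param gm a \code{\linkS4class{GenotypeMatrix}}.
#' @param populations optional subset of populations to compare (default:
#'   all populations shared by the two datasets).
#' @param usePCs also score PC1/PC2 of the traits (default TRUE).
#' @param nBoot bootstrap replicates (default 1000).
#' @param seed optional RNG seed.
#' @param ciMethod Q_ST confidence interval: \code{"parametric"}
#'   (default) inverts the pivotal F ratio of the one-way ANOVA
#'   (exact under trait normality, and wide enough to cover the
#'   evolutionary sampling of population effects);
#'   \code{"bootstrap"} resamples populations and individuals.
#' @param aggregate how the pairwise Q_ST values are combined:
#'   \code{"components"} (default) sums the two-population variance
#'   components over pairs before taking the Q_ST ratio (near-unbiased,
#'   like the multilocus Weir-Cockerham estimator); \code{"ratios"}
#'   averages per-pair Q_ST ratios (downward-biased since each pair's
#'   between-population variance has one degree of freedom).
#' @return object of class \code{"qstFstComparison"}: data.frame with one
#'   row per trait/PC: qst, qstLo, qstHi, fst, fstLo, fstHi, verdict.
#' @export
qstFstCompare <- function(tm, gm, populations = NULL, usePCs = TRUE,
                          nBoot = 1000, seed = NULL,
                          aggregate = c("components", "ratios"),
                          ciMethod = c("parametric", "bootstrap")) {
  aggregate <- match.arg(aggregate)
  ciMethod <- match.arg(ciMethod)
  im <- individualMeans(tm)
  shared <- intersect(unique(im$population), unique(gm@popmap$population))
  if (!is.null(populations)) shared <- intersect(shared, populations)
  abort_if(length(shared) < 2, "need at least 2 shared populations")
  if (length(shared) < 3)
    warning("fewer than 3 populations: bootstrap CIs are unreliable")
  im <- im[im$population %in% shared, ]
  keep <- gm@popmap$population %in% shared
  gmSub <- new("GenotypeMatrix", calls = gm@calls[keep, , drop = FALSE],
               popmap = gm@popmap[keep, , drop = FALSE])

  # per-pair per-locus WC components for the locus bootstrap
  pops <- sort(shared)
  pairIdx <- utils::combn(length(pops), 2)
  dos <- dosageMatrix(gmSub)$dosage
  popv <- gmSub@popmap$population
  L <- ncol(dos)
  nPair <- ncol(pairIdx)
  Amat <- Tmat <- matrix(0, nPair, L)
  for (k in seq_len(nPair)) {
    sel <- popv %in% pops[pairIdx[, k]]
    fac <- factor(popv[sel])
    cmp <- t(vapply(seq_len(L), function(l) wcComponentsLocus(dos[sel, l], fac),
                    c(a = 0, b = 0, c = 0)))
    ok <- rowSums(is.na(cmp)) == 0 & rowSums(cmp) != 0
    Amat[k, ok] <- cmp[ok, "a"]
    Tmat[k, ok] <- rowSums(cmp)[ok]
  }
  # mean pairwise theta given per-locus resample weights
  pairTheta <- function(w) mean((Amat %*% w) / (Tmat %*% w), na.rm = TRUE)
  fstObs <- pairTheta(rep(1, L))

  cols <- tm@traitNames
  scoreSets <- lapply(cols, function(tr)
    list(label = tr, values = im[[tr]], populations = im$population))
  if (usePCs && length(cols) >= 2) {
    pca <- traitPca(new("TraitMatrix",
                        data = tm@data[tm@data$individual %in% im$individual, ],
                        traitNames = tm@traitNames))
    sc <- pca$scores[pca$scores$population %in% shared, ]
    for (pc in c("PC1", "PC2")[seq_len(min(2, pca$rank))])
      scoreSets[[length(scoreSets) + 1]] <-
        list(label = pc, values = sc[[pc]], populations = sc$population)
  }

  res <- withSeed(seed, {
    fstBoot <- vapply(seq_len(nBoot), function(b)
      pairTheta(tabulate(sample.int(L, L, replace = TRUE), nbins = L)), 0)
    fstLo <- quantile(fstBoot, 0.025, na.rm = TRUE)
    fstHi <- quantile(fstBoot, 0.975, na.rm = TRUE)
    rows <- lapply(scoreSets, function(ss) {
      qObs <- meanPairwiseQst(ss$values, ss$populations, aggregate)
      if (ciMethod == "parametric") {
        ci <- qstParametricCI(ss$values, ss$populations)
        qLo <- ci[1]; qHi <- ci[2]
      } else {
        idxByPop <- lapply(pops, function(p) which(ss$populations == p))
        names(idxByPop) <- pops
        qBoot <- vapply(seq_len(nBoot), function(b) {
          drawn <- sample(pops, length(pops), replace = TRUE)
          n <- m <- ssq <- numeric(length(drawn))
          for (k in seq_along(drawn)) {
            idx <- idxByPop[[drawn[k]]]
            x <- ss$values[sample(idx, length(idx), replace = TRUE)]
            x <- x[!is.na(x)]
            n[k] <- length(x); m[k] <- mean(x); ssq[k] <- sum((x - m[k])^2)
          }
          # exclude pairs of bootstrap copies of one source population
          qstPairMean(n, m, ssq, mask = outer(drawn, drawn, "!="),
                      aggregate = aggregate)
        }, 0)
        qLo <- quantile(qBoot, 0.025, na.rm = TRUE)
        qHi <- quantile(qBoot, 0.975, na.rm = TRUE)
      }
      verdict <- if (qLo > fstHi) "exceeds" else if (qHi < fstLo) "below"
                 else "overlap"
      data.frame(trait = ss$label, qst = qObs, qstLo = unname(qLo),
                 qstHi = unname(qHi), fst = fstObs, fstLo = unname(fstLo),
                 fstHi = unname(fstHi), verdict = verdict)
    })
    do.call(rbind, rows)
  })
  rownames(res) <- NULL
  class(res) <- c("qstFstComparison", "data.frame")
  res
}

#' @export
print.qstFstComparison <- function(x, ...) {
  cat("Q_ST - F_ST comparison (95% bootstrap CIs)\n")
  y <- as.data.frame(x)
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, 4)
  print(y, row.names = FALSE)
  invisible(x)
}
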