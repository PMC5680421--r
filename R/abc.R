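#' @include fst.R coalsim.R
NULL

# scale every time in a model by s (sizes and per-generation migration rates
# unchanged, so the scaled population rate 2Nm is preserved)
scaleModelTimes <- function(model, s) {
  model@mergeTable$time <- model@mergeTable$time * s
  model@nodeTimes <- model@nodeTimes * s
  model@epochs <- lapply(model@epochs, function(e) {
    e$start <- e$start * s; e$end <- e$end * s; e
  })
  model
}

# pairwise Phi_ST vector between units from a summed squared-distance
# matrix. Uses the closed form of the two-group distance AMOVA on block
# sums of D2 (identical to amovaComponents on each pair, but two matrix
# products give every pair at once).
fstVectorFromDist <- function(D2, units) {
  uu <- sort(unique(units))
  G <- vapply(uu, function(u) as.numeric(units == u), numeric(length(units)))
  B <- crossprod(G, D2 %*% G)             # block sums over unit pairs
  n <- colSums(G)
  out <- numeric(0)
  for (i in seq_len(length(uu) - 1)) for (j in seq(i + 1, length(uu))) {
    nx <- n[i]; ny <- n[j]; N <- nx + ny
    ssdTot <- (B[i, i] / 2 + B[j, j] / 2 + B[i, j]) / N
    ssdWP <- B[i, i] / (2 * nx) + B[j, j] / (2 * ny)
    msAP <- ssdTot - ssdWP                 # df = 1
    msWP <- ssdWP / (N - 2)
    n0 <- N - (nx^2 + ny^2) / N
    sigA <- (msAP - msWP) / n0
    out[paste0(uu[i], ":", uu[j])] <- sigA / (sigA + msWP)
  }
  out
}

#' F_ST summary-statistic vector of a multilocus dataset
#'
#' The ordered vector of pairwise Phi_ST values between lineages, the
#' summary statistic used for scenario choice. Exactly the same estimator
#' code path is applied to observed and simulated data, so no
#' summary-statistic bias enters the comparison.
#'
#' @param alignments list of \code{HaplotypeAlignment} sharing haplotypes.
#' @param lineageMap optional named character vector mapping deme labels to
#'   lineages; default uses the deme labels themselves.
#' @return named numeric vector, one entry per lineage pair in canonical
#'   (alphabetical) order.
#' @export
lineageFstSummary <- function(alignments, lineageMap = NULL) {
  prep <- amovaDistance(alignments, NULL)
  units <- prep$populations
  if (!is.null(lineageMap)) units <- unname(lineageMap[units])
  abort_if(length(unique(units)) < 2, "need at least 2 lineages")
  tab <- table(units)
  abort_if(any(tab < 2), paste("lineage with <2 haplotypes:",
                               paste(names(tab)[tab < 2], collapse = ", ")))
  fstVectorFromDist(prep$D^2, units)
}

defaultAbcPriors <- function() {
  list(theta = list(dist = "loguniform", min = 0.5, max = 20),
       timeMult = list(dist = "uniform", min = 0.5, max = 2))
}

drawPrior <- function(spec, n) {
  switch(spec$dist,
    uniform = runif(n, spec$min, spec$max),
    loguniform = exp(runif(n, log(spec$min), log(spec$max))),
    stop("unknown prior distribution: ", spec$dist, call. = FALSE))
}

# simulate one multilocus dataset under a compiled model and return the
# Phi_ST summary vector (distance route: mutation-count distances per locus
# summed, then squared for the AMOVA quadratic forms)
simFstVector <- function(cm, timeMult, u, nLoci, units) {
  n <- length(cm$tipDeme)
  D <- matrix(0, n, n)
  for (l in seq_len(nLoci)) {
    D <- D + .sim_locus_dist_cpp(cm$tipDeme, cm$nDemes, cm$N,
                                 cm$mergeTime * timeMult, cm$mergeA, cm$mergeB,
                                 cm$mergeP, cm$epStart * timeMult,
                                 cm$epEnd * timeMult, cm$epM, u)
  }
  fstVectorFromDist(D^2, units)
}

#' Simulate an ABC reference table of F_ST summaries
#'
#' Draws (theta, time-multiplier) from the priors and simulates
#' \code{nSimsPerModel} multilocus datasets per candidate scenario model,
#' recording the pairwise lineage Phi_ST vector of each. Per-model RNG
#' streams are derived from the master seed by model name, so the table is
#' invariant to the order of the model list.
#'
#' @param models named list of \code{DemographicModel} (the candidate
#'   scenarios; all must share extant deme names).
#' @param sampleSizes named haplotype counts per extant deme.
#' @param nLoci number of independent loci per simulated dataset.
#' @param nSimsPerModel simulations per model.
#' @param priors list with elements \code{theta} and \code{timeMult}, each
#'   \code{list(dist, min, max)} with dist \code{"uniform"} or
#'   \code{"loguniform"}; \code{NULL} for defaults (theta log-uniform on
#'   [0.5, 20] per locus; time multiplier uniform on [0.5, 2]).
#' @param lineageMap optional deme -> lineage map for the summary units.
#' @param seed optional master seed.
#' @return object of class \code{"abcRefTable"}: list with \code{stats}
#'   (matrix, one row per simulation), \code{model} (label per row),
#'   \code{params} (data.frame of draws), \code{statNames}.
#' @export
buildAbcReferenceTable <- function(models, sampleSizes, nLoci,
                                   nSimsPerModel, priors = NULL,
                                   lineageMap = NULL, seed = NULL) {
  abort_if(is.null(names(models)) || any(names(models) == ""),
           "models must be a named list")
  abort_if(nSimsPerModel < 1, "nSimsPerModel must be >= 1")
  if (is.null(priors)) priors <- defaultAbcPriors()
  ord <- order(names(models))
  seeds <- childSeeds(seed, length(models))       # assigned by name order
  statList <- list(); labels <- character(0); params <- list()
  for (k in seq_along(models)) {
    mi <- ord[k]
    model <- models[[mi]]
    cm <- compileModel(model, sampleSizes)
    units <- cm$demeOfTip
    if (!is.null(lineageMap)) units <- unname(lineageMap[units])
    refN <- mean(model@demeSizes[model@demeNames])
    res <- withSeed(seeds[[k]], {
      th <- drawPrior(priors$theta, nSimsPerModel)
      tm <- drawPrior(priors$timeMult, nSimsPerModel)
      first <- simFstVector(cm, tm[1], th[1] / (4 * refN), nLoci, units)
      st <- matrix(0, nSimsPerModel, length(first),
                   dimnames = list(NULL, names(first)))
      st[1, ] <- first
      for (i in seq_len(nSimsPerModel)[-1])
        st[i, ] <- simFstVector(cm, tm[i], th[i] / (4 * refN), nLoci, units)
      list(st = st, th = th, tm = tm)
    })
    statList[[names(models)[mi]]] <- res$st
    labels <- c(labels, rep(names(models)[mi], nSimsPerModel))
    params[[names(models)[mi]]] <- data.frame(theta = res$th,
                                              timeMult = res$tm)
  }
  stats <- do.call(rbind, statList[names(models)[ord]])
  structure(list(stats = stats, model = labels,
                 params = do.call(rbind, params[names(models)[ord]]),
                 statNames = colnames(stats), nLoci = nLoci),
            class = "abcRefTable")
}

#' ABC rejection model choice among gene-flow scenarios
#'
#' Standardizes each summary-statistic dimension by the pooled simulated
#' median absolute deviation, computes Euclidean distances between the
#' observed vector and every simulation, accepts the closest
#' \code{tolerance} fraction of the pooled simulations, and reports each
#' model's share of the accepted draws as its posterior probability.
#'
#' @param observed named numeric summary vector (from
#'   \code{\link{lineageFstSummary}}, or the same statistic computed on a
#'   simulated pseudo-observed dataset).
#' @param refTable an \code{"abcRefTable"} from
#'   \code{\link{buildAbcReferenceTable}}; alternatively pass \code{models},
#'   \code{sampleSizes}, \code{nLoci}, \code{nSimsPerModel}, \code{priors},
#'   \code{lineageMap} and \code{seed} to build one on the fly.
#' @param tolerance accepted fraction of pooled simulations (default 0.001).
#' @param standardize divide each dimension by its pooled MAD before the
#'   Euclidean distance (default TRUE).
#' @param ... arguments forwarded to \code{buildAbcReferenceTable} when
#'   \code{refTable} is NULL.
#' @return object of class \code{"abcResult"}: list with \code{posterior}
#'   (named, sums to 1), \code{accepted} (counts per model), \code{nAccept},
#'   \code{tolerance}, \code{nSims}.
#' @export
abcRejection <- function(observed, refTable = NULL, tolerance = 0.001,
                         standardize = TRUE, ...) {
  if (is.null(refTable)) refTable <- buildAbcReferenceTable(...)
  abort_if(!inherits(refTable, "abcRefTable"), "refTable must be an abcRefTable")
  stats <- refTable$stats
  total <- nrow(stats)
  abort_if(tolerance * total < 1,
           "tolerance x simulation count is below 1; enlarge one")
  nAccept <- ceiling(tolerance * total)
  abort_if(length(observed) != ncol(stats),
           "observed summary length does not match the reference table")
  keepDim <- rep(TRUE, ncol(stats))
  scale <- rep(1, ncol(stats))
  if (standardize) {
    scale <- apply(stats, 2, stats::mad)
    keepDim <- scale > 0
    if (!all(keepDim))
      warning(sum(!keepDim), " degenerate summary dimension(s) dropped")
    abort_if(!any(keepDim), "all summary dimensions are degenerate")
  }
  z <- sweep(stats[, keepDim, drop = FALSE], 2, scale[keepDim], "/")
  zo <- observed[keepDim] / scale[keepDim]
  d2 <- rowSums(sweep(z, 2, zo, "-")^2)
  acc <- refTable$model[order(d2)[seq_len(nAccept)]]
  counts <- table(factor(acc, levels = unique(refTable$model)))
  post <- as.numeric(counts) / sum(counts)
  names(post) <- names(counts)
  structure(list(posterior = post, accepted = as.integer(counts),
                 nAccept = nAccept, tolerance = tolerance, nSims = total),
            class = "abcResult")
}

#' @export
print.abcResult <- function(x, ...) {
  cat("ABC rejection model choice (", x$nSims, " simulations, tolerance ",
      x$tolerance, ", ", x$nAccept, " accepted)\n", sep = "")
  for (m in names(x$posterior))
    cat(sprintf("  %-12s %.3f\n", m, x$posterior[[m]]))
  invisible(x)
}
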