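#' @include AllClasses.R
#' @importFrom ape read.tree is.binary is.rooted node.depth.edgelength Ntip
NULL

# Resolve a topology argument (phylo or newick string) to a rooted binary
# phylo with per-node times in generations.
resolveTopology <- function(topology, divergenceTimes = NULL) {
  if (is.character(topology)) topology <- ape::read.tree(text = topology)
  abort_if(!inherits(topology, "phylo"), "topology must be a phylo or newick string")
  abort_if(!ape::is.rooted(topology), "topology must be rooted")
  abort_if(!ape::is.binary(topology), "topology must be bifurcating")
  ntip <- ape::Ntip(topology)
  nnode <- topology$Nnode
  if (is.null(topology$node.label) || any(topology$node.label == "") ||
      anyDuplicated(c(topology$tip.label, topology$node.label))) {
    topology$node.label <- paste0("anc", seq_len(nnode))
  }
  if (is.null(divergenceTimes)) {
    abort_if(is.null(topology$edge.length),
             "supply divergenceTimes or a topology with branch lengths")
    depth <- ape::node.depth.edgelength(topology)
    h <- max(depth[seq_len(ntip)])
    abort_if(any(abs(depth[seq_len(ntip)] - h) > 1e-6 * max(h, 1)),
             "topology with branch lengths must be ultrametric")
    times <- h - depth
  } else {
    times <- numeric(ntip + nnode)
    if (!is.null(names(divergenceTimes))) {
      abort_if(!all(topology$node.label %in% names(divergenceTimes)),
               "divergenceTimes must be named for every internal node")
      times[ntip + seq_len(nnode)] <- divergenceTimes[topology$node.label]
    } else {
      abort_if(length(divergenceTimes) != nnode,
               "divergenceTimes must have one entry per internal node")
      times[ntip + seq_len(nnode)] <- divergenceTimes
    }
  }
  abort_if(any(times < 0), "divergence times must be >= 0")
  # strict decrease root -> tips: every child strictly younger than parent,
  # except that zero-length intervals are tolerated for degenerate tests
  par <- topology$edge[, 1]; chl <- topology$edge[, 2]
  abort_if(any(times[chl] > times[par] + 1e-9),
           "divergence times must decrease from root to tips")
  list(tree = topology, times = times, ntip = ntip)
}

# MRCA node id of two nodes (tips or internals) via ancestor paths
nodeMRCA <- function(tree, a, b) {
  anc <- function(x) {
    path <- x
    repeat {
      p <- tree$edge[tree$edge[, 2] == x, 1]
      if (length(p) == 0) break
      path <- c(path, p); x <- p
    }
    path
  }
  pa <- anc(a); pb <- anc(b)
  pa[pa %in% pb][1]
}

#' Build a gene-flow scenario demography
#'
#' Construct a \code{\linkS4class{DemographicModel}} implementing one of the
#' four canonical gene-flow scenarios on a rooted bifurcating deme tree:
#' \describe{
#'   \item{zero}{no migration at any time;}
#'   \item{constant}{symmetric migration between every pair of coexisting
#'     demes throughout their joint existence;}
#'   \item{historical}{migration restricted to the old part of each
#'     divergence, the interval \code{[epochFraction * tDiv, tDiv]} where
#'     \code{tDiv} is the divergence time of the pair;}
#'   \item{recent}{migration restricted to the young interval
#'     \code{[0, epochFraction * tDiv]}.}
#' }
#' Each active pair exchanges migrants symmetrically; a total scaled rate of
#' \code{rate2Nm} is split equally between the two directions, so
#' \code{rate2Nm = 1} gives 0.5 Nm per direction, i.e. a backward
#' per-generation rate of \code{rate2Nm / (4 N)} out of each deme.
#'
#' @param topology deme tree: \code{phylo} object or newick string. If branch
#'   lengths are present and ultrametric they define node times (in
#'   generations); otherwise supply \code{divergenceTimes}.
#' @param divergenceTimes numeric, generations before present for each
#'   internal node (named by node label, or unnamed in ape node order);
#'   \code{NULL} to take times from branch lengths.
#' @param demeSizes diploid effective size N_e: a single number recycled to
#'   every deme, or a vector named by all extant and ancestral deme names.
#' @param scenario one of \code{"zero"}, \code{"historical"},
#'   \code{"constant"}, \code{"recent"}.
#' @param rate2Nm scaled population migration rate 2Nm for an active pair
#'   (total over both directions; default 1 as in simulation studies that use
#'   0.5 Nm per direction).
#' @param epochFraction fraction in (0,1) of each divergence interval during
#'   which historical/recent gene flow acts (default 0.5).
#' @param migrationPairs optional 2-column character matrix of deme pairs
#'   allowed to exchange migrants; default all coexisting pairs.
#' @return a validated \code{DemographicModel}.
#' @examples
#' m <- buildScenario("((A:100,B:100):100,C:200);", demeSizes = 50,
#'                    scenario = "historical")
#' scenarioTag(m)
#' @export
buildScenario <- function(topology, divergenceTimes = NULL, demeSizes,
                          scenario = c("zero", "historical", "constant", "recent"),
                          rate2Nm = 1, epochFraction = 0.5,
                          migrationPairs = NULL) {
  scenario <- match.arg(scenario)
  abort_if(epochFraction <= 0 || epochFraction >= 1,
           "epochFraction must lie strictly between 0 and 1")
  abort_if(rate2Nm < 0, "rate2Nm must be >= 0")
  rt <- resolveTopology(topology, divergenceTimes)
  tree <- rt$tree; times <- rt$times; ntip <- rt$ntip
  demeNames <- tree$tip.label
  ancNames <- tree$node.label
  allDemes <- c(demeNames, ancNames)
  nAll <- length(allDemes)

  if (length(demeSizes) == 1 && is.null(names(demeSizes))) {
    N <- setNames(rep(demeSizes, nAll), allDemes)
  } else {
    abort_if(!all(allDemes %in% names(demeSizes)),
             "named demeSizes must cover every extant and ancestral deme")
    N <- demeSizes[allDemes]
  }
  abort_if(any(N <= 0), "deme sizes must be positive")

  nodeTimes <- setNames(times, allDemes)

  # merge schedule: internal nodes in increasing time order
  ord <- order(times[ntip + seq_len(tree$Nnode)])
  mt <- do.call(rbind, lapply(ord, function(k) {
    node <- ntip + k
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    data.frame(time = times[node], a = allDemes[kids[1]], b = allDemes[kids[2]],
               parent = allDemes[node], stringsAsFactors = FALSE)
  }))
  rootT <- max(mt$time)

  # deme lifespans: origin and absorption times
  parentNode <- rep(NA_integer_, nAll)
  parentNode[tree$edge[, 2]] <- tree$edge[, 1]
  origin <- times
  ends <- ifelse(is.na(parentNode), Inf, times[parentNode])

  # active migration windows per unordered pair
  windows <- list()
  if (scenario != "zero" && rate2Nm > 0) {
    allow <- NULL
    if (!is.null(migrationPairs)) {
      migrationPairs <- as.matrix(migrationPairs)
      allow <- paste(pmin(migrationPairs[, 1], migrationPairs[, 2]),
                     pmax(migrationPairs[, 1], migrationPairs[, 2]))
    }
    for (i in seq_len(nAll - 1)) for (j in seq(i + 1, nAll)) {
      t0 <- max(origin[i], origin[j])
      t1 <- min(ends[i], ends[j], rootT)
      if (t1 - t0 <= 0) next
      if (!is.null(allow)) {
        key <- paste(min(allDemes[i], allDemes[j]), max(allDemes[i], allDemes[j]))
        if (!key %in% allow) next
      }
      tDiv <- times[nodeMRCA(tree, i, j)]
      win <- switch(scenario,
        constant = c(t0, t1),
        historical = c(max(t0, epochFraction * tDiv), t1),
        recent = c(t0, min(t1, epochFraction * tDiv)))
      if (win[2] - win[1] <= 0) next
      windows[[length(windows) + 1]] <- list(i = i, j = j, start = win[1],
                                             end = win[2])
    }
  }

  # tile [0, rootT] at every window boundary
  bks <- sort(unique(c(0, rootT,
                       unlist(lapply(windows, function(w) c(w$start, w$end))))))
  bks <- bks[bks >= 0 & bks <= rootT]
  if (rootT == 0) bks <- c(0, 0)
  zeroM <- matrix(0, nAll, nAll, dimnames = list(allDemes, allDemes))
  epochs <- list()
  for (k in seq_len(length(bks) - 1)) {
    s <- bks[k]; e <- bks[k + 1]
    M <- zeroM
    mid <- (s + e) / 2
    for (w in windows) {
      if (mid > w$start && mid < w$end) {
        M[w$i, w$j] <- M[w$i, w$j] + rate2Nm / (4 * N[w$i])
        M[w$j, w$i] <- M[w$j, w$i] + rate2Nm / (4 * N[w$j])
      }
    }
    epochs[[length(epochs) + 1]] <- list(start = s, end = e, M = M)
  }
  # merge adjacent epochs with identical matrices
  if (length(epochs) > 1) {
    merged <- list(epochs[[1]])
    for (k in seq(2, length(epochs))) {
      last <- merged[[length(merged)]]
      if (identical(last$M, epochs[[k]]$M)) {
        merged[[length(merged)]]$end <- epochs[[k]]$end
      } else merged[[length(merged) + 1]] <- epochs[[k]]
    }
    epochs <- merged
  }

  new("DemographicModel", demeNames = demeNames, allDemes = allDemes,
      demeSizes = N, nodeTimes = nodeTimes, topology = tree, mergeTable = mt,
      epochs = epochs, scenario = scenario, rate2Nm = rate2Nm,
      epochFraction = epochFraction)
}

# Flatten a model + sampling layout into the argument list of the C++ core.
compileModel <- function(model, sampleSizes) {
  abort_if(is.null(names(sampleSizes)) ||
             !all(names(sampleSizes) %in% model@demeNames),
           "sampleSizes must be named by extant demes of the model")
  abort_if(any(sampleSizes < 1), "sample sizes must be >= 1 per sampled deme")
  idx <- match(model@allDemes, model@allDemes) # identity; deme i -> i
  tipDeme <- unlist(lapply(names(sampleSizes), function(d)
    rep(match(d, model@allDemes) - 1L, sampleSizes[[d]])))
  list(
    tipDeme = as.integer(tipDeme),
    nDemes = length(model@allDemes),
    N = unname(model@demeSizes[model@allDemes]),
    mergeTime = model@mergeTable$time,
    mergeA = match(model@mergeTable$a, model@allDemes) - 1L,
    mergeB = match(model@mergeTable$b, model@allDemes) - 1L,
    mergeP = match(model@mergeTable$parent, model@allDemes) - 1L,
    epStart = vapply(model@epochs, function(e) e$start, 0),
    epEnd = vapply(model@epochs, function(e) e$end, 0),
    epM = lapply(model@epochs, function(e) unname(e$M)),
    demeOfTip = names(sampleSizes)[rep(seq_along(sampleSizes),
                                       unlist(sampleSizes))]
  )
}
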