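#' @include coalsim.R
NULL

#' Genealogical sorting index
#'
#' Degree of exclusive ancestry of a labelled group of tips on a rooted
#' binary tree, from 0 (maximally dispersed) to 1 (monophyletic). The raw
#' ratio is \eqn{gs = n / \sum_{u \in U} (d_u - 2)} where U is the set of
#' internal nodes traversed in uniting the group (ascending from the group
#' tips until their paths connect at the group's most recent common
#' ancestor), \eqn{d_u} the node degree, and \eqn{n = |group| - 1} the
#' minimum number of nodes that could unite the group on a binary tree.
#' Every node's degree is counted as (number of children + 1) - the root's
#' basal edge is counted like a parent branch, so a group whose uniting walk
#' crosses the root is penalised for the crossing and gsi = 1 holds exactly
#' for groups monophyletic on the rooted tree. gsi rescales gs between its
#' minimum for the tree (the maximally dispersed arrangement traverses every
#' internal node, so \eqn{min(gs) = n / (T - 1)} on a binary T-tip tree)
#' and 1.
#'
#' @param tree rooted binary \code{phylo}. Polytomies are rejected.
#' @param group character vector of tip labels (or logical/integer index
#'   over tips); 2 <= |group| < number of tips.
#' @param nPerm optional number of tip-label permutations for a p-value
#'   (probability a random group of the same size sorts at least as well).
#' @param seed optional RNG seed for the permutation test.
#' @return list with \code{gs}, \code{gsi}, \code{monophyletic} and (if
#'   \code{nPerm > 0}) \code{pvalue}.
#' @examples
#' tr <- ape::read.tree(text = "((a,b),(c,d));")
#' computeGsi(tr, c("a", "b"))$gsi  # 1: monophyletic
#' @export
computeGsi <- function(tree, group, nPerm = 0, seed = NULL) {
  abort_if(!inherits(tree, "phylo"), "tree must be a phylo")
  abort_if(!ape::is.rooted(tree), "tree must be rooted")
  abort_if(!ape::is.binary(tree), "tree has polytomies; resolve before use")
  ntip <- length(tree$tip.label)
  if (is.character(group)) {
    miss <- setdiff(group, tree$tip.label)
    abort_if(length(miss) > 0,
             paste("group labels not in tree:", paste(miss, collapse = ", ")))
    gidx <- match(group, tree$tip.label)
  } else if (is.logical(group)) gidx <- which(group) else gidx <- as.integer(group)
  abort_if(length(gidx) < 2 || length(gidx) >= ntip,
           "group must contain between 2 and (tips - 1) members")
  parent <- integer(ntip + tree$Nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  gs <- gsRatio(parent, gidx, ntip)
  minGs <- (length(gidx) - 1) / (ntip - 1)
  gsi <- (gs - minGs) / (1 - minGs)
  out <- list(gs = gs, gsi = gsi,
              monophyletic = abs(gsi - 1) < 1e-12)
  if (nPerm > 0) {
    out$pvalue <- withSeed(seed, {
      hits <- 0L
      for (b in seq_len(nPerm)) {
        rg <- sample.int(ntip, length(gidx))
        g2 <- gsRatio(parent, rg, ntip)
        if ((g2 - minGs) / (1 - minGs) >= gsi - 1e-12) hits <- hits + 1L
      }
      (hits + 1) / (nPerm + 1)
    })
  }
  out
}

# uniting-walk ratio via parent pointers: U = internal nodes on the paths
# from group tips to the group MRCA; on binary trees each contributes
# degree - 2 = 1, so gs = (|group| - 1) / |U|
gsRatio <- function(parent, gidx, ntip) {
  # count, for every ancestor node, how many group-tip walks pass through it
  cnt <- integer(length(parent))
  for (tip in gidx) {
    v <- parent[tip]
    while (v != 0L) {
      cnt[v] <- cnt[v] + 1L
      v <- parent[v]
    }
  }
  k <- length(gidx)
  # MRCA = deepest node with cnt == k; U = visited nodes that are the MRCA
  # or have cnt < k (strictly inside the walk)
  U <- which(cnt > 0L)
  mrcaCandidates <- U[cnt[U] == k]
  # the MRCA is the one among them with no child also holding cnt == k;
  # equivalently all cnt==k nodes form a root-ward chain - keep the deepest
  inChain <- mrcaCandidates
  drop <- inChain[inChain %in% parent[inChain]]
  keep <- setdiff(U, drop)
  (k - 1) / length(keep)
}

#' Simulated gsi distributions across gene-flow scenarios
#'
#' Simulates genealogies under each supplied scenario model, computes the
#' gsi of every group on every tree, and tabulates the per-scenario mean and
#' spread - the simulation-based reference against which an empirical gsi
#' (from an inferred gene tree) is placed to time gene flow.
#'
#' @param models named list of \code{DemographicModel}s (typically the four
#'   scenarios built on one topology).
#' @param groups named list: group name -> character vector of deme names.
#'   Defaults to one group per extant deme.
#' @param sampleSizes named haplotype counts per extant deme.
#' @param nTrees simulated trees per scenario (default 10000).
#' @param seed optional master seed.
#' @param empirical optional rooted tree whose tips carry deme labels
#'   (\code{<deme>_...}); its gsi per group is appended for comparison.
#' @return data.frame with columns scenario, group, mean, sd, se, n; when
#'   \code{empirical} is given, extra rows with scenario \code{"empirical"}.
#'   With \code{nTrees = 1} sd/se are NA (flagged degenerate).
#' @export
gsiScenarios <- function(models, groups = NULL, sampleSizes, nTrees = 10000,
                         seed = NULL, empirical = NULL) {
  abort_if(!length(models), "no models given")
  if (is.null(names(models))) names(models) <- vapply(models, scenarioTag, "")
  if (is.null(groups)) {
    dn <- demeNames(models[[1]])
    groups <- setNames(as.list(dn), dn)
  }
  for (g in groups)
    abort_if(!all(g %in% demeNames(models[[1]])),
             "groups must map onto the model's extant demes")
  seeds <- childSeeds(seed, length(models))
  rows <- list()
  for (s in seq_along(models)) {
    vals <- withSeed(seeds[[s]], {
      sapply(seq_len(nTrees), function(i) {
        tr <- simulateGenealogy(models[[s]], sampleSizes)
        dem <- attr(tr, "tipDeme")
        vapply(groups, function(g)
          computeGsi(tr, which(dem %in% g))$gsi, 0)
      })
    })
    if (is.null(dim(vals))) vals <- matrix(vals, nrow = 1,
                                           dimnames = list(names(groups)))
    for (g in seq_along(groups)) {
      v <- vals[g, ]
      rows[[length(rows) + 1]] <- data.frame(
        scenario = names(models)[s], group = names(groups)[g],
        mean = mean(v),
        sd = if (nTrees > 1) sd(v) else NA_real_,
        se = if (nTrees > 1) sd(v) / sqrt(nTrees) else NA_real_,
        n = nTrees)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(empirical)) {
    dem <- sub("_[^_]+_[^_]+$", "", empirical$tip.label)
    emp <- vapply(groups, function(g)
      computeGsi(empirical, which(dem %in% g))$gsi, 0)
    out <- rbind(out, data.frame(scenario = "empirical",
                                 group = names(groups), mean = emp,
                                 sd = NA_real_, se = NA_real_, n = 1L))
  }
  rownames(out) <- NULL
  out
}
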