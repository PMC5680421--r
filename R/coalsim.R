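#' @include demography.R
#' @useDynLib speciflow, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

#' Simulate a genealogy under a structured coalescent
#'
#' Runs the structured coalescent backward in time on a
#' \code{\linkS4class{DemographicModel}}: within deme \code{i}, \code{k}
#' lineages coalesce at rate \code{k(k-1)/(4 N_i)} per generation; each
#' lineage migrates between demes at the current epoch's backward rates; at a
#' divergence time the daughter demes' lineages move into the ancestral
#' deme. The result is a rooted ultrametric tree with branch lengths in
#' generations.
#'
#' @param model a \code{DemographicModel}.
#' @param sampleSizes named integer vector: haplotypes sampled per extant
#'   deme (consecutive pairs of haplotypes form diploid individuals).
#' @param seed optional integer seed (local to this call).
#' @return an \code{ape::phylo}; tip labels are
#'   \code{<deme>_<individual>_<copy>}, \code{attr(tree, "tipDeme")} gives
#'   the deme of each tip and \code{attr(tree, "nodeTime")} the node times in
#'   generations.
#' @examples
#' m <- buildScenario("(A:200,B:200);", demeSizes = 100, scenario = "zero")
#' tr <- simulateGenealogy(m, c(A = 4, B = 4), seed = 1)
#' @export
simulateGenealogy <- function(model, sampleSizes, seed = NULL) {
  cm <- compileModel(model, sampleSizes)
  withSeed(seed, {
    raw <- .sim_coal_cpp(cm$tipDeme, cm$nDemes, cm$N, cm$mergeTime, cm$mergeA,
                         cm$mergeB, cm$mergeP, cm$epStart, cm$epEnd, cm$epM)
    assembleGenealogy(raw, cm$demeOfTip)
  })
}

assembleGenealogy <- function(raw, demeOfTip) {
  n <- length(demeOfTip)
  perDeme <- stats::ave(seq_len(n), demeOfTip, FUN = seq_along)
  labels <- paste(demeOfTip, ceiling(perDeme / 2), 2 - perDeme %% 2, sep = "_")
  tr <- structure(list(edge = raw$edge, edge.length = raw$edge.length,
                       Nnode = raw$Nnode, tip.label = labels),
                  class = "phylo", order = "none")
  attr(tr, "tipDeme") <- demeOfTip
  attr(tr, "nodeTime") <- raw$node.time
  tr
}

#' Mutation model for simulated loci
#'
#' The per-locus mutation rate can be given either as the population
#' mutation rate theta (= 4 N mu L per locus, with \code{refN} the reference
#' diploid size used to de-scale it) or directly as \code{mu}, a per-site
#' per-generation rate, combined with the locus length at mutation time.
#'
#' @param mode \code{"infinite_sites"} (each mutation strikes a new site) or
#'   \code{"jc69"} (Jukes-Cantor site-wise substitution).
#' @param theta per-locus population mutation rate 4*N*mu*L; requires
#'   \code{refN}.
#' @param refN reference diploid N_e used to convert theta to a
#'   per-generation rate.
#' @param mu per-site per-generation mutation rate (alternative to theta).
#' @return an object of class \code{"mutationModel"}.
#' @export
mutationModel <- function(mode = c("infinite_sites", "jc69"), theta = NULL,
                          refN = NULL, mu = NULL) {
  mode <- match.arg(mode)
  abort_if(is.null(theta) == is.null(mu),
           "give exactly one of theta (with refN) or mu")
  if (!is.null(theta)) {
    abort_if(is.null(refN) || refN <= 0, "theta requires a positive refN")
    abort_if(theta <= 0, "theta must be > 0")
  } else {
    abort_if(mu <= 0, "mu must be > 0")
  }
  structure(list(mode = mode, theta = theta, refN = refN, mu = mu),
            class = "mutationModel")
}

# per-locus per-generation mutation rate
locusRate <- function(mutation, locusLength) {
  if (!is.null(mutation$theta)) mutation$theta / (4 * mutation$refN)
  else mutation$mu * locusLength
}

# list of tip descendants for every node of a phylo (tips: themselves)
tipDescendants <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  kids <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge)))
    kids[[tree$edge[e, 1]]] <- c(kids[[tree$edge[e, 1]]], tree$edge[e, 2])
  out <- vector("list", nn)
  # process nodes children-first (internal ids decrease with time here, but
  # be safe: iterate until settled)
  fill <- function(v) {
    if (!is.null(out[[v]])) return(out[[v]])
    if (v <= n) { out[[v]] <<- v; return(out[[v]]) }
    out[[v]] <<- unlist(lapply(kids[[v]], fill))
    out[[v]]
  }
  root <- n + 1L
  fill(root)
  out
}

#' Drop mutations on a genealogy to produce a haplotype alignment
#'
#' Mutations fall on branches as a Poisson process with the per-locus rate
#' of the \code{\link{mutationModel}}. Under \code{infinite_sites} each
#' mutation occupies a distinct uniformly drawn site (two nucleotide states
#' per mutated site); more mutations than sites is an error because the
#' infinite-sites regime is then violated. Under \code{jc69} sequences evolve
#' site-wise from a random root sequence.
#'
#' @param genealogy tree from \code{\link{simulateGenealogy}} (or any rooted
#'   \code{phylo} with branch lengths in generations and tip labels
#'   \code{<deme>_<individual>_<copy>}).
#' @param mutation a \code{\link{mutationModel}}.
#' @param locusLength locus length in bp.
#' @param seed optional integer seed (local to this call).
#' @param locusId locus identifier for the output alignment.
#' @return a \code{\linkS4class{HaplotypeAlignment}}.
#' @export
mutateAlignment <- function(genealogy, mutation, locusLength, seed = NULL,
                            locusId = "locus1") {
  abort_if(locusLength < 1, "locusLength must be positive")
  abort_if(!inherits(mutation, "mutationModel"), "mutation must be a mutationModel")
  u <- locusRate(mutation, locusLength)
  n <- length(genealogy$tip.label)
  bases <- c("A", "C", "G", "T")
  mat <- withSeed(seed, {
    if (mutation$mode == "infinite_sites") {
      nm <- rpois(nrow(genealogy$edge), u * genealogy$edge.length)
      S <- sum(nm)
      abort_if(S > locusLength, paste0(
        "infinite-sites overflow: ", S, " mutations for ", locusLength,
        " sites; lower theta/mu or lengthen the locus"))
      anc <- sample(bases, locusLength, replace = TRUE)
      m <- matrix(rep(anc, each = n), nrow = n)
      if (S > 0) {
        sites <- sample.int(locusLength, S)
        desc <- tipDescendants(genealogy)
        k <- 0L
        for (e in seq_len(nrow(genealogy$edge))) {
          if (nm[e] == 0) next
          tips <- desc[[genealogy$edge[e, 2]]]
          for (j in seq_len(nm[e])) {
            k <- k + 1L
            s <- sites[k]
            m[tips, s] <- sample(setdiff(bases, anc[s]), 1)
          }
        }
      }
      m
    } else {
      rate <- u / locusLength # per-site per-generation
      nn <- n + genealogy$Nnode
      seqs <- vector("list", nn)
      root <- n + 1L
      seqs[[root]] <- sample(bases, locusLength, replace = TRUE)
      # preorder: parents before children (sort edges by parent time desc)
      nt <- attr(genealogy, "nodeTime")
      ord <- if (!is.null(nt)) order(nt[genealogy$edge[, 1]], decreasing = TRUE)
             else seq_len(nrow(genealogy$edge))
      for (e in ord) {
        p <- genealogy$edge[e, 1]; ch <- genealogy$edge[e, 2]
        s <- seqs[[p]]
        hits <- rpois(locusLength, rate * genealogy$edge.length[e])
        idx <- which(hits > 0)
        for (s0 in idx) for (j in seq_len(hits[s0]))
          s[s0] <- sample(setdiff(bases, s[s0]), 1)
        seqs[[ch]] <- s
      }
      do.call(rbind, seqs[seq_len(n)])
    }
  })
  lab <- strsplit(genealogy$tip.label, "_")
  dem <- vapply(lab, function(x) paste(x[seq_len(length(x) - 2)], collapse = "_"), "")
  ind <- vapply(lab, function(x) x[length(x) - 1], "")
  cpy <- as.integer(vapply(lab, function(x) x[length(x)], ""))
  ss <- Biostrings::DNAStringSet(apply(mat, 1, paste, collapse = ""))
  names(ss) <- genealogy$tip.label
  new("HaplotypeAlignment", locusId = locusId, seqs = ss,
      individual = paste(dem, ind, sep = "_"), copy = cpy, deme = dem)
}

#' Simulate independent multilocus data under a demography
#'
#' Simulates one independent genealogy per locus (free recombination between
#' loci, none within) and drops mutations on each, mirroring a small panel of
#' unlinked nuclear loci. Per-locus RNG streams are derived deterministically
#' from \code{seed}, so extending the locus list never changes earlier loci.
#'
#' @param model a \code{DemographicModel}.
#' @param sampleSizes named integer vector of haplotypes per extant deme.
#' @param loci data.frame with columns \code{length} (bp) and \code{theta}
#'   (per-locus 4*N*mu*L, de-scaled with the model's mean extant deme size),
#'   optionally \code{mode}; or a list of \code{list(length=, mutation=)}.
#' @param seed optional integer master seed.
#' @return list with elements \code{alignments} (list of
#'   \code{HaplotypeAlignment}) and \code{genealogies} (list of trees).
#' @export
simulateMultilocus <- function(model, sampleSizes, loci, seed = NULL) {
  plan <- lociPlan(loci, model)
  abort_if(length(plan) < 1, "at least one locus is required")
  seeds <- childSeeds(seed, 2L * length(plan))
  alignments <- vector("list", length(plan))
  genealogies <- vector("list", length(plan))
  for (i in seq_along(plan)) {
    g <- simulateGenealogy(model, sampleSizes, seed = seeds[[2 * i - 1]])
    a <- mutateAlignment(g, plan[[i]]$mutation, plan[[i]]$length,
                         seed = seeds[[2 * i]],
                         locusId = names(plan)[i])
    genealogies[[i]] <- g
    alignments[[i]] <- a
  }
  names(alignments) <- names(genealogies) <- names(plan)
  list(alignments = alignments, genealogies = genealogies)
}

lociPlan <- function(loci, model) {
  if (is.data.frame(loci)) {
    refN <- mean(model@demeSizes[model@demeNames])
    mode <- if ("mode" %in% names(loci)) loci$mode else
      rep("infinite_sites", nrow(loci))
    plan <- lapply(seq_len(nrow(loci)), function(i)
      list(length = loci$length[i],
           mutation = mutationModel(mode[i], theta = loci$theta[i], refN = refN)))
  } else {
    plan <- loci
  }
  if (is.null(names(plan)) || any(names(plan) == ""))
    names(plan) <- sprintf("L%02d", seq_along(plan))
  plan
}
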