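#' @include coalsim.R fst.R qstfst.R
NULL

# serialize a node (list(children=, time=, label=) or character tip) to newick
nodeToNewick <- function(node, parentTime) {
  if (is.character(node))
    return(paste0(node, ":", format(parentTime, scientific = FALSE)))
  inner <- paste(vapply(node$children, nodeToNewick, "", parentTime = node$time),
                 collapse = ",")
  len <- parentTime - node$time
  paste0("(", inner, ")", node$label, ":", format(len, scientific = FALSE))
}

# ladder ("staggered star") subtree over population tips: split times evenly
# spaced in [0.9, 1.1] x depth so the tree stays strictly bifurcating
ladderNode <- function(tips, depth, labelPrefix) {
  if (length(tips) == 1) return(tips[1])
  k <- length(tips) - 1
  times <- if (k == 1) depth else seq(0.9 * depth, 1.1 * depth, length.out = k)
  node <- tips[1]
  for (i in seq_len(k)) {
    node <- list(children = list(node, tips[i + 1]), time = times[i],
                 label = paste0(labelPrefix, "x", i))
  }
  node
}

#' Default study configuration for the synthetic generator
#'
#' Mirrors the sampling design that the analysis expects: 7 species in 4
#' lineages (EbuW; Lut; PAS = Pol + Alu + Sui; EX = EbuE + Xiz), 43
#' populations of 5-14 individuals (about 405 in total), 6 nuclear sequence
#' loci of 669-1197 bp, a 541-locus biallelic SNP panel, and 5 floral traits
#' (CL, CH, CW, PW1, PW2) measured on 5 flowers per individual in a subset
#' of 22 populations. Species divergence times (in generations) follow the
#' relative depths of the complex (the most recent split about a quarter of
#' the root age); population substructure splits at about 0.1x the species
#' divergence. Two of the trait distributions (PW1, PW2) are generated
#' log-normal so the normality screen has work to do.
#'
#' @param scenario gene-flow scenario of the generating demography.
#' @param rate2Nm scaled migration rate for non-zero scenarios.
#' @param epochFraction epoch fraction of the historical/recent scenarios.
#' @param selectionMultiplier multiplier on the neutral between-population
#'   trait variance (1 = neutral drift, so E[Q_ST] matches F_ST; 10 mimics
#'   strong divergent selection).
#' @param nSnps number of SNP panel loci.
#' @param missingRate per-call missing-data probability of the SNP panel.
#' @return a list of class \code{"studyConfig"}.
#' @export
studyConfig <- function(scenario = "historical", rate2Nm = 1,
                        epochFraction = 0.5, selectionMultiplier = 1,
                        nSnps = 541, missingRate = 0.02) {
  cfg <- list(
    species = c("EbuW", "Lut", "Pol", "Alu", "Sui", "EbuE", "Xiz"),
    lineageOf = c(EbuW = "EbuW", Lut = "Lut", Pol = "PAS", Alu = "PAS",
                  Sui = "PAS", EbuE = "EX", Xiz = "EX"),
    popsPerSpecies = c(EbuW = 13, Lut = 5, Pol = 3, Alu = 5, Sui = 2,
                       EbuE = 12, Xiz = 3),
    indRange = c(5L, 14L),
    # species-level divergence times, generations
    speciesTimes = c(root = 80000, WEXPAS = 60000, EXPAS = 50000,
                     EX = 20000, PAS = 18000, AluSui = 15000),
    popDepthFraction = 0.1,
    popN = 2000, ancN = 10000,
    lociLengths = c(669L, 802L, 915L, 1002L, 1100L, 1197L),
    mu = 5e-8,
    snpLocusLength = 300L,
    nSnps = nSnps,
    snpMinCount = 5L,
    missingRate = missingRate,
    scenario = scenario, rate2Nm = rate2Nm, epochFraction = epochFraction,
    traitMeans = c(CL = 35, CH = 12, CW = 14, PW1 = 9, PW2 = 10),
    logNormalTraits = c("PW1", "PW2"),
    traitCVwithin = 0.10, traitCVmeasure = 0.03, traitSdLog = 0.35,
    traitPopsPerSpecies = c(EbuW = 8, EbuE = 8, Pol = 2, Alu = 2, Sui = 2),
    traitIndPerPop = 6L, flowersPerInd = 5L,
    selectionMultiplier = selectionMultiplier
  )
  class(cfg) <- "studyConfig"
  cfg
}

# species divergence time of each species from its sister group (used for
# the within-species population split depth)
speciesSisterTime <- function(cfg) {
  st <- cfg$speciesTimes
  c(EbuW = unname(st["WEXPAS"]), Lut = unname(st["root"]),
    Pol = unname(st["PAS"]), Alu = unname(st["AluSui"]),
    Sui = unname(st["AluSui"]), EbuE = unname(st["EX"]),
    Xiz = unname(st["EX"]))
}

# population-level demography newick for the whole complex
studyPopulationTree <- function(cfg, popNames) {
  st <- cfg$speciesTimes
  sis <- speciesSisterTime(cfg)
  spNode <- lapply(cfg$species, function(sp) {
    ladderNode(popNames[[sp]], cfg$popDepthFraction * sis[[sp]], sp)
  })
  names(spNode) <- cfg$species
  ex <- list(children = spNode[c("EbuE", "Xiz")], time = st[["EX"]],
             label = "EXanc")
  alusui <- list(children = spNode[c("Alu", "Sui")], time = st[["AluSui"]],
                 label = "AluSuianc")
  pas <- list(children = list(spNode[["Pol"]], alusui), time = st[["PAS"]],
              label = "PASanc")
  expas <- list(children = list(ex, pas), time = st[["EXPAS"]],
                label = "EXPASanc")
  wexpas <- list(children = list(spNode[["EbuW"]], expas),
                 time = st[["WEXPAS"]], label = "WEXPASanc")
  root <- list(children = list(spNode[["Lut"]], wexpas), time = st[["root"]],
               label = "ROOT")
  paste0(nodeToNewick(root, root$time + 1), ";") |>
    sub(pattern = ":1;$", replacement = ";")
}

#' Topologies of the study's scenario models
#'
#' The three deme trees on which gene-flow scenarios are tested: the
#' four-lineage model \code{(Lut,(EbuW,(EX,PAS)))}, the three-species model
#' \code{(Pol,(Alu,Sui))} and the two-species model \code{(EbuE,Xiz)}, with
#' divergence times (generations) taken from \code{\link{studyConfig}}.
#'
#' @param which \code{"fourLineage"}, \code{"threeSpecies"} or
#'   \code{"twoSpecies"}.
#' @param cfg a \code{studyConfig} (for the time scale).
#' @return newick string with branch lengths in generations.
#' @export
studyTopology <- function(which = c("fourLineage", "threeSpecies",
                                    "twoSpecies"),
                          cfg = studyConfig()) {
  which <- match.arg(which)
  st <- cfg$speciesTimes
  nw <- function(node) paste0(nodeToNewick(node, node$time), ";")
  tree <- switch(which,
    fourLineage = list(children = list(
      "Lut",
      list(children = list(
        "EbuW",
        list(children = list("EX", "PAS"), time = st[["EXPAS"]],
             label = "EXPASanc")),
        time = st[["WEXPAS"]], label = "WEXPASanc")),
      time = st[["root"]], label = "ROOT"),
    threeSpecies = list(children = list(
      "Pol",
      list(children = list("Alu", "Sui"), time = st[["AluSui"]],
           label = "AluSuianc")),
      time = st[["PAS"]], label = "PASanc"),
    twoSpecies = list(children = list("EbuE", "Xiz"), time = st[["EX"]],
                      label = "EXanc"))
  nw(tree)
}

#' Build the four scenario models on one topology
#'
#' @param topology newick string or phylo with branch lengths in
#'   generations.
#' @param demeSizes diploid N_e (scalar or named).
#' @param rate2Nm scaled migration rate of the non-zero scenarios.
#' @param epochFraction historical/recent epoch fraction.
#' @return named list of \code{DemographicModel}s:
#'   zero, historical, constant, recent.
#' @export
buildScenarioSuite <- function(topology, demeSizes, rate2Nm = 1,
                               epochFraction = 0.5) {
  sc <- c("zero", "historical", "constant", "recent")
  setNames(lapply(sc, function(s)
    buildScenario(topology, demeSizes = demeSizes, scenario = s,
                  rate2Nm = rate2Nm, epochFraction = epochFraction)), sc)
}

#' Generate a complete synthetic study dataset
#'
#' Simulates, from one population-level demography of the 7-species /
#' 4-lineage complex: phased multilocus sequence alignments, a biallelic SNP
#' panel (one non-singleton segregating site per independent short locus,
#' mimicking an ascertained unlinked panel; sprinkled missing calls), the
#' population map, and floral trait measurements whose between-population
#' variance is calibrated against the realized SNP differentiation so that
#' a selection multiplier of 1 gives the neutral expectation
#' E[Q_ST] = E[F_ST] (larger multipliers mimic divergent selection).
#'
#' @param cfg a \code{\link{studyConfig}}.
#' @param seed master seed; all stages derive deterministic child streams,
#'   so one seed reproduces the whole dataset byte for byte.
#' @return list with \code{alignments} (list of
#'   \code{HaplotypeAlignment}), \code{genotypes}
#'   (\code{GenotypeMatrix}), \code{popmap} (data.frame), \code{traits}
#'   (\code{TraitMatrix}), \code{model} (the generating
#'   \code{DemographicModel}, ground truth), \code{config}.
#' @export
generateStudy <- function(cfg = studyConfig(), seed = NULL) {
  abort_if(!inherits(cfg, "studyConfig"), "cfg must be a studyConfig")
  abort_if(!setequal(names(cfg$popsPerSpecies), cfg$species),
           "popsPerSpecies must cover exactly the configured species")
  abort_if(any(cfg$popsPerSpecies < 1) || any(cfg$indRange < 1),
           "population and individual counts must be >= 1")
  seeds <- childSeeds(seed, 5)

  popNames <- lapply(cfg$species, function(sp)
    sprintf("%s%02d", sp, seq_len(cfg$popsPerSpecies[[sp]])))
  names(popNames) <- cfg$species
  allPops <- unlist(popNames)

  # sampling layout
  indPerPop <- withSeed(seeds[[1]], {
    setNames(sample(seq(cfg$indRange[1], cfg$indRange[2]), length(allPops),
                    replace = TRUE), allPops)
  })
  popmap <- do.call(rbind, lapply(allPops, function(p) {
    sp <- cfg$species[vapply(cfg$species, function(s)
      p %in% popNames[[s]], TRUE)]
    data.frame(individual = paste0(p, "_", seq_len(indPerPop[[p]])),
               population = p, species = sp,
               lineage = unname(cfg$lineageOf[sp]))
  }))
  rownames(popmap) <- NULL

  # demography over populations: extant population demes at popN, every
  # ancestral deme at the larger ancN
  nwk <- studyPopulationTree(cfg, popNames)
  tr0 <- ape::read.tree(text = nwk)
  sizes <- c(setNames(rep(cfg$popN, length(tr0$tip.label)), tr0$tip.label),
             setNames(rep(cfg$ancN, tr0$Nnode), tr0$node.label))
  model <- buildScenario(nwk, demeSizes = sizes, scenario = cfg$scenario,
                         rate2Nm = cfg$rate2Nm,
                         epochFraction = cfg$epochFraction)

  sampleSizes <- setNames(as.integer(2 * indPerPop[model@demeNames]),
                          model@demeNames)

  # sequence loci
  lociList <- lapply(cfg$lociLengths, function(L)
    list(length = L, mutation = mutationModel("infinite_sites", mu = cfg$mu)))
  names(lociList) <- sprintf("nDNA%02d", seq_along(cfg$lociLengths))
  seqs <- withSeed(seeds[[2]],
    simulateMultilocus(model, sampleSizes, lociList))

  # SNP panel
  genotypes <- withSeed(seeds[[3]],
    simulateSnpPanel(model, sampleSizes, popmap, cfg))

  # floral traits, calibrated on realized SNP differentiation
  traits <- withSeed(seeds[[4]], simulateTraits(genotypes, model, cfg))

  list(alignments = seqs$alignments, genotypes = genotypes, popmap = popmap,
       traits = traits, model = model, config = cfg)
}

# derived allele counts below every edge of a raw simulated tree
edgeTipCounts <- function(edge, nodeTime, nTip) {
  cnt <- c(rep(1L, nTip), rep(0L, nTip - 1L))
  ord <- order(nodeTime[edge[, 2]])
  for (e in ord) cnt[edge[e, 1]] <- cnt[edge[e, 1]] + cnt[edge[e, 2]]
  cnt
}

simulateSnpPanel <- function(model, sampleSizes, popmap, cfg) {
  cm <- compileModel(model, sampleSizes)
  nHap <- length(cm$tipDeme)
  nInd <- nHap / 2
  bases <- c("A", "C", "G", "T")
  calls <- matrix(NA_character_, nInd, cfg$nSnps)
  for (l in seq_len(cfg$nSnps)) {
    raw <- .sim_coal_cpp(cm$tipDeme, cm$nDemes, cm$N, cm$mergeTime, cm$mergeA,
                         cm$mergeB, cm$mergeP, cm$epStart, cm$epEnd, cm$epM)
    cnt <- edgeTipCounts(raw$edge, raw$node.time, nHap)
    below <- cnt[raw$edge[, 2]]
    mc <- max(2L, cfg$snpMinCount)
    elig <- which(below >= mc & below <= nHap - mc)
    if (!length(elig)) elig <- seq_len(nrow(raw$edge))
    e <- elig[sample.int(length(elig), 1,
                         prob = raw$edge.length[elig] + 1e-12)]
    # derived tips: all tips below the chosen edge
    derived <- tipsBelow(raw$edge, raw$node.time, nHap, raw$edge[e, 2])
    al <- sample(bases, 2)
    hap <- rep(al[1], nHap); hap[derived] <- al[2]
    g1 <- hap[seq(1, nHap, by = 2)]
    g2 <- hap[seq(2, nHap, by = 2)]
    calls[, l] <- paste(pmin(g1, g2), pmax(g1, g2), sep = "/")
  }
  calls[matrix(runif(length(calls)) < cfg$missingRate, nrow(calls))] <- NA
  dimnames(calls) <- list(popmap$individual,
                          sprintf("SNP%03d", seq_len(cfg$nSnps)))
  new("GenotypeMatrix", calls = calls, popmap = popmap)
}

tipsBelow <- function(edge, nodeTime, nTip, node) {
  if (node <= nTip) return(node)
  out <- integer(0)
  stack <- node
  kids <- split(edge[, 2], edge[, 1])
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= nTip) out <- c(out, v)
    else stack <- c(stack, kids[[as.character(v)]])
  }
  out
}

simulateTraits <- function(genotypes, model, cfg) {
  # trait populations: subset per configured species
  pm <- genotypes@popmap
  traitPops <- unlist(lapply(names(cfg$traitPopsPerSpecies), function(sp) {
    pp <- unique(pm$population[pm$species == sp])
    pp[seq_len(min(cfg$traitPopsPerSpecies[[sp]], length(pp)))]
  }))
  # realized pairwise differentiation between trait populations, on the
  # same (MAF/missingness-filtered) panel the downstream comparison sees
  keep <- pm$population %in% traitPops
  gsub <- new("GenotypeMatrix", calls = genotypes@calls[keep, , drop = FALSE],
              popmap = pm[keep, , drop = FALSE])
  gsub <- filterGenotypes(gsub)
  fst <- pairwiseFst(gsub, nPerm = 0)$fst[traitPops, traitPops]
  Fij <- pmin(pmax(fst, 0.001), 0.95)

  # Population trait effects are hierarchical: an exchangeable
  # within-species deviation (the star-like population splits are
  # near-simultaneous) plus a species-level effect. Each layer's variance
  # is tied to the realized mean F_ST at that level through the neutral
  # identity sigmaB = 2 sigmaW^2 F/(1-F), times the selection multiplier,
  # so E[Q_ST] tracks the realized F_ST in every within- and
  # between-species comparison.
  P <- length(traitPops)
  spOf <- pm$species[match(traitPops, pm$population)]
  species <- unique(spOf)
  mult <- cfg$selectionMultiplier
  fFac <- function(F) mult * 2 * F / (1 - F)
  sameSp <- outer(spOf, spOf, "==")
  ut <- upper.tri(Fij)
  wAll <- mean(Fij[sameSp & ut])
  wFac <- vapply(species, function(s2) {
    sel <- sameSp & ut & outer(spOf == s2, spOf == s2, "&")
    if (any(sel)) fFac(mean(Fij[sel])) else fFac(wAll)
  }, 0)
  S <- length(species)
  dFac <- matrix(0, S, S)
  for (i in seq_len(S - 1)) for (j in seq(i + 1, S)) {
    bf <- fFac(mean(Fij[outer(spOf == species[i], spOf == species[j])]))
    dFac[i, j] <- dFac[j, i] <- max(0, 2 * bf - wFac[i] - wFac[j])
  }
  J <- diag(S) - matrix(1 / S, S, S)
  Csp <- -0.5 * J %*% dFac %*% J
  evSp <- eigen(Csp, symmetric = TRUE)
  lamSp <- pmax(evSp$values, 0)
  spIdx <- match(spOf, species)
  popEffects <- function(sigmaW2) {
    spEff <- drop(evSp$vectors %*% (sqrt(lamSp) * rnorm(S))) * sqrt(sigmaW2)
    spEff[spIdx] + rnorm(P, 0, sqrt(sigmaW2 * wFac[spIdx]))
  }

  rows <- list()
  nms <- names(cfg$traitMeans)
  effs <- list()
  indVals <- list()
  for (tr in nms) {
    logScale <- tr %in% cfg$logNormalTraits
    if (logScale) {
      sw2 <- cfg$traitSdLog^2
      eff <- popEffects(sw2)
      base <- log(cfg$traitMeans[[tr]])
    } else {
      sw2 <- (cfg$traitCVwithin * cfg$traitMeans[[tr]])^2
      eff <- popEffects(sw2)
      base <- cfg$traitMeans[[tr]]
    }
    effs[[tr]] <- setNames(eff, traitPops)
    indVals[[tr]] <- list(sw2 = sw2, base = base, logScale = logScale)
  }

  for (p in traitPops) {
    inds <- pm$individual[pm$population == p]
    inds <- inds[seq_len(min(cfg$traitIndPerPop, length(inds)))]
    for (ind in inds) {
      iv <- vapply(nms, function(tr) {
        v <- indVals[[tr]]
        v$base + effs[[tr]][[p]] + rnorm(1, 0, sqrt(v$sw2))
      }, 0)
      for (f in seq_len(cfg$flowersPerInd)) {
        fv <- vapply(nms, function(tr) {
          v <- indVals[[tr]]
          x <- iv[[tr]] + rnorm(1, 0, cfg$traitCVmeasure *
                                  (if (v$logScale) cfg$traitSdLog else
                                     cfg$traitMeans[[tr]]))
          # measured dimensions cannot go non-positive: strong divergent-
          # selection settings saturate at a small positive floor
          if (v$logScale) exp(x) else max(x, 0.05 * cfg$traitMeans[[tr]])
        }, 0)
        rows[[length(rows) + 1]] <- data.frame(
          individual = ind, population = p, flower = f,
          as.list(setNames(fv, nms)))
      }
    }
  }
  d <- do.call(rbind, rows)
  new("TraitMatrix", data = d, traitNames = nms)
}

#' Generate a pseudo-observed dataset under a known scenario
#'
#' One multilocus dataset formatted like observed input, tagged with its
#' generating scenario - the workhorse of model-recovery experiments for
#' the ABC and gsi stages.
#'
#' @param model a \code{DemographicModel} (the true scenario).
#' @param sampleSizes named haplotype counts per extant deme.
#' @param loci loci plan as in \code{\link{simulateMultilocus}}.
#' @param seed optional seed.
#' @return list with \code{alignments}, \code{genealogies},
#'   \code{trueScenario}.
#' @export
generatePseudoObserved <- function(model, sampleSizes, loci, seed = NULL) {
  sim <- simulateMultilocus(model, sampleSizes, loci, seed = seed)
  list(alignments = sim$alignments, genealogies = sim$genealogies,
       trueScenario = scenarioTag(model))
}
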