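# shared fixture builders: everything is generated in code at test time

mkAln <- function(seqs, demes, locusId = "toy", copy = NULL) {
  n <- length(seqs)
  if (is.null(copy)) copy <- rep(1L, n)
  new("HaplotypeAlignment", locusId = locusId,
      seqs = Biostrings::DNAStringSet(seqs),
      individual = paste0(demes, "_", seq_len(n)),
      copy = as.integer(copy), deme = demes)
}

# single panmictic deme of diploid size N (two demes with zero-age split)
panmicticModel <- function(N = 500) {
  buildScenario("(A:0,B:0);", demeSizes = N, scenario = "zero")
}

twoDemeModel <- function(tDiv, N = 500, scenario = "zero", rate2Nm = 1,
                         epochFraction = 0.5) {
  buildScenario(sprintf("(A:%d,B:%d);", tDiv, tDiv), demeSizes = N,
                scenario = scenario, rate2Nm = rate2Nm,
                epochFraction = epochFraction)
}

fourDemeSuite <- function(N = 500, rate2Nm = 1) {
  top <- paste0("(((EX:", 5 * N, ",PAS:", 5 * N, "):", N, ",EbuW:", 6 * N,
                "):", 2 * N, ",Lut:", 8 * N, ");")
  buildScenarioSuite(top, demeSizes = N, rate2Nm = rate2Nm)
}

# toy genotype matrix from explicit call strings
mkGeno <- function(calls, pops, species = NULL, lineage = NULL) {
  n <- nrow(calls)
  if (is.null(species)) species <- pops
  if (is.null(lineage)) lineage <- species
  pm <- data.frame(individual = paste0("i", seq_len(n)), population = pops,
                   species = species, lineage = lineage)
  rownames(calls) <- pm$individual
  new("GenotypeMatrix", calls = calls, popmap = pm)
}

# small synthetic study configuration used where a full-size study would be
# wasteful; the trait model and all estimator settings stay at defaults
smallStudyConfig <- function(...) {
  cfg <- studyConfig(...)
  cfg$popsPerSpecies <- c(EbuW = 4, Lut = 2, Pol = 2, Alu = 2, Sui = 2,
                          EbuE = 3, Xiz = 2)
  cfg$indRange <- c(4L, 6L)
  cfg$lociLengths <- c(700L, 900L)
  cfg$nSnps <- 120
  cfg$traitPopsPerSpecies <- c(EbuW = 4, EbuE = 3, Pol = 2, Alu = 2, Sui = 2)
  cfg$traitIndPerPop <- 5L
  cfg
}

# independent gsi oracle: igraph path-union evaluation of the uniting walk
gsiOracle <- function(tree, groupTips) {
  ntip <- length(tree$tip.label)
  g <- igraph::graph_from_edgelist(tree$edge, directed = TRUE)
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])
  paths <- lapply(groupTips, function(tp)
    as.integer(igraph::shortest_paths(g, from = root, to = tp,
                                      mode = "out")$vpath[[1]]))
  # MRCA: last node common to all root->tip paths
  common <- Reduce(intersect, paths)
  depth <- vapply(common, function(v) which(paths[[1]] == v), 0L)
  mrca <- common[which.max(depth)]
  U <- unique(unlist(lapply(paths, function(p) {
    i <- which(p == mrca)
    p[seq(i, length(p))]
  })))
  U <- setdiff(U, groupTips)
  gs <- (length(groupTips) - 1) / length(U)
  minGs <- (length(groupTips) - 1) / (ntip - 1)
  list(gs = gs, gsi = (gs - minGs) / (1 - minGs))
}

# all rooted binary labelled topologies on n tips (via phangorn)
allRootedTrees <- function(n) {
  phangorn::allTrees(n, rooted = TRUE, tip.label = letters[seq_len(n)])
}
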