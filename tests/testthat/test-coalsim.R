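# structured coalescent: calibration, determinism, degenerate limits

treeHeight <- function(tr) max(attr(tr, "nodeTime"))

test_that("every simulated genealogy is ultrametric with the right tip count", {
  suite <- fourDemeSuite()
  for (sc in names(suite)) {
    tr <- simulateGenealogy(suite[[sc]],
                            c(EX = 3, PAS = 3, EbuW = 3, Lut = 3),
                            seed = 17)
    expect_s3_class(tr, "phylo")
    expect_length(tr$tip.label, 12)
    nt <- attr(tr, "nodeTime")
    depth <- ape::node.depth.edgelength(tr)
    tipDepth <- depth[seq_len(12)]
    expect_lt(max(tipDepth) - min(tipDepth), 1e-9 * treeHeight(tr))
    expect_true(all(diff(sort(nt[nt > 0])) >= 0))
  }
})

test_that("mean TMRCA of a panmictic pair is 2N (reduced-scale calibration)", {
  m <- panmicticModel(N = 400)
  h <- withr::with_seed(5, replicate(4000, {
    treeHeight(simulateGenealogy(m, c(A = 1, B = 1)))
  }))
  se <- sd(h) / sqrt(length(h))
  expect_lt(abs(mean(h) - 800), 3 * se)
})

test_that("zero-age split of two demes behaves like one panmictic deme", {
  mSplit <- twoDemeModel(0, N = 300)
  mPan <- panmicticModel(N = 300)
  hs <- withr::with_seed(7, replicate(1500,
    treeHeight(simulateGenealogy(mSplit, c(A = 3, B = 3)))))
  hp <- withr::with_seed(8, replicate(1500,
    treeHeight(simulateGenealogy(mPan, c(A = 3, B = 3)))))
  expect_gt(suppressWarnings(ks.test(hs, hp))$p.value, 0.01)
})

test_that("deme order in the sampling request does not change the height distribution", {
  m <- twoDemeModel(1000, N = 300, scenario = "constant")
  h1 <- withr::with_seed(9, replicate(1500,
    treeHeight(simulateGenealogy(m, c(A = 4, B = 2)))))
  h2 <- withr::with_seed(10, replicate(1500,
    treeHeight(simulateGenealogy(m, c(B = 2, A = 4)))))
  expect_gt(suppressWarnings(ks.test(h1, h2))$p.value, 0.01)
})

test_that("deep divergence without migration sorts demes to reciprocal monophyly", {
  m <- twoDemeModel(20 * 2 * 100, N = 100) # t_div = 20 x (2N)
  mono <- withr::with_seed(11, replicate(400, {
    tr <- simulateGenealogy(m, c(A = 5, B = 5))
    dem <- attr(tr, "tipDeme")
    computeGsi(tr, which(dem == "A"))$monophyletic &&
      computeGsi(tr, which(dem == "B"))$monophyletic
  }))
  expect_gt(mean(mono), 0.97)
})

test_that("pairwise coalescent times match the analytic isolation model", {
  # two demes, sizes N, split t, ancestor Na, no migration:
  # E[T_within] = 2N(1 - exp(-t/2N)) + 2Na exp(-t/2N); E[T_between] = t + 2Na
  N <- 300; Na <- 600; t <- 800
  m <- buildScenario("(A:800,B:800);",
                     demeSizes = c(A = N, B = N, anc1 = Na),
                     scenario = "zero")
  hw <- hb <- numeric(3000)
  withr::with_seed(12, {
    for (i in seq_along(hw)) {
      tr <- simulateGenealogy(m, c(A = 2, B = 1))
      nt <- attr(tr, "nodeTime")
      dem <- attr(tr, "tipDeme")
      ia <- which(dem == "A")
      hw[i] <- nt[ape::getMRCA(tr, ia)]
      hb[i] <- nt[ape::getMRCA(tr, c(ia[1], which(dem == "B")))]
    }
  })
  expW <- 2 * N * (1 - exp(-t / (2 * N))) + 2 * Na * exp(-t / (2 * N))
  expB <- t + 2 * Na
  # sampling consistency: marginal pair coalescence times are unaffected by
  # the other sampled lineages, so both means are exact expectations
  expect_lt(abs(mean(hw) - expW), 3.5 * sd(hw) / sqrt(length(hw)))
  expect_lt(abs(mean(hb) - expB), 3.5 * sd(hb) / sqrt(length(hb)))
})

test_that("mutation stage reproduces Watterson's E[S] (reduced scale)", {
  m <- panmicticModel(N = 500)
  mm <- mutationModel("infinite_sites", theta = 5, refN = 500)
  S <- withr::with_seed(13, replicate(1500, {
    g <- simulateGenealogy(m, c(A = 5, B = 5))
    a <- mutateAlignment(g, mm, 1000)
    seqDiversity(a)$S
  }))
  an <- sum(1 / seq_len(9))
  expect_lt(abs(mean(S) - 5 * an), 3 * sd(S) / sqrt(length(S)))
})

test_that("vanishing mutation rate gives zero segregating sites", {
  m <- panmicticModel()
  g <- simulateGenealogy(m, c(A = 4, B = 4), seed = 3)
  a <- mutateAlignment(g, mutationModel("infinite_sites", mu = 1e-12), 500,
                       seed = 4)
  expect_equal(seqDiversity(a)$S, 0)
  aj <- mutateAlignment(g, mutationModel("jc69", mu = 1e-12), 500, seed = 4)
  expect_equal(seqDiversity(aj)$S, 0)
})

test_that("infinite-sites overflow fails loudly", {
  m <- panmicticModel(N = 5000)
  g <- simulateGenealogy(m, c(A = 10, B = 10), seed = 5)
  expect_error(mutateAlignment(g, mutationModel("infinite_sites", theta = 500,
                                                refN = 5000), 10, seed = 6),
               "overflow")
})

test_that("alignments are byte-identical under a fixed seed", {
  m <- twoDemeModel(2000, N = 400, scenario = "constant")
  g <- simulateGenealogy(m, c(A = 6, B = 6), seed = 21)
  for (mode in c("infinite_sites", "jc69")) {
    mm <- mutationModel(mode, theta = 4, refN = 400)
    a1 <- mutateAlignment(g, mm, 800, seed = 22)
    a2 <- mutateAlignment(g, mm, 800, seed = 22)
    expect_identical(as.matrix(a1), as.matrix(a2))
    expect_true(all(as.matrix(a1) %in% c("A", "C", "G", "T")))
  }
})

test_that("multilocus simulation echoes locus lengths and keeps per-locus streams stable", {
  m <- fourDemeSuite()$historical
  ss <- c(EX = 2, PAS = 2, EbuW = 2, Lut = 2)
  loci <- data.frame(length = c(669L, 915L, 1197L), theta = c(3, 4, 5))
  r1 <- simulateMultilocus(m, ss, loci, seed = 30)
  expect_length(r1$alignments, 3)
  expect_equal(vapply(r1$alignments,
                      function(a) Biostrings::width(a@seqs)[1], 0L),
               c(L01 = 669L, L02 = 915L, L03 = 1197L))
  r2 <- simulateMultilocus(m, ss, loci, seed = 30)
  expect_identical(lapply(r1$alignments, as.matrix),
                   lapply(r2$alignments, as.matrix))
  # adding a locus must not perturb earlier loci
  r3 <- simulateMultilocus(m, ss, rbind(loci,
                                        data.frame(length = 700L, theta = 2)),
                           seed = 30)
  expect_identical(as.matrix(r1$alignments[[2]]), as.matrix(r3$alignments[[2]]))
})

test_that("simulation requests are validated", {
  m <- panmicticModel()
  expect_error(simulateGenealogy(m, c(A = 2, Z = 2)), "named by extant demes")
  expect_error(simulateGenealogy(m, c(A = 0, B = 2)), ">= 1")
  expect_error(simulateMultilocus(m, c(A = 2, B = 2), list()), "at least one")
})
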