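# genealogical sorting index: oracle agreement and distributional behaviour

test_that("monophyletic groups score exactly 1", {
  trees <- c("((a,b),(c,d));", "(((a,b),c),(d,(e,f)));",
             "((((a,b),c),d),e);")
  for (nw in trees) {
    tr <- ape::read.tree(text = nw)
    r <- computeGsi(tr, c("a", "b"))
    expect_equal(r$gsi, 1)
    expect_true(r$monophyletic)
  }
})

test_that("breaking monophyly pushes gsi strictly inside (0, 1)", {
  tr <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  r <- computeGsi(tr, c("a", "b", "c", "e")) # one tip swapped out of a clade
  expect_lt(r$gsi, 1)
  expect_gt(r$gsi, 0)
  expect_false(r$monophyletic)
})

test_that("maximally dispersed groups on a caterpillar tree score 0", {
  tr <- ape::read.tree(text = "((((((a,b),c),d),e),f),g);")
  # alternating tips force the uniting walk through every internal node
  r <- computeGsi(tr, c("a", "c", "e", "g"))
  expect_equal(r$gsi, 0)
})

test_that("gs and gsi agree with the independent path-union oracle on all small trees", {
  for (n in 5:6) {
    trees <- allRootedTrees(n)
    groups <- utils::combn(letters[seq_len(n)], 3, simplify = FALSE)
    set.seed(n)
    groups <- groups[sample(length(groups), 5)]
    for (ti in seq_along(trees)) {
      tr <- trees[[ti]]
      for (g in groups) {
        mine <- computeGsi(tr, g)
        ref <- gsiOracle(tr, match(g, tr$tip.label))
        expect_equal(mine$gs, ref$gs)
        expect_equal(mine$gsi, ref$gsi)
        expect_identical(mine$monophyletic,
                         ape::is.monophyletic(tr, g))
      }
    }

  }
})

test_that("gsi is invariant to tip-label permutations within group and complement", {
  set.seed(3)
  tr <- ape::rtree(12)
  tr$edge.length <- NULL
  grp <- c("t1", "t2", "t3", "t4")
  base <- computeGsi(tr, grp)$gsi
  # permute labels within the complement
  tr2 <- tr
  comp <- setdiff(tr$tip.label, grp)
  tr2$tip.label[match(comp, tr$tip.label)] <- sample(comp)
  expect_equal(computeGsi(tr2, grp)$gsi, base)
  # permute labels within the group
  tr3 <- tr
  tr3$tip.label[match(grp, tr$tip.label)] <- sample(grp)
  expect_equal(computeGsi(tr3, grp)$gsi, base)
})

test_that("degenerate groups and polytomies are rejected", {
  tr <- ape::read.tree(text = "((a,b),(c,d));")
  expect_error(computeGsi(tr, "a"), "between 2")
  expect_error(computeGsi(tr, c("a", "b", "c", "d")), "between 2")
  expect_error(computeGsi(tr, c("a", "zz")), "not in tree")
  poly <- ape::read.tree(text = "((a,b,c),(d,e));")
  expect_error(computeGsi(poly, c("a", "b")), "polytomies")
})

test_that("permutation p-values reward well-sorted groups", {
  tr <- ape::read.tree(text = "(((a,b),(c,d)),((e,f),(g,h)));")
  pMono <- computeGsi(tr, c("a", "b", "c", "d"), nPerm = 199, seed = 5)$pvalue
  expect_lt(pMono, 0.05)
  pBad <- computeGsi(tr, c("a", "e"), nPerm = 199, seed = 6)$pvalue
  expect_gt(pBad, 0.1)
  expect_lte(pBad, 1)
})

test_that("simulated gsi distributions track the gene-flow scenarios", {
  suite <- fourDemeSuite(N = 250)
  ss <- c(EX = 4, PAS = 4, EbuW = 4, Lut = 4)
  tab <- gsiScenarios(suite, sampleSizes = ss, nTrees = 300, seed = 91)
  expect_setequal(unique(tab$scenario), names(suite))
  expect_true(all(tab$mean >= 0 & tab$mean <= 1))
  zero <- tab[tab$scenario == "zero", ]
  konst <- tab[tab$scenario == "constant", ]
  rec <- tab[tab$scenario == "recent", ]
  # deep zero-migration divergence sorts to near-monophyly
  expect_true(all(zero$mean > 0.85))
  # constant and recent allow present-day migration: both well below zero's
  expect_true(all(konst$mean < zero$mean - 0.2))
  # and their distributions coincide (same recent coalescent behaviour)
  expect_true(all(abs(konst$mean - rec$mean) <
                    3 * sqrt(konst$se^2 + rec$se^2) + 0.02))
})

test_that("mean simulated gsi is non-increasing in migration rate", {
  ss <- c(A = 5, B = 5)
  means <- vapply(c(0, 0.5, 2, 8), function(r) {
    m <- twoDemeModel(3000, N = 300,
                      scenario = if (r == 0) "zero" else "constant",
                      rate2Nm = r)
    tab <- gsiScenarios(list(m = m), groups = list(A = "A"),
                        sampleSizes = ss, nTrees = 250, seed = 92 + r)
    tab$mean
  }, 0)
  ses <- 0.03
  expect_true(all(diff(means) < 2 * ses))
  expect_lt(means[4], means[1])
})

test_that("single-tree simulation mode flags undefined spread", {
  m <- twoDemeModel(2000, N = 200)
  tab <- gsiScenarios(list(zero = m), groups = list(A = "A"),
                      sampleSizes = c(A = 3, B = 3), nTrees = 1, seed = 93)
  expect_true(is.na(tab$sd))
  expect_true(is.na(tab$se))
})

test_that("an empirical tree is placed alongside the simulated distributions", {
  m <- twoDemeModel(6000, N = 200)
  emp <- simulateGenealogy(m, c(A = 4, B = 4), seed = 94)
  tab <- gsiScenarios(list(zero = m), groups = list(A = "A", B = "B"),
                      sampleSizes = c(A = 4, B = 4), nTrees = 50, seed = 95,
                      empirical = emp)
  expect_true("empirical" %in% tab$scenario)
  expect_equal(sum(tab$scenario == "empirical"), 2)
})
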