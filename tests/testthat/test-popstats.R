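# sequence and SNP statistics against brute-force oracles

test_that("sequence diversity matches forced values on tiny alignments", {
  a0 <- mkAln(rep("ACGTACGTAC", 4), rep("X", 4))
  s0 <- seqDiversity(a0)
  expect_equal(unlist(s0[c("S", "h", "Hd", "pi")]),
               c(S = 0, h = 1, Hd = 0, pi = 0))
  a1 <- mkAln(c("AAAAAAAAAA", "AAAAAAAAAT"), c("X", "X"))
  s1 <- seqDiversity(a1)
  expect_equal(unlist(s1[c("S", "h", "Hd", "pi")]),
               c(S = 1, h = 2, Hd = 1, pi = 0.1))
  expect_error(seqDiversity(a1, stratum = "missing"), "2 haplotypes")
})

test_that("Hd and pi are invariant to row order and allele relabelling", {
  set.seed(41)
  seqs <- replicate(8, paste(sample(c("A", "C", "G", "T"), 30, TRUE),
                             collapse = ""))
  a <- mkAln(seqs, rep("X", 8))
  s <- seqDiversity(a)
  aPerm <- mkAln(seqs[8:1], rep("X", 8))
  expect_equal(seqDiversity(aPerm)[c("Hd", "pi", "S", "h")],
               s[c("Hd", "pi", "S", "h")])
  relab <- chartr("ACGT", "TGCA", seqs)
  expect_equal(seqDiversity(mkAln(relab, rep("X", 8)))[c("Hd", "pi", "S", "h")],
               s[c("Hd", "pi", "S", "h")])
})

test_that("gaps and ambiguities are excluded by pairwise deletion", {
  a <- mkAln(c("AAAAAAAAAA", "AAAAA-AAAN", "TAAAAAAAAA"), rep("X", 3))
  s <- seqDiversity(a)
  expect_equal(s$S, 1)
  # pairs: (1,2): 0/8; (1,3): 1/10; (2,3): 1/8
  expect_equal(s$pi, mean(c(0, 1 / 10, 1 / 8)))
})

test_that("Tajima's D equals an independent brute-force evaluation", {
  set.seed(42)
  seqs <- replicate(6, paste(sample(c("A", "T"), 20, TRUE, prob = c(.8, .2)),
                             collapse = ""))
  a <- mkAln(seqs, rep("X", 6))
  D <- tajimasD(a)
  # brute force, written out from the canonical constants
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- 6
  S <- sum(apply(m, 2, function(cc) length(unique(cc)) > 1))
  diffs <- c()
  for (i in 1:5) for (j in (i + 1):6) diffs <- c(diffs, sum(m[i, ] != m[j, ]))
  piT <- mean(diffs)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  Dref <- (piT - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
  expect_equal(D, Dref)
  expect_true(is.finite(D))
})

test_that("Tajima's D edge cases are flagged, not fabricated", {
  aMono <- mkAln(rep("ACGT", 5), rep("X", 5))
  d <- tajimasD(aMono)
  expect_true(is.na(d))
  expect_match(attr(d, "reason"), "segregating")
  aSmall <- mkAln(c("AAAA", "AAAT", "AATT"), rep("X", 3))
  expect_error(tajimasD(aSmall), "at least 4")
})

test_that("neutral equilibrium simulations give Tajima's D near zero (reduced scale)", {
  m <- panmicticModel(N = 500)
  mm <- mutationModel("infinite_sites", theta = 5, refN = 500)
  D <- withr::with_seed(14, replicate(400, {
    g <- simulateGenealogy(m, c(A = 10, B = 10))
    tajimasD(mutateAlignment(g, mm, 2000))
  }))
  expect_lt(abs(mean(D, na.rm = TRUE)), 0.15)
})

test_that("SNP diversity matches forced values and a brute-force toy", {
  hom <- mkGeno(matrix("A/A", 4, 3), rep(c("P1", "P2"), each = 2))
  s <- snpDiversity(hom)
  expect_equal(unlist(s[c("PPL", "A", "Ae", "Ho", "He")]),
               c(PPL = 0, A = 1, Ae = 1, Ho = 0, He = 0))
  het <- mkGeno(matrix("A/G", 4, 1), rep("P1", 4))
  s2 <- snpDiversity(het)
  expect_equal(unlist(s2[c("Ho", "He", "Fis")]), c(Ho = 1, He = 0.5, Fis = -1))
  # 2-locus, 4-individual brute force
  calls <- matrix(c("A/A", "A/G", "G/G", "A/G",
                    "C/C", "C/C", "C/T", "C/C"), 4, 2)
  gm <- mkGeno(calls, rep("P1", 4))
  s3 <- snpDiversity(gm)
  # locus 1: p_A = 0.5 -> He = .5, Ho = .5, Ae = 2; locus 2: p_C = 7/8 ->
  # He = 2*7/64 = .21875, Ho = .25, Ae = 1/(49/64+1/64)
  expect_equal(s3$A, 2)
  expect_equal(s3$Ae, mean(c(2, 64 / 50)))
  expect_equal(s3$Ho, mean(c(0.5, 0.25)))
  expect_equal(s3$He, mean(c(0.5, 0.21875)))
  expect_equal(s3$Fis, mean(c((0.5 - 0.5) / 0.5,
                              (0.21875 - 0.25) / 0.21875)))
  expect_equal(s3$PPL, 100)
})

test_that("genotype filtering removes loci then individuals, and is idempotent", {
  # 3 loci with MAF {0, 0.05 on observed, 0.30}; locus 2 has MAF below 0.01
  # only when computed over all 10 individuals
  calls <- cbind(rep("A/A", 10),
                 c("A/G", rep("A/A", 9)),
                 c(rep("C/T", 3), rep("C/C", 7)))
  calls[calls == "A/G"] <- "A/A" # locus 2 now monomorphic -> MAF 0
  calls[1, 3] <- NA              # individual 1 missing its only kept locus
  gm <- mkGeno(calls, rep("P1", 10))
  f <- filterGenotypes(gm, mafMin = 0.01, missingMax = 0.10)
  rep <- attr(f, "filterReport")
  expect_equal(rep$lociKept, 1)
  expect_equal(rep$individualsKept, 9)
  expect_false("i1" %in% rownames(genotypeCalls(f)))
  f2 <- filterGenotypes(f, mafMin = 0.01, missingMax = 0.10)
  expect_identical(genotypeCalls(f2), genotypeCalls(f))
  expect_error(filterGenotypes(mkGeno(matrix("A/A", 4, 2), rep("P", 4))),
               "all loci removed")
})

test_that("pairwise F_ST hits the null and fixation endpoints", {
  # one panmictic pool split into two arbitrary labels
  m <- panmicticModel(N = 500)
  sim <- simulateMultilocus(m, c(A = 25, B = 25),
                            data.frame(length = rep(800L, 40),
                                       theta = rep(5, 40)), seed = 55)
  r <- pairwiseFst(sim$alignments, nPerm = 199, seed = 56)
  expect_lt(abs(r$fst["A", "B"]), 0.02)
  expect_gt(r$pvalues["A", "B"], 0.05)
  # fixed alternative alleles
  aFix <- mkAln(c(rep("AAAAAAAAAA", 3), rep("TTTTTTTTTT", 3)),
                rep(c("P1", "P2"), each = 3))
  rf <- pairwiseFst(aFix, nPerm = 0)
  expect_equal(rf$fst["P1", "P2"], 1)
  # SNP route endpoints
  gFix <- mkGeno(cbind(rep(c("A/A", "T/T"), each = 3),
                       rep(c("C/C", "G/G"), each = 3)),
                 rep(c("P1", "P2"), each = 3))
  rs <- pairwiseFst(gFix, nPerm = 0)
  expect_equal(rs$fst["P1", "P2"], 1)
  expect_identical(rs$estimator, "WC")
})

test_that("Weir-Cockerham theta matches a hand-computed single-locus case", {
  # two pops of 4, locus with p1 = 0.75, p2 = 0.25, all heterozygotes at
  # the minor-allele carriers: spelled-out 1984 components
  calls <- cbind(c("A/A", "A/A", "A/G", "A/G", "G/G", "G/G", "A/G", "A/G"))
  gm <- mkGeno(calls, rep(c("P1", "P2"), each = 4))
  r <- pairwiseFst(gm, nPerm = 0)
  ni <- c(4, 4); pi <- c(0.75, 0.25); hi <- c(0.5, 0.5); rr <- 2
  nbar <- 4; nc <- (2 * nbar - sum(ni^2) / (2 * nbar)) / 1; pbar <- 0.5
  s2 <- sum(ni * (pi - pbar)^2) / ((rr - 1) * nbar)
  hbar <- 0.5
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) /
                              (4 * nbar) * hbar)
  cc <- hbar / 2
  expect_equal(r$fst["P1", "P2"], a / (a + b + cc))
})

test_that("units with a single sample are skipped and flagged", {
  a <- mkAln(c("AAAA", "AATT", "TTTT", "TTAA", "ATAT"),
             c("P1", "P1", "P2", "P2", "P3"))
  r <- pairwiseFst(a, nPerm = 0)
  expect_true(is.na(r$fst["P1", "P3"]))
  expect_false(is.na(r$fst["P1", "P2"]))
})

test_that("AMOVA components equal hand-computed sums of squares on a toy", {
  # 2 populations x 2 haplotypes; distances hand-enumerated
  a <- mkAln(c("AAAAAAAAAA", "AAAAAAAAAT", "TTTTTTTTAA", "TTTTTTTTAT"),
             c("P1", "P1", "P2", "P2"))
  r <- amova(a, nPerm = 0)
  # count distances: within pairs 1; across pairs 8,9,9,8 (x squared)
  d2w <- 1^2
  ssdTot <- (d2w + d2w + 8^2 + 9^2 + 9^2 + 8^2) / 4
  ssdWP <- d2w / 2 + d2w / 2
  ssdAP <- ssdTot - ssdWP
  expect_equal(r$table$SSD, c(ssdAP, ssdWP))
  msAP <- ssdAP / 1; msWP <- ssdWP / 2
  sigW <- msWP; sigA <- (msAP - msWP) / 2
  expect_equal(r$table$sigma2, c(sigA, sigW))
  expect_equal(unname(r$phi["PhiST"]), sigA / (sigA + sigW))
  expect_equal(sum(r$table$percent), 100)
})

test_that("two-level AMOVA decomposes into three components that sum to 100%", {
  set.seed(77)
  suite <- fourDemeSuite(N = 300)
  sim <- simulateMultilocus(suite$zero,
                            c(EX = 6, PAS = 6, EbuW = 6, Lut = 6),
                            data.frame(length = 800L, theta = 5), seed = 78)
  groups <- c(EX = "east", PAS = "east", EbuW = "west", Lut = "west")
  r <- amova(sim$alignments, groups = groups, nPerm = 99, seed = 79)
  expect_equal(nrow(r$table), 3)
  expect_equal(sum(r$table$percent), 100, tolerance = 1e-9)
  expect_named(r$phi, c("PhiCT", "PhiSC", "PhiST"))
  expect_true(all(r$pvalues >= 0 & r$pvalues <= 1))
  expect_equal(r$table$df, c(2 - 1, 4 - 2, 24 - 4))
  # clamped view renormalises to 100
  expect_equal(sum(r$clamped$percent), 100, tolerance = 1e-9)
})

test_that("1-level AMOVA Phi_ST equals pairwise F_ST on two-unit input", {
  a <- mkAln(c("AAAAAAAAAA", "AAAAAATTAT", "TATTTTTTAA", "TTTTTTTTAT",
               "AATAAATTAT", "TATTATTTAA"),
             c("P1", "P1", "P2", "P2", "P1", "P2"))
  r1 <- amova(a, nPerm = 0)
  r2 <- pairwiseFst(a, nPerm = 0)
  expect_equal(unname(r1$phi["PhiST"]), r2$fst["P1", "P2"], tolerance = 1e-9)
})

test_that("mean F_ST decreases with migration under the island-like model", {
  rates <- c(0.1, 1, 4, 16)
  means <- vapply(rates, function(r2nm) {
    m <- twoDemeModel(4000, N = 500, scenario = "constant", rate2Nm = r2nm)
    f <- withr::with_seed(100 + round(r2nm * 10), replicate(120, {
      sim <- simulateMultilocus(m, c(A = 6, B = 6),
                                data.frame(length = 600L, theta = 4))
      lineageFstSummary(sim$alignments)
    }))
    mean(f)
  }, 0)
  expect_true(all(diff(means) < 0))
})

test_that("multilocus diversity table aggregates dnasp-style and by concatenation", {
  m <- twoDemeModel(3000, N = 400)
  sim <- simulateMultilocus(m, c(A = 8, B = 8),
                            data.frame(length = c(600L, 800L), theta = c(4, 5)),
                            seed = 61)
  tab <- seqDiversityTable(sim$alignments)
  expect_setequal(tab$stratum, c("A", "B"))
  perLocus <- lapply(sim$alignments, function(x) seqDiversity(x, "A"))
  expect_equal(tab$S[tab$stratum == "A"],
               sum(vapply(perLocus, function(x) x$S, 0)))
  expect_equal(tab$Hd[tab$stratum == "A"],
               mean(vapply(perLocus, function(x) x$Hd, 0)))
  tabC <- seqDiversityTable(sim$alignments, concat = TRUE)
  expect_true(all(tabC$S >= 0))
  # lineage-level grouping via a deme -> unit map
  tabL <- seqDiversityTable(sim$alignments, by = c(A = "L1", B = "L1"))
  expect_identical(tabL$stratum, "L1")
})
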