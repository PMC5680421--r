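# trait preprocessing, PCA and Q_ST machinery

mkTraits <- function(vals, pops, inds = NULL, flowers = 1L) {
  if (is.null(inds)) inds <- paste0(pops, "_", seq_along(pops))
  d <- do.call(rbind, lapply(seq_len(flowers), function(f)
    data.frame(individual = inds, population = pops, flower = f, vals)))
  new("TraitMatrix", data = d, traitNames = setdiff(names(d),
      c("individual", "population", "flower")))
}

test_that("normality screening log-transforms skewed traits and keeps normal ones", {
  set.seed(11)
  n <- 500
  d <- data.frame(norm = rnorm(n, 20, 2), lnorm = exp(rnorm(n, 2, 0.6)))
  tm <- mkTraits(d, rep(paste0("P", 1:10), each = 50))
  out <- preprocessTraits(tm)
  rep <- attr(out, "report")
  expect_identical(rep$action[rep$trait == "norm"], "kept")
  expect_identical(rep$action[rep$trait == "lnorm"], "log-transformed")
  expect_true("log_lnorm" %in% traitNames(out))
  # post-transform values are in fact near-normal
  x <- traitData(out)$log_lnorm
  expect_gt(suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))$p.value,
            0.05)
})

test_that("constant traits are flagged and excluded, not transformed", {
  d <- data.frame(flat = rep(5, 40), ok = rnorm(40, 10))
  tm <- mkTraits(d, rep(c("P1", "P2"), each = 20))
  out <- preprocessTraits(tm)
  expect_false("flat" %in% traitNames(out))
  rep <- attr(out, "report")
  expect_match(rep$action[rep$trait == "flat"], "constant")
})

test_that("PCA: perfectly correlated traits load on a single component", {
  set.seed(12)
  base <- rnorm(30, 10, 1)
  d <- data.frame(t1 = base, t2 = 2 * base + 3)
  tm <- mkTraits(d, rep(c("P1", "P2", "P3"), each = 10))
  pc <- traitPca(tm)
  expect_equal(pc$varExplained[1], 1, tolerance = 1e-10)
  expect_equal(pc$rank, 1)
})

test_that("PCA: isotropic traits spread variance evenly over components", {
  set.seed(13)
  d <- as.data.frame(matrix(rnorm(5 * 800, mean = 50), 800, 5))
  names(d) <- paste0("t", 1:5)
  tm <- mkTraits(d, rep(paste0("P", 1:8), each = 100))
  pc <- traitPca(tm)
  expect_true(all(abs(pc$varExplained - 0.2) < 0.05))
})

test_that("Q_ST endpoints are forced by construction", {
  set.seed(14)
  # identical population means
  v0 <- rnorm(60, 10, 1)
  q0 <- estimateQst(values = v0, populations = rep(paste0("P", 1:6), each = 10))
  expect_lt(q0$qst, 0.2)
  # no within-population variance, distinct means
  v1 <- rep(c(1, 2, 3), each = 10)
  q1 <- estimateQst(values = v1, populations = rep(paste0("P", 1:3), each = 10))
  expect_equal(q1$qst, 1)
  expect_error(estimateQst(values = v0, populations = rep("P1", 60)),
               "at least 2")
})

test_that("Q_ST equals the hand-computed balanced-design formula", {
  set.seed(15)
  v <- rnorm(12, rep(c(0, 3, 5), each = 4))
  pops <- rep(c("P1", "P2", "P3"), each = 4)
  q <- estimateQst(values = v, populations = pops)
  av <- anova(lm(v ~ pops)) # independent arithmetic route
  msb <- av$`Mean Sq`[1]; msw <- av$`Mean Sq`[2]
  sigB <- max(0, (msb - msw) / 4)
  expect_equal(q$qst, sigB / (sigB + 2 * msw))
  expect_equal(q$sigmaW, msw)
})

test_that("Q_ST is invariant to positive rescaling of the trait", {
  set.seed(16)
  v <- rnorm(40, rep(c(0, 2, 4, 9), each = 10))
  pops <- rep(paste0("P", 1:4), each = 10)
  q1 <- estimateQst(values = v, populations = pops)$qst
  q2 <- estimateQst(values = 7.3 * v, populations = pops)$qst
  expect_equal(q1, q2)
  expect_equal(meanPairwiseQst(v, pops), meanPairwiseQst(7.3 * v, pops))
})

test_that("vectorized pairwise Q_ST agrees with the scalar two-population ANOVA", {
  set.seed(17)
  v <- rnorm(50, rep(c(0, 1, 3, 6, 10), each = 10))
  pops <- rep(paste0("P", 1:5), each = 10)
  ratioMean <- meanPairwiseQst(v, pops, aggregate = "ratios")
  qs <- c()
  for (pp in utils::combn(unique(pops), 2, simplify = FALSE)) {
    idx <- pops %in% pp
    qs <- c(qs, unname(speciflow:::qstComponents(v[idx], pops[idx])["qst"]))
  }
  expect_equal(ratioMean, mean(qs))
})

test_that("nested flower-level mode removes measurement variance from sigma_W", {
  set.seed(18)
  pops <- rep(paste0("P", 1:4), each = 8)
  inds <- paste0(pops, "_", seq_along(pops))
  indVal <- rnorm(32, rep(c(10, 12, 14, 16), each = 8), 1)
  d <- do.call(rbind, lapply(1:5, function(f)
    data.frame(individual = inds, population = pops, flower = f,
               tr = indVal + rnorm(32, 0, 2))))
  tm <- new("TraitMatrix", data = d, traitNames = "tr")
  qFlat <- estimateQst(tm, "tr")
  qNest <- estimateQst(tm, "tr", nested = TRUE)
  # averaging 5 flowers leaves ~ sigma_meas^2/5 in sigma_W; the nested mode
  # strips it, so sigma_W (nested) <= sigma_W (averaged)
  expect_lte(qNest$sigmaW, qFlat$sigmaW)
  expect_gte(qNest$qst, qFlat$qst)
})

test_that("the comparison table carries coherent CIs and verdicts", {
  cfg <- smallStudyConfig()
  st <- generateStudy(cfg, seed = 19)
  gm <- filterGenotypes(st$genotypes)
  pops <- intersect(unique(st$popmap$population[st$popmap$species == "EbuW"]),
                    unique(traitData(st$traits)$population))
  cmp <- qstFstCompare(st$traits, gm, populations = pops, nBoot = 200,
                       seed = 20)
  expect_s3_class(cmp, "qstFstComparison")
  expect_true(all(c("CL", "CH", "CW", "PW1", "PW2", "PC1", "PC2") %in%
                    cmp$trait))
  expect_true(all(cmp$qstLo <= cmp$qstHi))
  expect_true(all(cmp$fstLo <= cmp$fstHi))
  expect_true(all(cmp$verdict %in% c("exceeds", "below", "overlap")))
  expect_true(all(cmp$qst >= 0 & cmp$qst <= 1))
  # the verdict rule is exactly CI separation
  manual <- ifelse(cmp$qstLo > cmp$fstHi, "exceeds",
                   ifelse(cmp$qstHi < cmp$fstLo, "below", "overlap"))
  expect_identical(cmp$verdict, manual)
})

test_that("fewer than three shared populations is warned about", {
  cfg <- smallStudyConfig()
  st <- generateStudy(cfg, seed = 21)
  gm <- st$genotypes
  pops <- unique(traitData(st$traits)$population)[1:2]
  expect_warning(qstFstCompare(st$traits, gm, populations = pops,
                               nBoot = 50, seed = 22), "unreliable")
})
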