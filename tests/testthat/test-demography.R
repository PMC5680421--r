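# scenario construction: epoch windows, rates, invariants

activePairs <- function(model) {
  lapply(migrationEpochs(model), function(e) {
    nz <- which(e$M > 0, arr.ind = TRUE)
    if (!nrow(nz)) return(character(0))
    sort(unique(apply(nz, 1, function(r)
      paste(sort(model@allDemes[r]), collapse = "-"))))
  })
}

test_that("zero scenario admits no migration on any topology", {
  for (top in c("(A:100,B:100);", "((B:100,C:100):100,A:200);")) {
    m <- buildScenario(top, demeSizes = 50, scenario = "zero")
    expect_true(all(vapply(migrationEpochs(m),
                           function(e) all(e$M == 0), TRUE)))
    expect_identical(scenarioTag(m), "zero")
  }
})

test_that("constant two-deme scenario: one epoch over [0, T] at 0.5 Nm per direction", {
  N <- 200
  m <- buildScenario("(EbuE:1000,Xiz:1000);", demeSizes = N,
                     scenario = "constant", rate2Nm = 1)
  ep <- migrationEpochs(m)
  expect_length(ep, 1)
  expect_equal(ep[[1]]$start, 0)
  expect_equal(ep[[1]]$end, 1000)
  # a total scaled rate 2Nm = 1 splits into m = 0.5/(2N) per direction
  expect_equal(ep[[1]]$M["EbuE", "Xiz"], 0.5 / (2 * N))
  expect_equal(ep[[1]]$M["Xiz", "EbuE"], 0.5 / (2 * N))
})

test_that("historical scenario on (A,(B,C)): hand-enumerated epoch windows", {
  # t_BC = 100, t_root = 200, fraction 0.5:
  # B-C active only on [50, 100]; A-anc(B,C) active only on [100, 200]
  m <- buildScenario("((B:100,C:100):100,A:200);", demeSizes = 50,
                     scenario = "historical", epochFraction = 0.5)
  ep <- migrationEpochs(m)
  ap <- activePairs(m)
  anc <- setdiff(m@allDemes, c("A", "B", "C"))[2] # the (B,C) ancestor
  starts <- vapply(ep, function(e) e$start, 0)
  ends <- vapply(ep, function(e) e$end, 0)
  expect_equal(starts, c(0, 50, 100))
  expect_equal(ends, c(50, 100, 200))
  expect_identical(ap[[1]], character(0))
  expect_identical(ap[[2]], "B-C")
  expect_identical(ap[[3]], paste(sort(c("A", anc)), collapse = "-"))
})

test_that("recent scenario restricts migration to the young epoch", {
  m <- buildScenario("(A:1000,B:1000);", demeSizes = 50, scenario = "recent",
                     epochFraction = 0.3)
  ap <- activePairs(m)
  ep <- migrationEpochs(m)
  expect_equal(vapply(ep, function(e) e$start, 0), c(0, 300))
  expect_identical(ap[[1]], "A-B")
  expect_identical(ap[[2]], character(0))
})

test_that("migration is only ever active while both demes coexist", {
  for (sc in c("historical", "constant", "recent")) {
    m <- buildScenario("(((D:50,E:50):150,C:200):300,F:500);",
                       demeSizes = 100, scenario = sc)
    origin <- m@nodeTimes
    ends <- setNames(rep(Inf, length(m@allDemes)), m@allDemes)
    for (k in seq_len(nrow(m@mergeTable))) {
      ends[m@mergeTable$a[k]] <- m@mergeTable$time[k]
      ends[m@mergeTable$b[k]] <- m@mergeTable$time[k]
    }
    for (e in migrationEpochs(m)) {
      mid <- (e$start + e$end) / 2
      nz <- which(e$M > 0, arr.ind = TRUE)
      for (r in seq_len(nrow(nz))) {
        for (d in m@allDemes[nz[r, ]]) {
          expect_lte(origin[[d]], mid)
          expect_gte(ends[[d]], mid)
        }
      }
    }
    # epochs tile [0, rootTime]
    ss <- vapply(migrationEpochs(m), function(e) e$start, 0)
    ee <- vapply(migrationEpochs(m), function(e) e$end, 0)
    expect_equal(ss[1], 0)
    expect_equal(ee[length(ee)], rootTime(m))
    if (length(ss) > 1) expect_equal(ss[-1], ee[-length(ee)])
  }
})

test_that("invalid construction arguments are rejected", {
  expect_error(buildScenario("(A:100,B:100);", demeSizes = 50,
                             scenario = "constant", epochFraction = 1.2),
               "epochFraction")
  expect_error(buildScenario("((A:50,B:50,C:50):50,D:100);", demeSizes = 50,
                             scenario = "zero"), "bifurcating")
  expect_error(buildScenario("(A:100,B:100);", demeSizes = -5,
                             scenario = "zero"), "positive")
  expect_error(buildScenario("(A,B);", divergenceTimes = -10, demeSizes = 5,
                             scenario = "zero"), ">= 0")
  expect_error(buildScenario("(A:100,B:100);",
                             demeSizes = c(A = 10, B = 10),
                             scenario = "zero"), "cover")
})

test_that("divergence times can come from branch lengths or be supplied", {
  m1 <- buildScenario("(A:100,B:100);", demeSizes = 10, scenario = "zero")
  m2 <- buildScenario("(A,B);", divergenceTimes = 100, demeSizes = 10,
                      scenario = "zero")
  expect_equal(rootTime(m1), 100)
  expect_equal(rootTime(m2), 100)
  expect_error(buildScenario("(A:50,B:100);", demeSizes = 10,
                             scenario = "zero"), "ultrametric")
})

test_that("years-generations conversion round-trips", {
  expect_equal(generationsToYears(yearsToGenerations(5.52e6, 5), 5), 5.52e6)
})
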