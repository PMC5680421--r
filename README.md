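# speciflow

Coalescent-based dissection of speciation history for closely related
species complexes: did lineages diverge with or without gene flow, when
did any gene flow happen, and is trait divergence driven by selection or
drift?

`speciflow` is aimed at population geneticists working on recently
diverged, fragmented systems (its synthetic study design mirrors a
complex of karst-endemic herbs: 7 species in 4 lineages, ~43 populations,
6 nuclear loci, a 541-SNP panel and 5 floral traits). It provides:

* a **structured-coalescent simulator** (Rcpp core) for multi-population
  isolation-with-migration demographies whose migration acts only in
  configurable epochs — the four canonical gene-flow scenarios:
  *zero*, *historical* (only in `[f·t, t]` after each divergence at time
  `t`), *constant*, and *recent* (only in `[0, f·t]`);
* **ABC rejection model choice** among scenarios using the vector of
  pairwise lineage Φ~ST~ values as summary statistic
  (posterior = each model's share of the closest `tolerance` fraction of
  pooled simulations);
* the **genealogical sorting index**,
  `gs = n / Σ_{u∈U}(d_u − 2)` over the internal nodes U traversed in
  uniting a group (gsi rescaled to [0, 1], 1 ⇔ monophyly), on empirical
  trees and on simulated genealogies per scenario;
* a **jml-style minimum-distance test** of hybridization versus
  incomplete lineage sorting;
* multilocus **diversity statistics** (S, h, Hd, π; PPL, A, Ae, Ho, He,
  Fis), **Tajima's D**, MAF/missingness **filtering**, **pairwise F~ST~**
  (distance-based Φ~ST~ for sequences, Weir–Cockerham θ for SNPs) and
  hierarchical **AMOVA** with permutation tests;
* a **Q~ST~–F~ST~ comparison**
  (`Q_ST = σ²_B / (σ²_B + 2 σ²_W)`) with bootstrap/parametric CIs and a
  divergent-selection verdict;
* a **synthetic study generator** producing alignments, SNP genotypes,
  population maps and floral traits with known ground truth.

## Worked example

```r
library(speciflow)

# A two-species demography with constant gene flow (times in generations)
m <- buildScenario("(EbuE:20000,Xiz:20000);", demeSizes = 10000,
                   scenario = "constant", rate2Nm = 1)
m
#> DemographicModel: 2 extant demes ( EbuE, Xiz )
#>   scenario: constant | rate 2Nm: 1 | epoch fraction: 0.5
#>   root time: 20,000 generations; 1 migration epoch(s)

sim <- simulateMultilocus(m, c(EbuE = 20, Xiz = 20),
                          data.frame(length = c(669L, 915L, 1197L),
                                     theta = c(4, 5, 6)), seed = 7)
seqDiversityTable(sim$alignments)
#>   stratum  n  S  h        Hd          pi
#> 1    EbuE 20 81 30 0.8947368 0.006921378
#> 2     Xiz 20 83 24 0.8368421 0.009424919

pairwiseFst(sim$alignments, nPerm = 199, seed = 8)
#> Pairwise F_ST (PhiST estimator)
#>        EbuE    Xiz
#> EbuE 0.0000 0.4558
#> Xiz  0.4558 0.0000
#> mean = 0.4558, range = [0.4558, 0.4558]
```

`S` is the number of segregating sites per species summed over the three
loci, `Hd` the haplotype diversity and `pi` the per-site nucleotide
diversity; the Φ~ST~ of ~0.46 is the substantial differentiation expected
for a 20,000-generation split leaking only 0.5 Nm migrants per direction.

Scenario choice on the same data, with narrow "empirical-style" priors on
the nuisance parameters (the emulated procedure conditions on previously
estimated divergence times and rates):

```r
suite <- buildScenarioSuite("(EbuE:20000,Xiz:20000);", demeSizes = 10000)
priors <- list(theta = list(dist = "loguniform", min = 2, max = 8),
               timeMult = list(dist = "uniform", min = 0.8, max = 1.25))
tab <- buildAbcReferenceTable(suite, c(EbuE = 20, Xiz = 20), nLoci = 3,
                              nSimsPerModel = 2000, priors = priors,
                              seed = 9)
abcRejection(lineageFstSummary(sim$alignments), tab, tolerance = 0.01)
#> ABC rejection model choice (8000 simulations, tolerance 0.01, 80 accepted)
#>   constant     0.338
#>   historical   0.138
#>   recent       0.400
#>   zero         0.125
```

The scenarios that allow present-day gene flow (constant and recent)
share most of the posterior while no-gene-flow ranks last; constant and
recent are near-equivalent under F~ST~ summaries — the vignette
quantifies exactly how far they can be separated.

A complete synthetic study (alignments + SNPs + popmap + traits + the
generating model as ground truth):

```r
st <- generateStudy(studyConfig(), seed = 42)
filt <- filterGenotypes(st$genotypes)   # MAF >= 0.01, missingness <= 10%
amova(st$alignments, nPerm = 199, seed = 1)
qstFstCompare(st$traits, filt, nBoot = 1000, seed = 2)
```

There is also a thin command-line wrapper (`inst/cli/speciflow`) with
`synth`, `simulate`, `stats`, `gsi`, `abc` and `jmltest` subcommands.

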