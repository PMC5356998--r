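# minkr

Noninvasive prenatal detection of fetal trisomy from shotgun sequencing of
cell-free DNA in maternal plasma, using the MINK (Minimally Invasive
Karyotyping) algorithm, together with the evaluation machinery needed to
benchmark such a caller (confusion metrics with exact binomial confidence
intervals, two-sample proportion tests, read-depth titration) and a
synthetic-cohort simulator with known ground truth.

## The problem and the method

A pregnant woman's plasma contains cell-free DNA of which a fraction *f*
(the **fetal fraction**, typically 4–15% in early gestation) is placental.
If the fetus carries a trisomy, reads from the affected chromosome are
over-represented by a factor of roughly 1 + *f*/2 — a signal of a few
percent that must be detected against library-specific technical biases,
chiefly the dependence of read counts on local GC content.

The pipeline:

1. **Binning** — aligned reads (unique, mismatch-free, deduplicated) are
   counted into non-overlapping 50 kb windows per chromosome
   (`makeBins()`, `countLibrary()`).
2. **GC correction** — per library, a loess-style local regression of bin
   counts on bin GC removes the smooth GC bias multiplicatively
   (`localRegression()`, `gcCorrect()`).
3. **The MINK test** — the test library is compared with each karyotypically
   normal reference library in turn. For a pair, the per-bin log2 ratio of
   size-scaled counts,

   r_i = log2((a_i + ε) / (b_i + ε)),

   is regressed on GC content over the *diploid* training chromosomes
   (the potentially aneuploid targets 13/14/18/21 and the sex chromosomes
   are excluded from training). The fitted model predicts r on the target
   chromosome, and the prediction residuals d_i = r_i − r̂_i are tested
   with a one-sample t statistic, t = mean(d) / (sd(d)/√m), df = m − 1,
   upper-tailed for a gain (`pairwiseLog2Ratios()`, `fitDiploidModel()`,
   `testTarget()`).
4. **Calling** — the p values over the whole reference panel are aggregated
   by the **median-p rule**: trisomy if median p ≤ 0.05, normal if ≥ 0.1,
   ambiguous in between (`minkCall()`, `callCohort()`, `sampleRollup()`).
5. **Power** — given *f*, the number of target bins m and the residual sd,
   the noncentral-t power of the test is available in closed form
   (`powerEstimate()`).

Evaluation lives in `confusionCounts()` / `metricsTable()` /
`binomialMetrics()` (sensitivity, specificity, PPV with Clopper–Pearson,
Wilson or Jeffreys intervals), `twoProportionTest()` (continuity-corrected
pooled test), `downsampleCounts()` / `titration()` (exact hypergeometric
read thinning over a depth ladder), and `ingestExternalCalls()` (third-party
callers are consumed as data, never reimplemented). `simulateCohort()`
generates complete cohorts with known karyotype truth.

## Worked example

```r
library(minkr)

cfg <- simConfig(nReference = 20, nTestNormal = 3, nTestTrisomy = 3)
mcs <- simulateCohort(cfg, seed = 11)   # 2200 bins x 26 libraries
mcs <- gcCorrect(mcs)                   # adds the "corrected" assay
calls <- callCohort(mcs, minkConfig(targetChroms = "chr21"),
                    testIds = colnames(mcs)[21:26])
calls
#>   library_id sample_id chrom n_refs     median_p    call
#> 1    TESTN01 S_TESTN01 chr21     20 7.111512e-01  normal
#> 2    TESTN02 S_TESTN02 chr21     20 5.891067e-01  normal
#> 3    TESTN03 S_TESTN03 chr21     20 4.955821e-01  normal
#> 4    TESTT01 S_TESTT01 chr21     20 1.972965e-21 trisomy
#> 5    TESTT02 S_TESTT02 chr21     20 1.149810e-08 trisomy
#> 6    TESTT03 S_TESTT03 chr21     20 1.285812e-06 trisomy
```

All three simulated trisomy-21 libraries (fetal fractions 0.136, 0.064,
0.062) are called trisomic with median p values far below the 0.05
threshold; the three normal libraries sit near the middle of the null
distribution. Companion statistics:

```r
twoProportionTest(1, 1188, 11, 1188)
#> two-sample proportion test (continuity-corrected): 1/1188 vs 11/1188,
#> chi-sq = 6.7843, p = 0.009196

binomialMetrics(47, 48)       # sensitivity 47/48 with exact 95% CI
#>   estimate     ci_lo     ci_hi
#> 1 0.9791667 0.8893038 0.9994727

powerEstimate(f = 0.10, m = 100, s = 0.12, nRefs = 20)$perTest
#> [1] 0.9999999
```

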