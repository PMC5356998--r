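---
title: "Aneuploidy calling from binned cell-free DNA counts: model and design notes"
author: "minkr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aneuploidy calling from binned cell-free DNA counts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(minkr)
```

## The statistical model

Maternal plasma carries cell-free DNA, a fraction $f$ of it placental. Under
a fetal trisomy of chromosome $c$, the expected share of reads mapping to
$c$ rises by the dosage factor $1 + f/2$: the fetal compartment contributes
three copies instead of two, the maternal compartment is unchanged. At
$f = 0.10$ the expected mean shift of the per-bin log2 ratio on the target
chromosome is $\log_2(1.05) \approx 0.070$ — the signal the caller must
separate from technical noise.

The caller works pairwise. For a test library $A$ and one karyotypically
normal reference $B$, both count vectors are scaled to a common total over
the *training* bins, and the per-bin ratio

$$r_i = \log_2\frac{a_i + \varepsilon}{b_i + \varepsilon}$$

is formed ($\varepsilon = 0.5$ a pseudocount). Pairwise ratios are the key
design choice: any per-bin effect *shared* by the two libraries —
mappability, reference artefacts, the common part of GC bias — cancels
exactly. What remains is (i) counting noise, (ii) the *difference* of the
two libraries' GC biases, and (iii) a dosage shift on a trisomic
chromosome. Component (ii) is smooth in GC, so the training ratios (all
autosomes except the target chromosome, the other potentially aneuploid
chromosomes 13, 14, 18, 21, and the sex chromosomes — a trisomy elsewhere
must never contaminate the "diploid" training set) are regressed on GC by
ordinary least squares, $r \sim 1 + \mathrm{gc}$ by default. The fitted
model predicts $\hat r_i$ on the target chromosome, and the prediction
residuals $d_i = r_i - \hat r_i$ carry the dosage signal. The test is the
one-sample t,

$$t = \frac{\bar d}{s_d/\sqrt{m}}, \qquad \mathrm{df} = m - 1,$$

upper-tailed for a gain. The variance formulation is deliberately the
simplest consistent with testing "observed minus predicted" residuals:
$s_d$ is the empirical sd of the target residuals themselves, so the test
adapts to whatever per-bin noise level the pair actually has.

One library is tested against every reference in the panel (excluding
itself if it is a panel member) and the p values are aggregated by the
median: **trisomy** if the median p ≤ 0.05, **normal** if ≥ 0.1,
**ambiguous** in between. The median is robust to a minority of aberrant
references; with an even count it is the mean of the two central order
statistics. Samples sequenced as several libraries roll up as
any-trisomy → trisomy, all-normal → normal, else ambiguous, with a
discordance flag.

### What the median-p rule can and cannot average away

Each pairwise comparison shares the test library's own counting noise on
the target chromosome; only the reference-side noise is independent across
the panel. Under the null the median-p statistic therefore behaves like a
Gaussian with standard deviation
$\rho = \sqrt{v_A/(v_A + v_B)} \in [0.71, 1)$ (in units of the per-pair t),
where $v_A, v_B$ are the per-bin ratio-variance contributions of the test
and reference libraries. A consequence worth knowing: enlarging the
reference panel does **not** drive the false-positive rate to zero; a
normal library whose target chromosome drifted high by chance will sit near
the trisomy threshold against *every* reference. The per-library
false-positive probability is of order 1–3% at the 0.05 threshold under
realistic noise, which matches the single false positive the method shows
at cohort scale. The ambiguous zone between 0.05 and 0.1 exists precisely
to catch these borderline libraries for further investigation.

## GC-bias correction

Counts depend on bin GC in a smooth, library-specific way. Before the
pairwise stage each library is corrected multiplicatively:
$\tilde y_i = y_i \cdot m / \max(f(\mathrm{gc}_i), 10^{-6} m)$, where $f$
is a local-regression fit of counts on GC over unmasked *autosomal* bins
and $m$ its median. Multiplicative correction keeps counts non-negative and
scale-comparable across libraries (an additive correction can go negative);
normalising by the median fitted value preserves the library's overall
depth. Sex chromosomes are corrected with the autosomal curve but never
used to estimate it — their counts depend on fetal sex and would distort
the fit. The pairwise GC regression then absorbs whatever pair-specific
residual the per-library correction leaves, which is why the pipeline
applies both stages.

The smoother is a self-contained local regression: at each evaluation point
the $q = \lceil \mathrm{span}\cdot n\rceil$ nearest neighbours are fit by
weighted least squares with tricube weights $(1-(d/d_{max})^3)^3$, where
$d_{max}$ is the $q$-th smallest distance — points at the window boundary
get weight zero, so distance ties are inconsequential. Robustness
iterations (default 2) reweight by the bisquare $(1-(r/6m_r)^2)^2$ on
residuals, $m_r$ the median absolute residual, discounting outlier bins.
Defaults span = 0.3 and degree = 2 suit the smooth, unimodal GC-bias curves
seen in practice; both are configurable. The implementation (an
RcppArmadillo inner loop) is verified in the test suite against an
independent per-point weighted-least-squares oracle to $10^{-8}$.

## Tunable parameters

| parameter | default | role |
|---|---|---|
| bin width | 50 kb | counting resolution; fixed-width by construction (terminal partial bins are dropped, not truncated, so all bins are exchangeable) |
| $\varepsilon$ (pseudocount) | 0.5 | keeps ratios finite at low counts |
| `minCount` | 1 | bins below this raw count in either library leave both vectors |
| thresholds | 0.05 / 0.1 | the median-p call rule; between them lies the ambiguous zone |
| loess span / degree / robustness | 0.3 / 2 / 2 | GC-correction smoother |
| regression form | linear in GC | quadratic and per-bin covariate columns are options, off by default |
| direction | gain | loss / two-sided available (the same machinery applies to deletions) |
| masking | >10% ambiguous bases | masked bins leave every downstream computation |

## The synthetic cohort generator

No public sequencing data accompany the method, so the simulator is a
first-class module: it emulates the statistical structure the caller
assumes, with known truth, so that every stage is testable.

Per-bin rates are
$\lambda_i = w_i \, j_i \, e^{b(\mathrm{gc}_i;\theta)} \, d_i$:

* $w_i$ — a log-normal per-bin propensity (sd 0.1) drawn once per genome
  and shared by all libraries (mappability-like structure; cancels in
  pairwise ratios, as in real data);
* $j_i$ — a log-normal per-library, per-bin jitter (sd 0.03): residual
  technical variation (library preparation, insert-size-dependent
  mappability) that does *not* cancel pairwise. This term is what keeps
  reference-side noise realistic for deep libraries; without it, deep
  references would be implausibly clean and the median-p rule would face
  only the test library's own noise;
* $b(\cdot;\theta)$ — a quadratic log-scale GC bias with random slope,
  curvature and peak per library ("experimental-specific factors"); smooth
  and unimodal, i.e. exactly the shape a loess can remove;
* $d_i$ — the dosage factor, $1 + f/2$ on a trisomic chromosome's bins.

Counts are negative-binomial with $\mathrm{var} = \mu + \phi\mu^2$,
$\phi = 5\times 10^{-4}$ by default ($\phi = 0$ gives Poisson for oracle
checks). GC per bin is Beta-distributed with mean 0.41, sd 0.06; 2% of bins
are masked at random. Fetal fractions are uniform on [0.04, 0.15] (the
clinically plausible early-gestation range); aligned-read totals are
log-uniform, 10–40M for references and 20–40M for test libraries in the
titration design (references deep, test libraries able to survive thinning
to 20M), 1–40M otherwise.

The default genome is deliberately scaled down — 22 autosomes of 5 Mb,
i.e. 100 bins of 50 kb each, 2200 bins in total — so that a full
simulate–correct–call cycle runs in seconds and the whole titration (a
60-library cohort over a ladder of depths, several seeds) in minutes. A
`grch37` preset provides the real autosome lengths (57,611 bins) when
realistic scale matters more than speed. With 100 target bins and these
noise levels, a trisomy at $f = 0.04$ thinned to 2M reads still yields a
median pairwise t around 3, i.e. detection with high margin, while the
margin (the trisomic libraries' median p) degrades visibly as depth falls
further.

What the simulator does **not** emulate: fragment-length structure,
sequencing error, maternal copy-number variants, placental mosaicism, and
whatever drives the abrupt detection collapse real libraries show at the
very lowest depths. On the last point: under any smooth count-noise model
the pairwise t shrinks only like $\sqrt{\mathrm{depth}}$, so a cohort whose
fetal fractions span 0.04–0.15 cannot simultaneously show perfect detection
at 2M reads and total failure at 1M; real low-input libraries evidently
suffer an additional breakdown (bias correction or model failure) that a
count model does not capture. Passing tests on synthetic cohorts therefore
demonstrate the caller's statistical behaviour under its stated
assumptions, not its robustness to every artefact of real sequencing.

## Numerical choices and degenerate inputs

* Coordinates: bins are 0-based half-open on disk (BED convention),
  1-based closed in memory (GRanges convention); alignment positions are
  1-based (SAM convention) and converted at exactly one place, in
  `countLibrary()`.
* Duplicates are identical (chromosome, position, strand) — the standard
  single-end criterion; the duplicate definition is an assumption and is
  recorded as such.
* A perfect diploid fit would give $s = 0$; the residual sd is floored at
  $10^{-8}$, and a zero-variance target residual vector sets p by the sign
  of the mean with a degeneracy flag.
* An all-zero or GC-constant library makes the GC correction fall back to
  the identity with a warning rather than dividing by zero.
* Reference panels: references failing a pairwise comparison
  (insufficient usable bins) are skipped and counted, never fatal; a
  library with no usable reference becomes a `no_call` row and the cohort
  run continues.
* Downsampling uses sequential conditional hypergeometric draws, giving
  the exact target total (mirroring read-level subsampling); binomial
  thinning (expected total) is available behind a flag.
* Given fixed inputs and configuration the caller is bit-reproducible: no
  randomness enters outside the simulator and the downsampler, and both
  take explicit seeds.

## Design decisions that were genuinely open

* **Regression form.** Only "regressed against GC content" is specified;
  linear is the default, quadratic a flag. With per-library loess already
  applied, the pairwise residual GC effect is mild and the linear form is
  measurably sufficient (the quadratic form changes null calibration by
  nothing detectable in the suite).
* **Test direction.** Gain (upper tail) is the default since trisomy is
  the use case; loss and two-sided are supported because the same
  statistic applies to deletions.
* **Which counts enter the pairwise stage.** GC-corrected values by
  default (with the `minCount` filter always on *raw* counts); the choice
  is recorded in the call object.
* **Sample-level rollup.** Any-trisomy wins at sample level, with a
  discordance flag — the conservative clinical reading of multi-library
  samples.
* **CI method.** Clopper–Pearson by default; Wilson and Jeffreys are
  flags. The method behind any externally reported interval cannot be
  assumed, so intervals are never compared across methods silently.

## Problem sizes used in the checks

The shipped tests run the full pipeline at the scaled-down genome: null
calibration on 80 disjoint library pairs; a 60-library titration cohort
over the depth ladder 20/4/2/1M for five seeds; GC-bias removal at 2000
bins; oracle equality checks at n ≤ 300. The acceptance script replays the
titration cohort at 2M reads for three seeds. These sizes keep a complete
run in minutes while leaving every statistical property measurable at the
stated tolerances.
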