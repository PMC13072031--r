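---
title: "Methods: within-branch C:N:P stoichiometry and nutrient reallocation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: within-branch C:N:P stoichiometry and nutrient reallocation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question and the data model

In declining conifer plantations on nutrient-poor sandy soils, basal (older)
needles of a branch often turn chlorotic while apical needles stay green.
Two explanations compete: the soil is too poor to supply the whole branch
(passive starvation), or the tree actively withdraws nitrogen and phosphorus
from older needles to provision apical growth (active reallocation). The
package implements the stoichiometric toolkit used to separate these
hypotheses from a small paired field design: per tree, one composite needle
sample per branch position (apical, basal) and one composite soil sample per
20-cm depth layer of a 1-m core, each measured for total C, N and P in mg
per g dry mass.

Concentrations are treated strictly mass-based; no molar conversion is
applied anywhere, because all reference values for this system are printed
on the mass scale. Validation is total and non-coercing: missing values,
non-positive or implausibly large concentrations (≥ 1000 mg/g), levels
outside the closed design vocabularies, and duplicate (tree, position) or
(tree, layer) keys are all rejected with diagnostics naming the offending
sample. The design has no legitimate missingness (one composite per
position per tree), so imputation is deliberately absent.

## The five indices

For a sample with concentrations $C, N, P$ the mass ratios are
$C{:}N = C/N$, $C{:}P = C/P$, $N{:}P = N/P$; they satisfy
$(N{:}P)(C{:}N) = C{:}P$ identically, which the package verifies to
$10^{-9}$ relative tolerance.

* **Homeostatic index.** For a group of ratio values,
  $HI = \bar X / SD = 1/CV$. Larger HI means tighter regulation of the
  ratio. The sample standard deviation ($n-1$ denominator) is used
  everywhere a spread enters (HI, CV, z-scores): the design is small-$n$
  and the sample convention is standard practice. A zero-spread group
  yields $HI = \infty$ with a `degenerate` flag rather than an error.
* **Nutrient stress index.** $NSI = Z_{C:N} + Z_{C:P}$, with z-scores
  standardized across *all* needle samples of the run (never per group, so
  groups remain comparable on one scale). NSI sums to zero over the
  standardization set by construction; more positive values mean stronger
  combined N and P limitation.
* **Nutrient resorption efficiency.**
  $NRE = (C_{apical} - C_{basal}) / C_{apical} \times 100\%$, the
  percentage of a nutrient withdrawn from the basal needles relative to
  the apical needles of the same branch. NRE is computed per tree and then
  summarized per condition — not from group means — so the between-tree
  variance needed by the condition contrast (a Welch t-test) is preserved.
  With constant within-group inputs the two conventions coincide. NRE here
  is a proxy for premature, stress-induced mobilization: basal chlorotic
  needles are senescing but not terminally senesced, a caveat inherited by
  every downstream interpretation.
* **Resorption priority index.** $RPI = NRE_N / NRE_P$, again per tree,
  with the reported group RPI being the mean of per-tree values. Values
  above 1 indicate N-priority, below 1 P-priority. The "approximately 1"
  band is a configurable tolerance, default $|RPI - 1| \le 0.1$; inside
  the band a leaning hint is attached (e.g. `coupled (P-leaning)`). The
  band half-width has no canonical value in the field; 0.1 was chosen once
  as a round, conservative default.
* **Stoichiometric deviation index.**
  $SDI = |R_{needle} - R_{soil}| / R_{soil}$ for the corresponding ratio.
  The denominator is always the soil ratio: the index measures how far the
  tissue sits from the soil's balance, so it is deliberately asymmetric,
  and it is invariant under a common rescaling of both ratios. Pairing is
  same-tree: the needle ratio of tree $i$ is compared with tree $i$'s soil
  ratio at each layer, the only choice consistent with per-tree composite
  soils. Because published summaries of this index could be either
  group-level or tree-level, the grid is reported under both conventions —
  `group_mean` (SDI of group-mean ratios, the default reporting
  convention) and `per_tree` (mean of per-tree SDIs); they coincide when
  within-group variation vanishes.

## The inferential chain

Group contrasts follow the field's variance-gated recipe at
$\alpha = 0.05$ (configurable), all tests two-sided:

1. Levene's test for homogeneity of variances, *mean*-centred (the
   original form, rather than the median-centred Brown–Forsythe variant).
   The degenerate case where the absolute deviations show no between-group
   spread is reported as statistic 0, $p = 1$.
2. If $p \ge \alpha$: classical one-way ANOVA, then Tukey HSD pairwise
   comparisons. Otherwise: Welch's ANOVA, then Games–Howell pairwise
   comparisons (pairwise Welch t referred to the studentized range over
   all $k$ groups). The heteroscedastic route has no canonical post-hoc in
   this literature; Games–Howell is used so compact letters can always be
   produced, and is documented as an extension.
3. A compact letter display summarizes the pairwise significance matrix by
   the insert-and-absorb construction, followed by an exact reduction over
   the maximal cliques of the non-significance graph (feasible for up to
   ten groups; this design has at most six). The display contract — two
   groups share a letter iff their comparison is non-significant — is
   property-tested against an independent exhaustive oracle.

Useful identities checked numerically: two-group ANOVA F equals the
squared pooled t, and for *two* balanced equal-variance groups Welch's F
equals the classical F exactly. For three or more groups Welch's
small-sample correction shrinks the statistic slightly even under perfect
balance, so no identity is asserted there.

The healthy-vs-chlorotic contrasts of per-tree NRE and RPI use Welch
t-tests. Needle–soil coupling is screened as a Pearson correlation grid
(needle group × soil layer × ratio, across trees); cells with fewer than
three trees are flagged `insufficient`, zero-variance cells `degenerate`,
and cells at the minimal design size ($n = 3$) are stamped `low-power` —
they are reported, but the package treats them as exploratory. No multiple
-testing correction is applied to the primary p-values (matching the
field's reporting of raw values); a Benjamini–Hochberg column is appended,
clearly labelled an extension.

The PCA of needle ratios standardizes each ratio column to zero mean and
unit sample variance (a correlation-structure decomposition). Loading
signs are arbitrary in any PCA; each component is oriented so its
largest-magnitude loading is positive, fixing reproducibility. Explained
fractions over the three components sum to one, and scores reconstruct the
input exactly (tested to $10^{-9}$).

The homeostatic index is one number per group, so it admits no
within-group F-test without resampling; the report therefore presents HI
descriptively (with its $n$, mean and spread provenance) and offers no
significance letters for it. A resampling-based comparison was considered
and deliberately left out: with three trees per group a bootstrap of a
variance-derived index is too unstable to be honest.

## The synthetic generator

The generator emulates the study design: `n_trees_per_condition` (default
3) trees per condition, one apical and one basal needle composite per
tree, five soil layers per tree. Defaults are the published group means of
the reference system — needle N/P/C of 21.9/8.3/447.8 (apical healthy),
12.8/4.3/481.8 (basal healthy), 24.7/7.9/461.4 (apical chlorotic),
7.2/1.6/472.4 (basal chlorotic) mg/g — and the regional sandy-soil means
2.30/0.23/0.13 mg/g, held depth-constant because the study text prints no
per-layer values.

Noise is normal, truncated to the data model's admissible range
(0, 1000) mg/g, with SD = CV × mean so variance scales with the mean;
default CVs are 0.10 (needles) and 0.15 (soil). The true within-group
spreads of the reference study live in its data deposit, not its text, so
these defaults are field-plausible placeholders and are labelled as such.
C is drawn independently of N and P — no covariance model is available
from printed information — which is a known limitation: real needle C:N
and C:P covary through shared C.

Two modes:

* **descriptive** — each sample is drawn around its group's configured
  mean; ground truth for every index follows from the means by the
  closed-form arithmetic of `ground_truth()`.
* **mechanistic** — chlorotic trees start from the *healthy* branch pools
  and move a fraction $f_N$ (default 0.39) of the basal N pool and $f_P$
  (default 0.51) of the basal P pool to the apical compartment before
  noise. The expected resorption efficiency is then
  $100\,(1 - (1-f)B / (A + fB))$ for healthy pools $A$ (apical) and $B$
  (basal). The default fractions were calibrated once, by solving this
  expression for the reference study's observed chlorotic efficiencies at
  its healthy pools, and are not revisited. Carbon pools are not
  reallocated.

Randomness uses one root seed with a documented child seed per tree
(condition-specific blocks), so enlarging one condition never reshuffles
trees already generated; at CV = 0 the generator is exact, which gives the
pipeline a noise-free limit in which every index must equal ground truth
to floating point.

What passing tests show — and do not. Parameter recovery (500 replicates
at 50 trees per condition recovering NRE within 1 percentage point and RPI
within 0.03, with the chlorotic-greater-than-healthy contrast detected at
$p < 0.05$ in at least 95% of replicates) validates the pipeline's
arithmetic and inference under the generator's assumptions: independent
truncated-normal noise, no C–N–P covariance, depth-constant soil. It does
not validate those assumptions against real field data, nor does it add
power to a real $n = 3$ design.

## Numerical choices and degenerate inputs

* Sample SD ($n-1$) throughout; groups need $n \ge 2$ for any spread.
* Zero-spread HI groups are flagged, not fatal; zero reference SD in NSI
  standardization is an error naming the degenerate ratio.
* $NRE$ requires a positive apical concentration; $RPI$ is `NA` with a
  warning where $NRE_P = 0$; SDI requires a positive soil ratio.
* In the orchestrated run, a variable whose gated comparison is undefined
  (e.g. zero within-group variance everywhere in a noise-free synthetic
  run) is recorded in the test section with a note instead of aborting the
  other variables.
* Statistical calibration is checked by simulation at the package's chosen
  sizes: 2000 null replicates (4 groups, $n = 10$) for the gated
  comparison's type-I error, 500 × 50-tree replicates for recovery, 1000
  replicates for Levene's level, 10000 shuffles for the small-$n$
  permutation cross-check of the ANOVA p-value.
* Report determinism: rerunning the same inputs, configuration and seed
  reproduces every number; only the timestamp in `run_metadata` differs.

## Benchmark mode and its limits

`run_benchmark()` reads a data deposit through a user-supplied column
mapping (the deposit's native headers are unknown, so nothing is guessed),
recomputes the reference quantities, and reports a side-by-side comparison
with tolerance of half a unit in the last printed digit. From printed text
alone only the needle group means are fully checkable: the published
topsoil deviation indices (N:P 0.73, C:N 11.6, C:P 16.1 for basal
chlorotic needles vs the 0–20 cm layer) and the soil ratio bounds
(C:N < 7, C:P < 20) depend on plot-level soil values that exist only in
the deposit. Note the tension baked into the defaults: the regional soil
means imply soil C:N = 10.0, while the study plot itself reports C:N
below 7 — the generator defaults follow the regional values, and the
deposit-dependent rows of the comparison table are expected to disagree
until real deposit data are supplied.

## Known limitations

* $n = 3$ trees per condition: correlations and PCA at this size are
  exploratory, and the package stamps them accordingly.
* Mass-based ratios only; no elements beyond C, N, P; no senescence-stage
  model behind NRE.
* The generator's noise model is a calibration vehicle, not a biological
  model; its soil profile is depth-constant by default.
* Compact-letter minimality is guaranteed by exact search only up to ten
  groups; beyond that the insert-and-absorb result (which always satisfies
  the sharing contract) is returned as-is.
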