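# needlestoich

Within-branch C:N:P stoichiometry and nutrient-reallocation analysis for
conifer plantations on nutrient-poor sandy soils.

## The problem

In declining Scots pine plantations on sandy land, the basal (older)
needles of a branch frequently turn chlorotic while the apical needles on
the same branch stay green. Is that passive starvation from poor soil, or
an active survival strategy in which the tree withdraws nitrogen and
phosphorus from old needles to provision apical growth? `needlestoich`
implements the stoichiometric toolkit used to tell these apart from a
paired field design — per tree, one composite needle sample per branch
position (apical/basal) and one composite soil sample per 20-cm layer of a
1-m core, each measured for total C, N, P (mg per g dry mass).

It is written for plant ecophysiologists and restoration ecologists who
have tidy CSV tables of elemental concentrations and want the standard
indices, the inference chain, and a validated synthetic testbed in one
pipe-friendly package.

## What it computes

Mass ratios C:N, C:P, N:P per sample, and five indices:

| Index | Definition | Reading |
|---|---|---|
| HI  | mean/SD = 1/CV of a ratio within a group | higher = stronger homeostatic regulation |
| NSI | z(C:N) + z(C:P), standardized across all needle samples | more positive = stronger combined N+P limitation |
| NRE | (C_apical − C_basal)/C_apical × 100%, per tree | % of a nutrient withdrawn from basal needles |
| RPI | NRE_N / NRE_P, per tree | >1 N-priority, <1 P-priority, ≈1 coupled |
| SDI | \|R_needle − R_soil\| / R_soil, same tree | larger = needle decoupled from soil balance |

Inference follows the field's variance-gated recipe at α = 0.05: Levene's
test (mean-centred) routes each variable to classical ANOVA + Tukey HSD or
to Welch ANOVA + Games–Howell; compact letter displays are built by
insert-and-absorb with an exact minimality reduction; healthy-vs-chlorotic
contrasts of NRE and RPI use Welch t-tests; needle–soil coupling is a
Pearson correlation grid (group × layer × ratio); and a PCA of
standardized needle ratios summarizes multivariate separation. A synthetic
generator reproduces the whole study design with closed-form ground truth
(descriptive and mechanistic-reallocation modes) for parameter-recovery
validation. See the methods vignette
(`vignettes/needle-stoichiometry-methods.Rmd`) for conventions and
limitations.

## Worked example

```r
library(needlestoich)

cfg <- generator_config(mode = "mechanistic", n_trees_per_condition = 10, seed = 42)
ds  <- generate_study(cfg)     # or: study_dataset(read_samples("needles.csv", "needle"),
                               #                   read_samples("soils.csv", "soil"))
report <- run_analysis(ds)
report
#> <analysis_report>
#>   provenance: generate_study(mode=mechanistic, seed=42, n=10)
#>   40 needle samples, 100 soil samples, alpha = 0.05
#>   condition means of per-tree resorption:
#>     healthy   NRE_N =  42.76%  NRE_P =  47.84%  RPI = 0.906 (coupled (P-leaning))
#>     chlorotic NRE_N =  74.08%  NRE_P =  79.93%  RPI = 0.928 (coupled (P-leaning))
```

Chlorotic trees withdraw far more N and P from their basal needles than
healthy trees (here ~74% and ~80% of the apical concentration, against
~43%/~48%), while RPI stays near 1 for both — N and P are withdrawn
together, the signature of coordinated reallocation rather than a
single-element deficiency. The contrasts are formal Welch t-tests:

```r
report$resorption_tests[, c("variable", "estimate", "statistic", "df", "p_value")]
#> # A tibble: 3 × 5
#>   variable estimate statistic    df       p_value
#> 1 nre_n    -31.3       -6.87  10.4  0.0000354
#> 2 nre_p    -32.1      -15.7   12.1  0.00000000214
#> 3 rpi       -0.0218    -0.204  9.61 0.843
```

NRE differs strongly by condition; RPI does not (p = 0.84) — resorption is
stronger in chlorotic trees but equally balanced between N and P. Letters
for any variable come from the gated comparison, e.g. needle C:N separates
all four groups:

```r
dplyr::filter(report$letters, variable == "c_n")
#>   c_n  AC a ; AH b ; BC c ; BH d
```

The generator's closed-form ground truth for the same configuration
(`ground_truth(cfg)$resorption`) gives chlorotic NRE_N = 71.0%,
NRE_P = 79.9%, RPI = 0.888 — the run above recovers these within sampling
error at 10 trees per condition. `write_report(report, "out/")` emits
`report.json` plus tidy CSVs; `autoplot()` methods and `plot_*()` helpers
cover the usual figures. A thin CLI with `generate`/`analyze`/`benchmark`
verbs is in `inst/scripts/needlestoich-cli.R`.

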