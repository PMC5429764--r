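---
title: "Methods: QTS mapping of yield traits in a RIL population"
author: "rilqts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTS mapping of yield traits in a RIL population}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rilqts)
```

## The genetic model

`rilqts` analyses multi-environment trials of biparental recombinant
inbred lines (RILs) under a saturated mixed linear model. The phenotype
of line $k$ in environment $h$ is

$$y_{hk} = \mu + \sum_i a_i x_{ik} + \sum_{i<j} aa_{ij} x_{ik} x_{jk}
  + e_h + \sum_i ae_{hi} x_{ik} + \sum_{i<j} aae_{hij} x_{ik} x_{jk}
  + \varepsilon_{hk},$$

where $x_{ik} \in \{+1, -1\}$ codes the paternal (QQ) versus maternal
(qq) homozygote at locus $i$. Additive effects $a_i$ and
additive-by-additive epistatic effects $aa_{ij}$ are fixed;
environments $e_h$ and the interaction deviations $ae_{hi}$,
$aae_{hij}$ are random (environments being largely uncontrollable), and
$\varepsilon_{hk}$ is residual noise. A negative $a_i$ means the
paternal homozygote decreases the trait. In an F13 RIL the expected
heterozygosity is $(1/2)^{12} \approx 2.4\times10^{-4}$, so the model
carries no dominance terms; residual heterozygous genotype calls are
treated as missing and imputed from the nearest flanking marker (ties
to the left flank).

The package was written around a rice study design -- grain yield (GYD)
and its components (panicle number NP, filled grains per panicle NFGP,
1000-grain weight GW) scored on 138 F13 lines of a XieqingzaoB x
Zhonghui9308 cross in two locations -- but every stage takes arbitrary
marker panels, line counts, trait names and environment sets.

## The simulator as the study stand-in

No genotype accession accompanies the reference study, so the package
ships a generative stand-in. `simulate_ril_genotypes()` runs single
seed descent explicitly: each line starts as an F1, and every selfing
generation draws two gametes whose crossovers between adjacent markers
occur at Haldane recombination fractions
$r = \tfrac12(1 - e^{-2d/100})$ ($d$ in cM, no interference). Haldane
was chosen because it leaves the engine analytically checkable: for
selfed inbred lines the recombinant fraction between two loci converges
to $R = 2r/(1+2r)$, and the residual heterozygosity after $g$ selfing
generations is $(1/2)^g$ -- both are asserted by tests against the
engine at $n = 20{,}000$ lines. A `"mosaic"` mode samples the limiting
distribution directly (a Markov chain of codes with switch probability
$R$); it is an order of magnitude faster and is validated against the
meiosis engine, which remains the oracle.

`make_truth_preset()` plants the catalogued per-trait architecture
(`yield_qts_catalogue()`): the published additive, epistatic and
environment-interaction effect sizes, placed at evenly spaced positions
on their catalogued chromosomes of a 12-chromosome, 150 cM genome with
20 markers per chromosome (roughly 7.9 cM marker spacing; physical
positions use a nominal 250 kb/cM, close to the rice genome average).
Two calibrations make the presets self-consistent:

* **Phenotypic variance.** The study never prints $V_P$, but it is
  recoverable because $h^2 = 100\,\mathrm{eff}^2\,\mathrm{Var}(x)/V_P$
  with $\mathrm{Var}(x) = 1$: every row of a trait back-solves to the
  same $V_P$ (e.g. $1.54^2/0.1091 \approx 21.7$ for GYD), a consistency
  the test suite checks at 5% relative tolerance across all four
  traits. The preset residual SD is then solved so the *expected*
  sample $V_P$ -- including the covariance $2 a_i a_j (1-2R_{ij})$
  between loci sharing a chromosome -- hits the back-solved target;
  without that correction the realised heritabilities of traits with
  two loci on one chromosome would drift upward by about half a
  percentage point.
* **Environment effects.** Environment means split the catalogued
  between-location difference D symmetrically around the reference
  grand mean (e.g. $\pm 5.17/2$ for GYD), reproducing the reported
  significant location contrasts qualitatively.

Interaction deviations must sum to (approximately) zero across
environments; the validator allows a slack of 0.02 because published
deviations are rounded to two decimals ($-0.65 + 0.64 \ne 0$).

What the simulator deliberately omits: segregation distortion,
selection during SSD, dominance, genotyping error, and missing-data
patterns beyond an optional masking. Tests passing on simulated data
therefore demonstrate the *estimators*' behaviour under the stated
model, not robustness to those real-data pathologies.

## Trait statistics and conditional phenotypes

`summarize_traits()` reports per-environment means, sample SDs, ranges,
$CV = 100\,SD/\text{mean}$ and the between-environment difference
$D = \bar y_{E1} - \bar y_{E2}$ (signed; reported study tables print
$|D|$). With only two locations a studentised-range test reduces to a
two-sample comparison, so D's significance uses Welch's test with
`*`/`**` at 0.05/0.01.

Genotypic values are predicted by shrinkage: the balanced two-way
moment estimators give $\hat\sigma^2_\varepsilon = MS_{resid}$ and
$\hat\sigma^2_g = (MS_{line} - MS_{resid})/H$, and the line effect is
shrunk by $\lambda = \sigma^2_g / (\sigma^2_g + \sigma^2_\varepsilon /
H_k)$. Full REML would add nothing here: on the balanced two-environment
design the moment solution *is* the REML solution, and its closed form
is directly testable.

Conditional phenotypes $T_1|T_2$ remove from a target trait the
variation linearly predictable from a component trait, separately
within each environment: $b_h = \mathrm{Cov}_h(y_1,
y_2)/\mathrm{Var}_h(y_2)$ and $y_{1|2,hk} = y_{1,hk} - b_h(y_{2,hk} -
\bar y_{2,h})$. The construction's defining contract -- zero
within-environment covariance with the given trait -- is exact by
construction and property-tested, as are idempotence and preservation
of components independent of the conditioning trait. Whether the
original mixed-model software conditioned on observed phenotypes or on
predicted genetic effect vectors is not recoverable from its
description; the package defaults to the observed-phenotype regression
(exactly testable) and exposes a `mode = "genotypic"` variant that
regresses on the predicted genotypic value of the given trait instead.

## Candidate screening

Genome-wide two-locus scans are quadratic in the marker count, so a
preliminary screen ranks loci by a cross-validated classification score
(the canonical MDR/GMDR cell-labelling rule, the named screening tool's
internals being unpublished): trait values are centred per environment,
each genotype class of a marker (or each of the four classes of a pair)
is labelled high/low by the sign of its mean training residual, and
testing accuracy is the share of held-out observations whose residual
sign matches their class label (ties and unseen cells credit 0.5),
averaged over 5 folds with fold assignment by line. The score is
invariant to affine transforms of the trait, sits at 0.5 for null
markers, reaches 1 for noiseless signals, and -- critically for
epistasis -- the pair version detects interactions whose marginal
effects cancel. `select_top_candidates()` keeps the top k per
chromosome (default 400, i.e. everything at desk scale) plus members of
top-ranked pairs; ties break to the smaller bp position for
determinism.

## Significance, selection, estimation

**Permutation threshold.** Each permutation shuffles line identities
jointly across environments -- a line's records move together, which
preserves environment main effects while severing the genotype link --
re-runs the scan, and records the maximum F. The threshold is the
empirical $(1-\alpha)$ quantile (type-1, so $\alpha = 1$ degenerates to
the minimum draw) of the max-F distribution; 2,000 permutations by
default (the reference procedure states none). The single-locus F
compares per-(environment, genotype) cell means against environment
means, testing additive and additive-by-environment together; the pair
F adds the product term and its environment interaction to a model
already holding both marginal terms. Both statistics are computed from
group sums, vectorised across markers *and* permutation columns, which
is what makes the 200-dataset calibration experiment run in seconds.
Saturated (zero-residual) fits cap F at $10^{15}$.

**Stepwise selection** alternates forward and backward rounds against
the permutation threshold, refitting every candidate conditional on the
current model; ties break by genomic position, duplicated marker
columns are entered once, and a 50-round guard catches cycles.

**Gibbs sampler.** The final model is re-estimated by MCMC (20,000
iterations, 2,000 burn-in, thinning 10): fixed effects drawn jointly
from their conditional normal (flat priors, one Cholesky of $X'X$ for
the whole chain), random effects singly with normal shrinkage, the
residual variance under the Jeffreys prior, and random-effect variances
under weakly informative scaled-inverse-$\chi^2$ priors (df 2, scale a
small fraction of the phenotypic variance -- with only two environments
the likelihood alone cannot stabilise these variances). Because the
fixed/random split leaves cross-environment means soft-identified, the
reported quantities are the identified combinations: the main effect
absorbs the mean of its interaction deviations, interaction estimates
are posterior means of deviations (summing to zero over environments),
and the population mean absorbs the environment-mean. On noiseless data
the sampler collapses onto the exact least-squares solution (tested to
$10^{-6}$); a split-chain potential-scale-reduction check above 1.1 on
any fixed effect raises a warning.

**Heritability** uses $V_P$ = pooled within-environment phenotypic
variance (environment means removed): $h^2(a_i) = 100\,a_i^2\,
\mathrm{Var}(x_i)/V_P$, epistasis analogously with
$\mathrm{Var}(x_i x_j)$, and interaction components use the *mean* of
squared per-environment deviations. Both conventions (the pooled
within-environment $V_P$; averaging rather than summing $ae^2$ over
environments) are the only pair under which the catalogued rows are
internally consistent, which the proportionality test verifies.

## Detection power at the study scale

With 138 lines and the catalogued effect magnitudes, loci explaining
around 5% of phenotypic variance sit near the edge of what an
experiment-wise 0.05 threshold over ~240 candidates can find: the
noncentral-F power of even the oracle conditional test is about 0.7 at
that size, and greedy stepwise entry pays a further toll when linked
loci compete. The replicated-recovery test therefore asserts what the
design can deliver -- the top locus (h² ≈ 11%) is selected in well over
80% of replicates, and *conditional on selection* every locus with
h² ≥ 5% has its posterior mean within two posterior SDs of the planted
value in ≥ 80% of replicates -- rather than an unconditional detection
rate the sample size cannot support. Published single-study effect
tables are themselves conditioned on detection, which is worth
remembering when comparing recovered and catalogued magnitudes.

## Unconditional versus conditional comparison

`compare_conditional()` reduces to pure set logic on "term → component
set" maps; a term present in both mappings is `retained` (unchanged
component set, effect-size fluctuation explicitly tolerated) or
`retained_component_changed` (an interaction gained or lost, decided at
a nominal 0.05 on the component-level conditional F), otherwise
`absent_under_conditioning` / `novel_conditional`. Conditional runs
re-screen candidates on the conditional trait rather than reusing the
unconditional candidate set, since conditioning can surface loci that
were invisible marginally.

## Problem sizes and numerical choices

Defaults were fixed once, before any result was inspected, at values a
desk-scale re-analysis would use: 12 chromosomes x 20 markers, 150 cM,
138 lines, 5 CV folds, 2,000 permutations, 20,000 Gibbs iterations.
The calibration experiment (200 null datasets x 200 permutations, 100
unlinked markers) and the recovery experiment (50 replicates of the GYD
preset) follow the sizes above; the test suite runs them in full.
Numerical edge cases are handled explicitly: monomorphic markers are
skipped with a warning, collinear pairs (including duplicated markers)
are dropped, saturated fits cap F rather than dividing by zero, and a
zero-variance conditioning trait or an empty line intersection is a
hard error.

## The command line

The package is function-first; `run_pipeline()` drives the whole
analysis from a YAML configuration and writes every table, the QTS
network and a manifest. A thin wrapper at
`inst/scripts/rilqts-cli.R` exposes `simulate`, `summarize`,
`condition` and `run` subcommands for shell use; the remaining stages
(screen/map/report) operate on in-memory model objects and are reached
through `run`, which writes all of their outputs.

## Limitations

Beyond the simulator's idealisations listed above: no
population-structure or kinship correction (a biparental RIL design
needs none), no dominance (homozygous lines), no genome-wide scan at
re-sequencing marker densities (the screening stage exists precisely
to avoid it), and conditional values are a linear adjustment -- any
nonlinear dependence between target and component trait survives
conditioning.
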