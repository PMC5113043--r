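---
title: "Diversity, LD and marker-trait association analysis of structured tetraploid wheat panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity, LD and marker-trait association analysis of structured tetraploid wheat panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(durumpanel)
```

## The setting

durumpanel analyses collections of tetraploid wheat (*Triticum turgidum*)
landraces genotyped with dominant biallelic markers — DArT-style assays
scored as band presence (1) or absence (0) — and phenotyped in
unreplicated, check-anchored field trials across several environments.
The archetypal panel the package is shaped around has 183 accessions of
three inter-fertile subspecies (*durum*, *turgidum* and *dicoccon*, sizes
132/38/13), 749 polymorphic markers of which 329 carry positions on a
consensus genetic map of chromosomes 1A–7B, nine STRUCTURE-style
subpopulations nested largely within subspecies, and plot trials laid out
as a modified augmented design with four repeated checks in up to four
location-year environments.

Because no genotype matrix of that kind is publicly deposited, the
package carries a first-class synthetic-data generator that emulates the
panel's statistical structure with full ground-truth bookkeeping; every
stage of the pipeline is tested against that generator and against dense
brute-force oracles.

## Models and procedures

### Gene diversity and diversity loss

For a dominant 0/1 marker the allele frequency is taken directly as the
band-presence frequency $p$ among non-missing calls — no
Hardy–Weinberg back-correction $q = \sqrt{\text{absence}}$ is applied,
because the analysis treats the scores as biallelic marker states
(`band_frequency()` documents this choice). Nei gene diversity per
marker is

$$H = 1 - p^2 - (1-p)^2 = 2p(1-p) \le 0.5,$$

and a scope (chromosome, genome A/B, or the full panel) is summarised by
the *unweighted mean* of per-marker $H$ over the markers in scope —
the source material is silent on weighting, and equal weights keep
chromosome values comparable across groups. Markers with no non-missing
call in a group are excluded from that group's mean; monomorphic markers
contribute $H = 0$. The relative diversity loss of a subspecies is

$$\Delta GD = 1 - H_{\text{subsp}} / H_{\text{wc}},$$

computed from full-precision $H$ (rounding the inputs first can move a
printed two-decimal $\Delta GD$ cell by one unit, which is why a couple
of published cells are not reproducible from their rounded $H$).
`monomorphic_scan()` lists markers fixed within each subspecies;
"fixed" is state-agnostic (all-0 and all-1 both count) and the overlap
counts between subspecies are on marker identity, not matching state.
Diversity uses all markers; the missing-data filter below applies only
to association scans.

### Linkage disequilibrium

`ld_pairs()` computes, for every unordered pair of markers, the Pearson
correlation $r$ of the two 0/1 columns over pairwise-complete accessions
and $R^2 = r^2$. Pairs on the same known chromosome are *syntenic* (with
cM distance), pairs on different known chromosomes *unlinked*; pairs
involving an unmapped marker enter neither class. The full ordered grid
including self-pairs ($m^2$ entries, the counting convention of the
source analysis: $329^2 = 108{,}241$) is recorded for bookkeeping while
statistics are computed once per unordered pair. Pairs with fewer than
20 pairwise-complete accessions, or a zero-variance column in the
complete subset, are flagged non-evaluable.

Significance of a pair is assessed by permutation
(`ld_permutation_p()`): one column is permuted across accessions
$n_{\text{perm}}$ times (default 1000) and
$p = (1 + \#\{R^2_{\text{perm}} \ge R^2_{\text{obs}}\}) / (n_{\text{perm}} + 1)$.
Ties between binary columns make the permutation distribution discrete,
so these p-values are slightly conservative (super-uniform) — the test
suite checks validity, not exact uniformity.

The *critical* $R^2$ separating linkage-driven LD from the background is
estimated from the unlinked pairs: their $R^2$ values are square-root
transformed to approximate normality and the parametric 95th percentile
is squared back,
$\left(\overline{\sqrt{R^2}} + z_{0.95}\, s_{\sqrt{R^2}}\right)^2$.
With fewer than 30 unlinked pairs the empirical 95th percentile is used
instead, with a warning. The *extent* of LD is the first downward
crossing of this baseline by a loess curve fitted to syntenic $R^2$
against distance — tricube weights, degree 2, span 0.5, robustness
iterations via `family = "symmetric"`, evaluated on a 0.1 cM grid with
linear interpolation at the crossing. A curve starting below the
baseline gives extent 0; a curve that never crosses, or a non-positive
baseline, is flagged not estimable. One collection-wide extent is
reported (per-chromosome curves can be obtained by subsetting the pair
table).

### BLUPs from the augmented design

Each trait-environment combination is fitted separately (the trials are
per-environment designs) with the plot-level linear mixed model

$$y = X\beta + Z_r u_r + Z_c u_c + Z_a u_a + e,$$

where $X$ holds the intercept and one contrast per repeated check (test
entries are the reference level), and field row, field column and
accession effects are independent random terms with variances
$\sigma^2_{\text{row}}, \sigma^2_{\text{col}}, \sigma^2_{\text{acc}},
\sigma^2_e$. The accession term applies to test entries only — a check
plot's genetic mean is its fixed effect — implemented as a random slope
on a test-entry indicator so check plots contribute nothing to it.
Fitting is by REML through `lme4::lmer()`, the standard and
numerically hardened REML implementation for exactly this model class;
the package wraps it behind `fit_augmented_reml()`, which returns the
variance components (with boundary flags), the REML log-likelihood, a
convergence flag (non-convergence is flagged, not raised) and the
accession BLUPs. The reported BLUP is the fixed intercept plus the
predicted accession deviation; deviations are centred with the mean
folded into the intercept, which leaves every prediction unchanged and
makes the deviations sum to zero exactly. Zero-variance traits return
zero components and constant BLUPs; a confounded check design is a hard
error. Checks are not used for any additional block-level adjustment:
predictions come from the global mixed model only.

### Structure-corrected association scan and declaration

Markers enter association scans only if their missing-call fraction is
strictly below 5% (`association_filter()`; a marker at exactly 5% is
dropped). For a response vector (per-environment BLUPs, or a one-vs-rest
class indicator for qualitative traits with at least 5 members), the
scan fits per marker the general linear model

$$y = \mu + Q_{1..K-1}\gamma + x\beta + \varepsilon,$$

where $Q$ is the population-membership matrix; its rows sum to 1, so the
last column is dropped against the intercept. The marker is tested by
the extra-sum-of-squares F statistic with $(1, n - K - 1)$ degrees of
freedom on complete cases, and its partial $R^2$ is
$(SSE_{\text{red}} - SSE_{\text{full}}) / SSE_{\text{red}}$. Markers
monomorphic in the sample are skipped; markers collinear with $Q$
(projected norm below $10^{-10}$) return `NA` with a diagnostic.
Bonferroni-adjusted scan p-values ($\min(1, pm)$ at the post-filter
family size) are reported alongside raw ones, but declaration uses the
raw printed thresholds — the corrected values are descriptive, since the
declaration rule of the source analysis states raw cutoffs and its
Bonferroni sentence is not interpretable as a defined step.

A marker-trait pair is *declared* an MTA when its scan passes
$p < 0.0005$ in at least one scan cell and it is confirmed within
subspecies: qualitative traits by a Pearson chi-square (2-by-k table of
marker state by class, no continuity correction) with $p < 0.01$ in at
least one subspecies; quantitative traits by within-cell simple
regressions of BLUP on marker state whose significant cells
($p < 0.05$) span more than one distinct environment or more than one
distinct subspecies. Confirmation regressions are computed in *all*
subspecies-by-environment cells for every scan hit, as the published
association tables do. All inequalities are strict: a p-value exactly at
a threshold never counts. For declared markers fixed in some subspecies,
`monomorphic_concordance()` checks whether the fixed allele state agrees
with that subspecies' phenotype, by comparing its trait mean (or
dominant class) with the allele-state means (or majority classes) of the
segregating accessions.

### Supporting statistics

`two_way_anova()` fits subspecies, environment and their interaction by
Type II sums of squares (via `car::Anova`); Type II is the appropriate
choice for the severely unbalanced subspecies sizes, and reduces to the
classical decomposition in balanced data. The interaction is dropped
with a warning when a cell is empty. `correlation_matrix()` chooses
Pearson or Spearman per variable pair by a Shapiro–Wilk normality gate
at $\alpha = 0.05$ on each variable, on pairwise-complete observations,
recording the method used. Carbon isotope discrimination uses
$\delta^{13}C = (R_{\text{grain}}/R_{\text{standard}} - 1) \times 1000$
and $\Delta^{13}C = (\delta_a - \delta_s) / (1 + \delta_s/1000)$ with
$\delta_a = -8$‰ for free atmospheric CO2 on the PDB scale. The
denominator divides $\delta_s$ by 1000 because both deltas are in per
mil; the formula is sometimes printed as $(1 + \delta_s)$, which only
yields grain-scale discriminations (about 16–19‰) under this per-mil
reading.

## The synthetic-data generator

`generate_collection()` draws band frequencies hierarchically — an
ancestral frequency per marker (uniform on 0.1–0.9), a subspecies
frequency by a Balding–Nichols beta draw (drift $F = 0.15$), and a
population frequency around it ($F = 0.05$), clipped to $[0.02, 0.98]$ —
and lays the mapped markers uniformly on the 14 chromosomes (140 cM
each). LD is induced by a first-order Markov copying process along each
chromosome: an accession copies the previous marker's call with
probability $e^{-d/\tau}$ (default $\tau = 5$ cM) and otherwise draws a
fresh Bernoulli call from its population frequency, giving monotone
distance-dependent decay within chromosomes and independence between
them. Per-subspecies monomorphic sets are planted by fixing the band
state of a sampled marker subset (defaults 11/749, 80/749, 265/749 for
*durum*/*turgidum*/*dicoccon*, the published fixation profile); the
truth ledger then records the *realized* fixation status of every
marker, since small groups also fix by chance. Missing calls are
injected into a configurable marker subset (default 29% of markers at
7–15% missing) so that the expected number of markers passing the 5%
filter is about 532 of 749; markers outside the subset stay complete.
The emitted Q matrix is the true population indicator softened by a
Dirichlet draw (own-population weight 20, others 0.25), emulating
imperfect STRUCTURE output.

`generate_trial()` places every accession in exactly one plot of a
14-by-16 grid per environment (183 entries plus 41 check plots cycling
through 4 checks) and generates
$y = \mu_{\text{env}} + \text{subspecies-by-environment shift} +
g + \text{row} + \text{col} + e$ with defaults
$\sigma^2_{\text{row}} = \sigma^2_{\text{col}} = 1$,
$\sigma^2_{\text{acc}} = 4$, $\sigma^2_e = 2$ — a repeatability across
environments of about 0.67, typical of phenology and quality traits in
multi-environment wheat trials. Genetic values are a shared polygenic
draw plus planted-QTL effects whose slopes are calibrated against the
full plot-level background variance so the marker's realized $R^2$ in
the calibration subspecies hits its target; realized per-environment
$R^2$ is recorded in the ledger. Qualitative traits threshold a latent
variable (planted marker effect plus standard normal noise) into
classes at its empirical quantiles.

What the generator does *not* emulate: coalescent genealogy, selection
and drift dynamics, genotype-calling error beyond random missingness,
spatial autocorrelation beyond additive row/column effects, and
genotype-by-environment interaction at the individual-accession level
(only subspecies-level shifts). Tests passing on this generator
therefore validate the statistical machinery, not the biology of any
particular panel.

## Numerical choices

* Loess: span 0.5, degree 2, `family = "symmetric"`, 0.1 cM grid; the
  extent is linearly interpolated between the last grid point above and
  the first at or below the baseline.
* Critical $R^2$: $z_{0.95} = `r round(qnorm(0.95), 4)`$; parametric
  form requires 30 unlinked pairs, otherwise empirical with a warning.
* Scan: collinearity tolerance $10^{-10}$ on the projected marker norm;
  complete-case per marker; minimum residual df of 1.
* REML: `lme4` defaults; components are flagged at the boundary when
  below $10^{-8}$ of the total variance; random terms with a single
  level are dropped.
* Permutation p never returns 0 by construction (the $+1$ in numerator
  and denominator).
* Ties and boundary p-values exactly at a declaration threshold are
  non-significant (strict inequalities throughout).
* RNG: every stochastic function takes an explicit integer seed;
  `withr::local_seed` scopes it so library code never leaks RNG state.

## Design decisions that were genuinely open

* **REML engine.** The variance-component optimizer could have been
  written directly over log-variances; the package instead relies on
  `lme4`, and proves its fits against a dense GLS/conditional-mean
  oracle at the fitted variances in the test suite. This buys decades of
  optimizer hardening at no loss of testability.
* **Scan responses across environments.** Whether the original scan ran
  on per-environment BLUPs or a joint value is unstated; the package
  scans per environment and lets the declaration rule demand
  multi-environment or multi-subspecies confirmation.
* **Confirmation cells.** All subspecies-by-environment cells are
  evaluated for every scan hit (the published per-cell $R^2$ tables
  cover all environments), rather than only the cell that produced the
  hit.
* **Qualitative responses in the scan.** Categorical traits enter as
  one-vs-rest indicators per class with at least 5 members; the
  chi-square confirmation then uses the full multi-class table.
* **Unlinked pairs.** Pairs with an unmapped member are excluded from
  both linkage classes rather than pooled into "unlinked".

## Calibration findings and known limitations

The package ships seeded study functions (`mta_declaration_study()`,
`ld_extent_recovery()`, `reml_recovery()`) that the acceptance tests run
at fixed problem sizes: 200 null collections and 100 planted-QTL
collections of 183 accessions and 532 markers in two environments, 20
extent replicates of 2000 syntenic pairs, and 50 augmented trials at the
default 14-by-16 layout. Two findings deserve emphasis.

**The declaration scheme does not control a 5% family-wise rate under a
global marker null.** With no planted QTL the trait still carries
accession-level polygenic repeatability across environments
(correlation $\approx 0.67$ at the default variances). A marker that
spuriously correlates with the polygenic vector in one environment
therefore tends to replicate in the other, so the regression
confirmation is far from independent of the scan, and the study function
measures a family-wise declaration rate around 0.2–0.3 rather than the
$\lesssim$ 5% that would follow if the two stages multiplied as
independent filters. This is a property of the
"confirmed in more than one environment" logic itself, not of this
implementation: replication across environments confirms any
*repeatable* spurious association. Power is excellent — a planted QTL
with realized $R^2 \ge 0.25$ in *durum* is declared in essentially every
seeded run — so the scheme is best read as a screening procedure whose
false-positive control rests on the stringent scan threshold per cell,
not on a family-wise guarantee.

**Row and column variances are information-limited at a single-trial
layout.** With 14 row and 16 column levels per trial, REML estimates of
$\sigma^2_{\text{row}}$ and $\sigma^2_{\text{col}}$ are unbiased but
have median relative errors around 0.35 over seeded trials — close to
the idealized $\chi^2_{13}$ bound of $\approx$ 0.26 before the partial
confounding of an unreplicated design is accounted for. Accession and
residual variances recover at $\approx$ 0.16 median relative error.
Users needing sharp spatial variance estimates should combine
environments or enlarge the layout.

Other limitations: no mixed-model (kinship) association, no D′ or
phase-aware LD, no AR1-type spatial correlation, no multi-environment
joint REML fits, and no heritability reporting — all outside the
package's scope.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run entirely on simulated
data: the default 183 x 749 collection for diversity/LD/pair-count
checks, 532-marker two-environment collections for the null (200 seeds)
and power (100 seeds) studies, 50 REML recovery trials, and 20 LD-extent
replicates. On one CPU the whole suite completes in a few minutes.
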