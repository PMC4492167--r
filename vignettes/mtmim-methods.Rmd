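---
title: "Methods: multi-trait multiple interval mapping in mtmim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-trait multiple interval mapping in mtmim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtmim)
```

This vignette is the package's own account of the statistical machinery:
the models, the numerical choices, what the synthetic-data generator does
and does not emulate, and the known limitations. Everything quantitative
stated here is computed by the test suite or by `scripts/acceptance.R`;
nothing is asserted beyond what those runs check.

## The population model

The package targets recombinant inbred lines (RILs) from a biparental
cross advanced by repeated selfing. Each locus carries one of the two
parental homozygotes, coded `+1` (parent A) and `-1` (parent B) in the
Cockerham contrast convention, so regression coefficients are additive
effects and products of codes are epistatic contrasts. Residual
heterozygosity is ignored: after about seven selfing generations roughly
1 % of loci remain heterozygous, which the two-state code space cannot
represent; heterozygous calls in input files are coerced to missing with
a logged count.

Genome-wide dependence is modelled as a first-order Markov chain over the
ordered loci of each chromosome. Interval lengths in cM convert to
meiotic recombination fractions by the inverse Kosambi map function
`r = 0.5 tanh(2d/100)`, and to observable RIL recombination by the
Haldane–Waddington infinite-selfing collapse `R = 2r/(1+2r)`. Two
approximations are involved and are deliberate:

* exact multilocus selfed-RIL frequencies are not Markov; the chain is
  the standard interval-mapping approximation, and it is also exactly the
  generative model of the simulator, so inference and simulation are
  internally consistent;
* the infinite-selfing limit is used although a real population is
  finite-generation; the difference is far below the resolution of a
  145-line study.

Conditional QTL genotype probabilities `q = P(+1 | markers)` are computed
by conditioning on the nearest informative marker on each side, which for
a Markov chain equals the full forward–backward solution (the test suite
checks equality with an exhaustive three-locus enumeration to 1e-12
across recombination fractions 0.01–0.45 and all flank patterns).
One-sided conditioning applies beyond the outermost informative marker;
a line with no informative marker on a chromosome gets `q = 0.5`
(stationary marginal) with a warning. Positions coinciding with an
observed marker reproduce the observed code exactly. Co-located markers
are jittered by +1e-6 cM in input order so positions are strictly
increasing; the jitter is below any biological resolution.

## Phenotype preparation

Each trait is fitted with `y_ij = mu + B_i + G_j + e_ij` (blocks and
genotypes fixed, sum-to-zero). Two residual models are available:
homoscedastic, and per-genotype variances `s2_j`. Choices made here:

* **Blocks are fixed effects.** With four blocks there is little
  information to estimate a block variance component, and the downstream
  quantities (fitted genotype values) are invariant to this choice in
  balanced designs.
* **The heteroscedastic fit is constrained ML.** Maximization is by
  coordinate ascent: generalized least squares for the mean given the
  variances, closed-form `s2_j` given the mean — each step increases the
  likelihood, so the heteroscedastic log-likelihood never falls below the
  homoscedastic one. The unconstrained likelihood is actually unbounded
  (the shared block parameters can chase one genotype's few observations
  and drive its variance to zero), so variances are floored at 1e-3 of
  the homoscedastic variance; the floor is two orders of magnitude below
  any realistic heterogeneity. The surface can be multimodal; the fit
  reported is the local maximum reached from the homoscedastic start,
  which the tests verify is a genuine constrained local optimum against
  a quasi-Newton optimizer.
* **Variance-model selection is a calibrated test, not the raw LRT.**
  With four replicates each per-genotype variance carries about three
  residual degrees of freedom, and the raw statistic `2(ll_het - ll_hom)`
  referred to chi-square with `J - 1` df rejects a true homoscedastic
  model essentially always (measured: ~100 % at 145 genotypes x 4
  blocks). `select_variance_model()` therefore uses the Bartlett-corrected
  form of the same likelihood ratio — group residual sums of squares
  weighted by their residual df, divided by the Bartlett scale factor —
  whose measured size is 0.05 at that design. The raw log-likelihood
  ratio is still reported (`lrt_raw`) for users who want the uncorrected
  comparison.
* **Standardization uses the sample sd** (n-1 denominator) of the fitted
  genotype values across lines. The centering and scale are stored so
  effects can be mapped back to measurement units.
* Negative ANOVA-based genetic-variance estimates are truncated at zero
  in the heritability formula.

QTL mapping consumes one fitted value per line (genotype means adjusted
for blocks), not raw replicate observations: the block design is a
nuisance for mapping, and the adjusted means carry all the genetic
signal.

## The QTL engine

The MT-MIM model is linear in the expected codes `xhat = 2q - 1`
(Haley–Knott regression): per-trait least squares with a shared design,
ML residual covariance `E'E/n`, multivariate-normal log-likelihood, and
determinant-ratio LOD `(n/2) log10(|Sigma_0|/|Sigma_1|)`. Single-trait
MIM is the one-column case of every routine and the suite verifies
agreement with an independent `lm`-based implementation to 1e-9.
Epistasis columns are products of expectations `xhat_r * xhat_l` rather
than expectations of products; the discrepancy is second order for dense
maps and keeps the design construction linear.

**Thresholds.** Genome-wide significance uses resampled score
statistics: for each candidate position the per-line score contributions
are `u_i = c_i e_i` (candidate covariate residualized against the current
design, times the current-model residual row), whitened by the empirical
covariance `U'U`; a resample multiplies the contributions by standard
normal weights `g_i` shared across positions and traits, preserving both
genome-wide and cross-trait dependence, and the threshold is the
empirical `(1 - alpha)` quantile (order statistic
`ceiling((1-alpha) K)`) of the resampled genome-wide maxima. No model is
refit during resampling, which is what makes recomputing the threshold
at every forward round affordable. The acceptance script measures the
realized false-positive rate of this gatekeeper under a null simulation
at the study design (145 lines, 5 x 100 cM, single trait, K = 200,
200 datasets): 15.0 % at the nominal 15 % level for the default seed,
13–18 % across other seeds tried.

**Search.** The forward search adds at most one QTL per round (the
genome-wide best, ties broken toward the lowest chromosome then lowest
cM), recomputing the threshold against the current model, for up to
three rounds with early stopping; positions are then re-estimated
coordinate-wise (each term re-scanned over its own chromosome holding
the others fixed, epistasis columns recomputed as the term moves) until
a fixed point or ten sweeps — an ascent, so the full-model LOD never
decreases. "Three rounds" could also be read as three passes each adding
several QTL; the one-per-round reading is implemented because it keeps
every addition gated by a threshold computed against the model that
actually contains the previously added terms.

The epistasis search tests all pairs of included terms against a
resampled threshold at the 5 % level (maxima over the candidate pairs),
adding the best pair repeatedly, and then retains a pair only if at
least one of its per-trait epistatic effects is significant at p < 0.05
by score-statistic resampling. The retention rule is read as applying to
the pair's own per-trait effects (not to the main effects of the
participating QTL); all per-trait effects of retained pairs are
reported, significant or not.

**Effect reports.** Per-effect p-values come from the wild-bootstrap
null of each effect's score statistic under the model excluding it, with
stars at 0.1/0.05/0.01/0.001. `R2` per effect is
`100 Var(b x)/Var(z)` and `R2_T` uses the full fitted genetic value,
including non-significant effects. Support intervals are drop-1.5-LOD on
the grid profile of each term (approximately 95 % coverage; the recovery
test measures >= 85 % at the scaled design), with flanking markers taken
at or outside the bounds; a profile whose range is below the drop yields
a chromosome-wide interval and a warning.

**Numerical details.** Candidate positions whose residualized covariate
has negligible norm (no information) score zero; near-singular score
covariances get a 1e-10 ridge before Cholesky; rank-deficient designs
are refused with the collinear columns named; LOD values are clipped at
zero (tolerance 1e-6 for the nestedness check). The grid step defaults
to 1 cM and the default resample count is K = 1000; the tests use
K = 200 with correspondingly wider tolerances.

## The synthetic-data generator

`simulate_study()` emulates the study design the package targets: 145
lines, 10 chromosomes of 178.75 cM carrying 292 markers (mean spacing
6.1 cM by the total/markers convention), four randomized complete blocks
with fixed trait shifts (-0.3, -0.1, 0.1, 0.3) sd, seven traits whose
residual covariance is the observed correlation matrix among root
surface area, root length, fine-root surface area, root diameter,
root:shoot ratio, total dry weight and P content
(`lowp_trait_correlations()`, positive definite with smallest eigenvalue
0.003), three QTL with additive effects of 0.25–0.40 sd placed on
chromosomes 1, 8 and 10, and one epistatic pair acting on total dry
weight (0.307 sd) and P content (0.265 sd). Optional per-line lognormal
residual-sd multipliers (geometric sd 1.5 when enabled) emulate
genotype-level heteroscedasticity, and marker missingness is Bernoulli.

What the generator does **not** emulate: genotyping error, segregation
distortion, selective genotyping, non-Gaussian phenotypes,
genotype-by-environment interaction, and polygenic background beyond the
planted QTL. Passing tests therefore demonstrate correctness of the
machinery under the stated model, and calibration/power at the stated
design — not robustness to real-data pathologies outside it.

Problem sizes in the suite are chosen to keep a full run under a minute
of compute while retaining power: the calibration check uses the
five-chromosome single-trait design above; the parameter-recovery check
runs 20 replicates of a three-chromosome version of the full seven-trait
design (the three-QTL architecture on a 536 cM genome), measuring mean
absolute effect bias below 0.05 sd and support-interval coverage of at
least 85 % of detections.

## Path analysis

Direct effects solve the normal equations `R_x P = r_xy` by QR; indirect
effects are `r_ii' P_i'`; reconstruction `P_i + sum I_ii'` is exact by
construction, and `R2 = sum P_i r_iy`. The solver reports the condition
number of `R_x` and warns above 1e3: with root-trait predictor sets the
matrix is routinely near-collinear (surface area and length correlate at
0.98), so direct effects computed from 2-dp published correlation tables
can differ materially from the originals even though products, sums and
R2 reproduce. The bundled worked example keeps its published direct
effects for exactly that reason, and the tests assert the identity-based
quantities rather than re-derived coefficients. Root:shoot ratio is
excluded from the default predictor set because it contributes to both
dependent variables of the example; published sources describe five root
traits as predictors while tabulating four — the module accepts any
predictor list. An `R2` outside [0, 1] (possible with rounded published
inputs that are not an exact correlation structure) raises a warning,
not an error.

## Known limitations

* The score-resampling construction is one of several in the literature;
  the shared-weight wild bootstrap implemented here is chosen for its
  validity for genome-wide maxima and is calibrated empirically, but
  other constructions could give slightly different thresholds.
* Dominance is not modelled (two homozygous classes only), and
  QTL-by-environment interaction is out of scope.
* The forward search is greedy; with tightly linked QTL of opposite sign
  it can stop early. Position refinement mitigates but does not remove
  this.
* Heritability assumes balanced (or near-balanced) replication; severely
  unbalanced designs should use a mixed-model package instead.
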