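---
title: "Bivariate nuclear twin family models with assortative mating: methods"
author: "ntfam"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bivariate nuclear twin family models with assortative mating: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`ntfam` models two standardized traits — by convention trait1 is IQ-like and
trait2 height-like, an order fixed everywhere in the package — measured on
nuclear twin families: monozygotic (MZ) and dizygotic (DZ) twins, their
non-twin siblings, and their parents.  Each observed trait vector is the sum
of latent 2-vectors weighted by 2x2 lower-triangular Cholesky path matrices:

* **A** — additive genetic effects shared between the sexes, paths `a_m`,
  `a_f`;
* **B** — additive genetic effects unique to males (qualitative sex
  limitation of A), paths `b`; modelling them as male-specific rather than
  female-specific is arbitrary and does not change the fit;
* **D** — dominance (non-additive) genetic effects, paths `d_m`, `d_f`;
* **S** — environments shared by all siblings including twins, but not by
  parents (school, peers, cohort), paths `s_m`, `s_f`;
* **T** — environments shared by twins only (prenatal environment, shared
  classes), paths `t_m`, `t_f`;
* **F** — familial environment transmitted from parent phenotype to
  offspring environment ("vertical transmission"), through four full 2x2
  matrices `v_fs`, `v_fd`, `v_ms`, `v_md` (father/mother to son/daughter);
* **C** — a family environment shared by spouses and children (social
  homogamy), paths `c_m`, `c_f`;
* **E** — unique environment and measurement error, paths `e_m`, `e_f`.

S and F generate identical sibling covariance patterns (siblings share F
with coefficient 1 and there is no residual F variance), so a model with
both free is not identified; modes gate them.  Three variants are offered:

* **ABDSTE** — primary phenotypic assortment with sibling environments;
* **ABDFTE** — primary phenotypic assortment with vertical transmission;
* **ABDCTE** — social homogamy (spousal resemblance through shared C;
  the copath matrix is inactive).

Quantitative sex limitation is expressed through the per-sex path matrices;
qualitative sex limitation through B and through free correlations `r_D`,
`r_S`, `r_T` between the D/S/T latents of opposite-sex pairs.

### Assortative mating and the copath matrix

Primary phenotypic assortment is modelled by a full 2x2 copath matrix `mu`
connecting the two spouses' phenotypes.  Rows of `mu` index the husband's
traits and columns the wife's: `mu_12` is the copath between the husband's
trait1 (IQ) and the wife's trait2 (height).  This orientation is a
convention — the study literature describes the two cross copaths verbally
and either assignment is defensible — and a single transpose of `mu` swaps
it.  The copath tracing rule states that for any variable X on the
husband's side and Y on the wife's side,

    cov(X, Y) = cov(X, P_h) %*% mu %*% cov(P_w, Y),

which is exactly the covariance structure obtained when mating depends on
the two phenotypes alone (conditional independence given phenotypes, with
spousal phenotypic cross-covariance `Vp_m mu Vp_f`).  The generational
simulator mates individuals by exactly this coupling, which is why the
analytic moments and the simulation agree without approximation beyond
Monte-Carlo error.

### The equilibrium q matrix

Assortment makes trait-increasing alleles statistically associated within
and across traits (gametic phase disequilibrium), inflating the additive
genetic covariance.  The package solves the stationary state jointly over
the stacked latent vector G = (A, B) with 4x4 covariance `QG`:

    Gamma = Cov(G_father, G_mother) = Cgp_m %*% mu %*% t(Cgp_f)
    QG    = I + (Gamma + t(Gamma)) / 2

where `Cgp_x = QG %*% t(L_x)` is the within-person latent-phenotype
covariance and `L_m = [a_m | b]`, `L_f = [a_f | 0]` are the per-sex
loadings.  Solving A and B jointly matters: assortment induces a nonzero
covariance between one spouse's B and the other's A, which separate scalar
fixed points would miss.  The classical q matrix is the leading 2x2 block
of `QG`; it is exactly the identity under random mating (`mu = 0`),
including social homogamy.  Offspring latents follow the infinitesimal
model `G_o = (G_fa + G_mo)/2 + xi` with segregation variance
`Var(xi) = I/2`, unaffected by assortment.

In the univariate embedding with additive variance a^2 and scalar copath
mu, the fixed point is the smaller root of `a^2 mu q^2 - q + 1 = 0`;
with `a^2 = 0.5`, `mu = 0.2` this gives q = 1.1270, which the solver
reproduces to 1e-8 and the forward simulator to Monte-Carlo error.

With vertical transmission the fixed point extends jointly over
`(QG, w_m, w_f, fvar_m, fvar_f)` — w is the covariance between an
individual's latents and their F, fvar the F variance — by iterating the
full moment recursion rather than hand-derived closed forms; its
correctness is delegated to the simulation oracle, which implements the
same structural equations agent by agent.

**Numerics.** The solver is a damped fixed-point iteration from the
random-mating state (damping 0.5, max-norm tolerance 1e-10, at most
10,000 iterations); it is linearly convergent and trivially verified
against the quadratic closed form.  Divergence (no admissible fixed point,
e.g. `4 a^2 mu > 1` in the univariate case) and loss of positive
semi-definiteness of q or the implied phenotypic covariance raise
structured `ntfInadmissible` errors; during optimisation such points are
treated as infinite-cost, never clamped.  Warm-starting the iteration from
the previous optimiser evaluation accelerates fitting; if a warm start
fails, the solver retries cold so the objective remains a function of the
parameters alone.

### Relative-pair covariance blocks

All expected blocks follow from the structural equations and the copath
rule.  Two are worth noting:

* **Parent-offspring.**  Besides the direct genetic half-path, the
  assortment-mediated route runs through the co-parent's *full phenotype*:
  `Cov(P_o, P_father) = L_o (Cgp_m + Cgp_f t(mu) Vp_m) / 2 + ...` — the
  copath rule applied to the complete system, not just to the co-parent's
  genotype.  The simulation oracle discriminates sharply between the two
  forms and confirms this one.
* **Opposite-sex pairs** share D/S/T at correlations `r_D`, `r_S`, `r_T`,
  and their additive block uses `L_m` on one side and `L_f` on the other
  with the common `QG`.

## Estimation

Fitting is raw-data (full-information) maximum likelihood: families are
grouped by configuration and missingness pattern, each group's data are
reduced to sufficient statistics (crossproduct and column sums), and the
-2 log-likelihood sums `k_obs log(2 pi) + log det Sigma_obs +
tr(Sigma_obs^-1 S)` over groups, where `Sigma_obs` is the model-implied
family covariance restricted to observed entries.  Deleting a fully
missing member therefore leaves the likelihood exactly unchanged, and the
result is independent of the grouping.  Means default to zero (appropriate
for standardized residuals); per-trait or per-trait-by-sex free means are
available.

The optimiser is `nlminb` (quasi-Newton with numerical gradients) under
box constraints — path-matrix diagonals nonnegative, cross-sex
correlations in [-1, 1], copaths free within the convergent region — with
multi-start jitter.  Likelihood-ratio tests use the plain chi-square
reference, the convention in this literature; at a variance
boundary this is conservative relative to mixture references, which is
noted rather than corrected.  Tiny negative likelihood-ratio statistics
(within the optimiser's relative precision, `max(1e-6, 1e-8 |2lnL|)`) are
clamped to zero with a flag; larger negatives raise an error because they
indicate an unconverged full model.  AIC is `-2lnL + 2k` with k counting
free parameters (equality groups once, equilibrium constraints
subtracted).

### Constraining the q off-diagonal

Testing gametic phase disequilibrium requires fitting a model whose
equilibrium q has a zero off-diagonal.  Two implementations were
considered.  Clamping `q_12 = 0` inside the fixed-point iteration turned
out to be vacuous: the spousal covariance Gamma still feeds the sibling
and parent-offspring blocks, and the free cross-paths (`a_21`, `d_21`,
`s_21`, `e_21`) absorb what remains, so the "constrained" model attains
the full model's likelihood exactly — the test statistic is identically
zero.  The package therefore restricts the *parameter space* instead:
fits with `constrainQ = TRUE` minimise the likelihood subject to
`q_12(theta) = 0`, enforced by a quadratic penalty (1e6, tightened by a second pass from
the first-pass solution when the residual `|q_12|` still exceeds 2e-4;
the reported -2lnL is the raw likelihood at the solution, and the
residual is typically below 1e-4).  Under this semantics the constraint genuinely conflicts with
the observed spousal cross-correlations and the test has power.  One
effective parameter is charged against k, so the test carries a single
degree of freedom.

A related identification fact, established by simulation during
development and worth knowing when designing studies: with all path
matrices equated across the sexes, the q-off-diagonal constraint remains
almost perfectly absorbable by the cross-paths, and the test has little
power at any realistic sample size.  The leverage comes from the
sex-specific additive structure — q is shared across the sexes while the
Cholesky cross paths are not — which is why the discrimination presets
(`ntfTruthPreset("pleiotropy_only")`, `"assortment_only"`) keep `a_m` and
`a_f` sex-specific (and, for parsimony, equate the nuisance matrices d, s,
e; see `discriminationModel()`).

## The generational simulator

`simulatePopulation()` runs the generative recursion forward: each
generation draws fresh D/S/T/E latents, forms phenotypes, mates the pools,
and produces offspring by the infinitesimal model.  Mate matching is a
sorting-based Gaussian-copula coupling: phenotypes are whitened and
rotated to canonical axes (SVD of the whitened target cross-covariance),
desired partner scores are generated at the target canonical correlations,
actual partners are matched to them by binned rank matching, and a few
refinement rounds correct the residual coupling (the matching is unbiased
within Monte-Carlo error).  A requested spousal structure whose joint
covariance is not positive semi-definite (canonical correlation >= 1) is
refused.  Under social homogamy, couples pair at random and a shared
couple environment C is drawn at pair formation and passed to the
children; an individual's natal C is replaced by the marital C in
adulthood, which treats C as nuclear-family context — the single-family
analytic model is silent on the transgenerational bookkeeping, and this
choice keeps simulation and analytic moments in exact agreement while
leaving the gene pool untouched (q = I exactly).

The simulator converges to the analytic fixed point at the true
generational map's linear rate (roughly halving the distance each
generation, more slowly under strong assortment with vertical
transmission); the analytic solver iterates the stationarity equation,
which has the same fixed point but a different transient.  Oracle tests
therefore allow enough generations for the transient to fall well inside
Monte-Carlo error: 15 generations at the study-like assortment strengths,
20 for the strongest regimes.

`simulateFamilies()` draws mated pairs with replacement and generates
offspring with the exact sharing structure the analytic blocks assume (MZ
co-twins copy A, B, D; all siblings share S and — deterministically given
the parents — F; twins share T; opposite-sex pairs draw D/S/T at the
cross-sex correlations).  `applyObservationModel()` maps the standardized
traits onto raw scales (IQ-like mean 100, SD 12; height-like centimetre
scale), adds sex, age and age-squared effects with role-specific uniform
age ranges (twins 12-28 sharing one age, siblings 10-35, parents 29-78),
and injects gross outliers (at least 4 SD from the clean mean) and
missingness.  `studyFixture()` composes these into the bundled synthetic
study: a four-sample design (twins+siblings+parents; two twin+sibling
samples without parents; one sibling+parent sample without twins) at
realistic family counts, with exactly 8 low and 2 high height outliers.

**What the generator does and does not emulate.**  It reproduces the
statistical structure the model assumes — multivariate-normal latents,
equilibrium assortment, linear covariate effects, pattern missingness —
so passing oracle and recovery tests demonstrates internal correctness of
the algebra and estimation, not robustness to real-data violations
(non-normality, age-varying architecture, selective participation,
assortment on unmeasured composites).  The `studylike` preset was
calibrated once so that the implied relative correlations sit where a
large twin-family study of IQ and height reports them (MZ about .82-.90,
DZ/sib about .44-.51, spousal .33/.18 within traits and .08/.15 across,
within-person cross-correlation about .1); it is the package's reference
regime, not a refit of any particular data set.

## The analysis pipeline

`runPipeline()` chains the study's analysis sequence:

1. **Adjustment** (`adjustPhenotypes`): per trait, least-squares
   adjustment for sex, age and age squared (optionally within sample),
   removal (set to missing) of scores beyond 4 SD, refit without them,
   and standardization of residuals to overall mean 0 and variance 1
   (within-sex variances stay free).  Counts are logged by trait and
   sign.  Preliminary equality testing of means/variances across relative
   types is deliberately simplified to the means-model options rather
   than a full saturated model.
2. **Mating-model comparison** (`compareMatingModels`): ABDSTE and ABDFTE
   (phenotypic assortment) and ABDCTE (social homogamy) are fit to the
   same data and ranked by AIC — they are not nested.
3. **Sequential reduction** (`sequentialReduction`): whole 2x2 matrices
   are dropped all-or-none, candidates ordered by the share of phenotypic
   variance they explain (operationalised as the summed share of both
   traits' variance attributable to the matrix in the current fit,
   smallest first — the ordering metric is configurable since the verbal
   rule does not pin it down), followed by cross-sex-correlation fixes to
   1, the copath symmetry constraint `mu_12 = mu_21`, and a test of
   `mu = 0`.  An edit is accepted when p >= threshold (default .10: a
   liberal criterion, so a matrix is retained when there is evidence for
   it in either trait); accepted edits accumulate; no multiple-testing
   correction is applied across steps, mirroring the sequential
   procedure.  A model dropping E is never attempted.
4. **Decomposition** (`decomposeFinal`): per-sex narrow and broad
   heritabilities and the additive genetic correlation r_A; the
   pleiotropy test (zero the a cross-paths, 2 df), the
   gametic-phase-disequilibrium test (q off-diagonal, 1 df), their joint
   test (3 df); and the assortment-inflation percentages (observed
   `a q a'` against the `q = I` random-mating counterfactual).

The exported functions plus `inst/scripts/ntf-pipeline.R` (a thin Rscript
front-end) are the interface; every step writes plain-text reports.

## Problem sizes and test design

The package's checks run at sizes chosen to keep Monte-Carlo error well
inside the asserted tolerances while remaining routine to execute: oracle
moment checks compare roughly one hundred block elements against 200,000
simulated families at 4 Monte-Carlo standard errors, drawn from a parent
pool of 200,000 couples so that resampling parents does not understate
the Monte-Carlo error of parent-side blocks; the univariate equilibrium
is checked against 200,000 mated pairs over 15 generations; parameter
recovery fits 25 replicates of 2,000 families under the sex-equated
study-like truth; the mating-model AIC comparison uses 25 replicates per
generating regime (2,400 families under phenotypic assortment, where
homogamy's smaller parameter count gives it an AIC head start and the
two families mimic each other closely; 1,200 under homogamy); and the
pleiotropy/disequilibrium discrimination uses 9 replicates of 800
families per regime with the sex-specific discrimination class.  Majority
criteria (rather than exact rates) are asserted for the selection studies
because single replicates at these scales retain appreciable sampling
variability.

## Known limitations

* Two traits only; the trait order is fixed and Cholesky-order sensitivity
  is acknowledged, not explored.
* No epistasis or gene-environment interaction; D absorbs genetic
  non-additivity broadly.
* Equilibrium (stationary) assortment only in the analytic core; the
  simulator covers transients.
* No standard errors beyond likelihood-ratio machinery; no ordinal traits.
* The vertical-transmission closed forms are not derived symbolically;
  the joint fixed point is validated against the agent-based oracle.
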