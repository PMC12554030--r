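---
title: "Multiomics risk scores for episodic memory: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiomics risk scores for episodic memory: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific problem

Episodic memory (EM) — the ability to encode and recall events — declines
early on the path to dementia, which makes it a useful endophenotype for
risk stratification before diagnostic criteria are met. `memoscore`
implements a complete pipeline that asks a concrete question: *how much
predictive value do molecular risk scores add to classical epidemiological
dementia risk factors?* Four per-person scores are built and compared:

* **CAIDE**, the integer cardiovascular dementia risk score over seven
  components (age, sex, education, systolic blood pressure, BMI, total
  cholesterol, physical inactivity);
* **MRS**, a metabolic risk score: a weighted sum of blood metabolite
  measures selected by a metabolome-wide LASSO;
* **LASSO-PRS**, a sparse polygenic score from a genome-wide LASSO fitted
  on individual-level dosages;
* **GWAMA-PRS**, a dense polygenic score whose weights are Bayesian
  posterior means computed from external meta-analyzed summary statistics
  under a continuous-shrinkage prior with a linkage-disequilibrium (LD)
  reference.

Each score's incremental contribution is quantified in a held-out test
sample via nested linear models, with layered false-discovery-rate control,
and the polygenic scores are additionally transferred to child cohorts with
deliberately incomplete variant overlap.

Because the individual-level data of the motivating study design are not
publicly deposited, the package ships a first-class synthetic-cohort
generator that reproduces the *statistical structure* the analysis assumes.
All claims the test suite makes are claims about that structure, not about
any real cohort.

## The synthetic cohort generator

`sim_config()` fixes the study conditions. The defaults are the conditions
the package emulates throughout: 1001 adults (897 training / 104 test), a
5000-variant panel in 50 LD blocks standing in for roughly a million imputed
SNPs, heritability $h^2 = 0.30$ concentrated in 10 causal variants
(twin-study estimates for EM span 30–60%, and a sparse architecture is the
regime in which a LASSO-based score is the method of interest), 137
correlated metabolic measures of which 15 carry signal (mirroring a standard
NMR panel), and an external meta-analysis of 23 cohorts averaging 1278
samples (total ≈ 29,400). The metabolome explains 5% of outcome variance and
the CAIDE score 2% by default — small fractions chosen so that the
epidemiological and metabolomic layers are plausible but weak relative to
genetics, the regime the evaluation layer is designed to distinguish.

**Genotypes.** Variants are split into contiguous blocks. For each sample,
two latent haplotype liabilities follow a stationary first-order
autoregressive Gaussian process across the variants of a block
(correlation `ld_rho`, default 0.8); each liability is thresholded at the
normal quantile of the variant's minor allele frequency (drawn uniformly
from `maf_range`, default 0.05–0.5) and the dosage is the sum of the two
alleles. This construction gives exact Hardy–Weinberg genotype frequencies
at every MAF while providing tunable block LD; the realized adjacent-variant
dosage correlation is `ld_rho` *attenuated* by the double thresholding, and
the test suite pins that attenuation against a 10^6^-draw Monte-Carlo oracle
of the same thresholding. The generator does **not** attempt realistic human
LD maps, imputation uncertainty, or population stratification; ancestry PCs
are carried as covariates downstream but are pure noise directions in
synthetic data.

**Outcome.** The continuous EM score is
$y = X\beta_g + M\beta_m + \gamma\,\mathrm{CAIDE} + \varepsilon$, with each
component rescaled on the realized sample so its variance fraction equals
the configured budget exactly (cross-terms contribute only Monte-Carlo
error). CAIDE enters through the integer score with a negative sign — more
risk factors, poorer memory. The reported scale is `20 + 4y`, i.e. roughly a
0–30 word-list-learning total; since the source instrument's distributional
treatment is not fixed, the generator emits the continuous score (used
everywhere) plus a clipped integer 0–30 version.

**External cohorts.** The emulated meta-analysis inputs reuse the same
variant universe (derived deterministically from the seed) and the same
causal coefficients, so effects are homogeneous across cohorts; each cohort
is an independent draw with unit-variance outcome and its own
per-variant univariate GWAS.

## Penalized regression with unpenalized covariates

The two LASSO analyses minimize

$$\frac{1}{2n}\lVert y - Z a - X b \rVert^2 + \lambda \lVert b \rVert_1,$$

where the covariate block $Z$ (intercept; CAIDE and age for both omics
layers; ancestry PCs for the genome-wide fit; the blood-draw interval for
the metabolome-wide fit) is never shrunk. Because $a$ is unpenalized, it is
profiled out exactly: the problem is solved by cyclic coordinate descent
(soft-thresholding updates) on the $Z$-residualized design, and $a$ is
recovered by an exact least-squares solve at every $\lambda$. Convergence is
declared from the Karush–Kuhn–Tucker conditions directly — worst violation
below `tol` (default $10^{-7}$) — which is robust where coefficient-change
criteria stall on near-collinear dosage columns. The test suite verifies
objective equality against an exact active-set/sign enumeration solver on
every instance with ≤ 8 features, and soft-threshold closed forms for single
features.

The $\lambda$ grid holds 100 log-spaced values below
$\lambda_{\max} = \max_j |x_j^\top M y|/n$ (the smallest all-zero penalty).
Grid depth follows the reference-implementation convention: down to
$10^{-3}\lambda_{\max}$ with comfortably more samples than features, but
$10^{-2}\lambda_{\max}$ otherwise (including a 1.5× margin so
cross-validation folds stay overdetermined) — near the interpolation limit
deeper grids are ill-conditioned and coordinate descent needs unbounded
sweeps for KKT-level accuracy. Both depth and grid size are configurable.

Two tuning protocols mirror the study: a single 80/20 training/validation
split for the genome-wide fit and 10-fold cross-validation for the
metabolome-wide fit, both selecting the $\lambda$ at minimum validation
error (largest $\lambda$ on ties) and then refitting on the full fitting
sample. The exact split fraction and selection rule are not fixed by the
design being emulated; the minimum rule (rather than 1-SE) is the default
because the emulated study reports a relatively large selected set, which is
minimum-rule behavior. One caveat the suite documents honestly: under a
pure-noise outcome the minimum rule picks a small non-empty model in roughly
half of replicates — the validation curve at $n_{val} \approx 60$ is noisy —
so sparsity under the null is "usually empty, always small", not
"always empty". Metabolites are used untransformed by default; a
transformation hook exists at the matrix level.

Weights are exported on the per-unit raw scale ($b/s_j$, per allele for
variants), so scores can be applied to unstandardized panels elsewhere.

## Summary statistics, meta-analysis, and the shrinkage posterior

`run_gwas()` computes per-variant OLS (dosage + covariates + intercept) via
the Frisch–Waugh–Lovell decomposition, which reproduces joint-model
estimates and t-tests exactly; monomorphic variants are flagged, not
silently dropped. `meta_fixed()` is the inverse-variance fixed-effect
combination ($w_i = 1/se_i^2$) with Cochran's Q and I² reported but not
acted on, allele reconciliation by sign-flip, and strict `<` at the
genome-wide threshold $5\times10^{-8}$.

`sample_posterior_effects()` draws posterior mean effects under the
gamma-gamma global-local hierarchy

$$\beta_j \sim N(0, \tfrac{\sigma^2}{n}\psi_j),\qquad
  \psi_j \sim \mathrm{Gamma}(a, \delta_j),\qquad
  \delta_j \sim \mathrm{Gamma}(b, \phi),$$

with block-wise multivariate-normal updates
$\beta_{blk} \mid \cdot \sim N(A^{-1}\hat\beta_{blk},
\tfrac{\sigma^2}{n}A^{-1})$, $A = R + \mathrm{diag}(1/\psi)$, a conjugate
inverse-gamma update for $\sigma^2$, gamma updates for $\delta$ and (in
`phi = "auto"` mode) for the global parameter, and generalized
inverse-Gaussian draws for $\psi$ (a Devroye-type rejection sampler,
compiled, driven by R's RNG for reproducibility). Defaults $a = 1$,
$b = 0.5$, 1000 iterations / 500 burn-in / thinning 5 and the $\psi \le 1$
cap mirror the reference settings of continuous-shrinkage polygenic-score
software; the cap can be lifted (`psi_max = Inf`), which the quadrature
tests do, since a capped chain is no longer a clean posterior. Whether the
global parameter was fixed or adaptive in the emulated study is unknown, so
both modes exist and `auto` is the default. LD references are per-block
correlation matrices, eigenvalue-floored at $10^{-6}$; block definitions
come from the generator's true structure in tests and from the user for
real inputs. Marginal effects enter on the standardized scale as
$z_j/\sqrt{n_j}$ and posterior means are back-transformed per allele using
the reference-panel dosage SDs (assuming unit trait variance — only the
score's scale, which is re-standardized downstream, depends on this).

The sampler is validated three ways: single-variant posterior means against
1-D numerical quadrature of the same hierarchy (2% tolerance; the weak
signal regime $z \approx 2.5$ mixes slowly and is estimated by pooling
independent chains), null-data posterior means within 3 batch-means
Monte-Carlo SEs of zero, and monotone shrinkage in $\phi$.

## Evaluation: nested models and layered FDR

The grid holds 12 linear models: background covariates only; background plus
each single score; CAIDE plus each PRS and/or the MRS; and MRS plus each
PRS. The two PRSs are never combined. The background covariate set (age at
assessment, blood-draw interval, ancestry PCs) is applied to *every* model
of a dataset, so that $R^2$ differences are attributable to the scores
alone; the alternative — per-model covariate sets keyed to which omics layer
is present — changes baselines between comparisons and was rejected for
that reason. Incremental $R^2$ is reported in percentage points and is
nonnegative for nested pairs by construction; model improvement is read from
adjusted $R^2$, predictor p-values, and AIC/BIC (full Gaussian-likelihood
convention, constants included, so deltas match mainstream software; only
deltas are interpreted). Scores are standardized within each evaluation
sample (not with training moments), so coefficients are per-SD in that
sample.

Multiple testing follows two Benjamini–Hochberg schemes over score
p-values pooled across all models and both test datasets (the full test
sample and its stroke-excluded sensitivity copy): *within-layer* families
(CAIDE | MRS | both PRSs as one genomics family) and *per-term* families,
which for the PRSs is the "each PRS separately" correction. Child-cohort
transfer fits (age, sex, maternal education as background) are corrected
separately. Child outcomes carry no adult genetic signal by default
(`h2_shared = 0`), matching the qualitative transfer result the design
anticipates; the parameter exists to explore the alternative.

## Numerical and reproducibility choices

* One top-level seed deterministically derives every stage seed via a
  string-hash (`derive_seed()`), and the run manifest records them, so any
  stage can be reproduced in isolation. `run_study()` output is
  byte-identical across repeated runs with one seed.
* Coordinate descent: KKT-based stopping at `tol`; λ_max inflated by a
  factor $1+10^{-6}$ so the top of the path is exactly null.
* Ties in tuning curves resolve to the largest λ; CV folds are seeded
  `sample(rep_len(1:k, n))`.
* Missing dosages are mean-imputed per variant for PCA, fitting and
  scoring (standard scoring-tool behavior); covariates are never imputed
  (complete-case evaluation).
* Strand-ambiguous (A/T, C/G) variants are dropped during harmonization
  rather than frequency-resolved, the simplest policy that is always
  correct without allele-frequency metadata; the synthetic universe
  therefore emits non-palindromic pairs only, and palindromic handling is
  exercised by hand-built fixtures.
* Degenerate inputs: zero-variance features are dropped with a log entry;
  an empty weight table scores zero with a warning; a score with zero
  variance in a dataset excludes the models that contain it (logged)
  rather than producing a rank-deficient fit.

## Problem sizes used by the automated checks

The suite runs the full adult scale where the property demands it (897
training samples, 5000 variants, external meta-analysis totalling ≈ 30k for
the parameter-recovery checks) and deliberately smaller scales elsewhere:
the end-to-end conclusion-pattern replicates use 1000-variant panels with a
6000-sample external layer and short shrinkage chains, and the determinism
check uses a compact configuration. These sizes are the package's own
desk-scale choices: each is stated next to the check it supports, and the
recovery margins observed (e.g. held-out PRS/true-genetic-value correlations
near 0.9 against a 0.4 threshold) leave the conclusions insensitive to the
exact scale.

## Known limitations

* The LD model is block-AR(1) by construction; conclusions about methods
  whose behavior depends on long-range or irregular LD do not transfer.
* The external meta-analysis emulation assumes a common trait scale across
  cohorts; harmonizing heterogeneous memory instruments is upstream of this
  package.
* The continuous-shrinkage sampler supports user-supplied block definitions
  but no built-in recombination-map segmentation, and no multi-ancestry
  extension.
* Passing tests on synthetic data demonstrate internal correctness and
  statistical calibration of the machinery — not predictive performance on
  any real cohort.
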