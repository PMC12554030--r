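# memoscore

Multiomics risk scores for prediction of episodic memory.

`memoscore` is an R package for biostatisticians and genetic
epidemiologists who want to quantify how much predictive value molecular
risk scores add to classical epidemiological dementia risk factors for
episodic memory (EM) — a cognitive endophenotype that declines years before
dementia is diagnosable. It implements, end to end:

* the **CAIDE** dementia risk score (points for age, male sex, low
  education, hypertension, obesity, hypercholesterolemia, inactivity;
  configurable point table, default maximum 15);
* a **metabolic risk score (MRS)** and a sparse polygenic score
  (**LASSO-PRS**) from in-repo L1-penalized regression with *unpenalized*
  covariates, minimizing
  `(1/2n)·||y − Za − Xb||² + λ·||b||₁`
  by cyclic coordinate descent with KKT-verified convergence, tuned by a
  training/validation split (genome-wide) or k-fold cross-validation
  (metabolome-wide);
* per-variant GWAS (`run_gwas`), inverse-variance fixed-effect
  meta-analysis (`meta_fixed`: `β = Σwᵢβᵢ/Σwᵢ`, `se = (Σwᵢ)^(−1/2)`,
  `wᵢ = 1/seᵢ²`, with Cochran's Q and I²) and genome-wide-significance
  filtering at p < 5×10⁻⁸;
* a dense Bayesian polygenic score (**GWAMA-PRS**): posterior-mean effects
  from summary statistics under the gamma-gamma continuous-shrinkage
  hierarchy `βⱼ ~ N(0, σ²ψⱼ/n)`, `ψⱼ ~ Gamma(a, δⱼ)`, `δⱼ ~ Gamma(b, φ)`,
  Gibbs-sampled over LD blocks with generalized-inverse-Gaussian updates;
* allele harmonization (strand-flip, palindromic drop, coverage reports),
  PLINK bed/bim/fam + VCF + TSV genotype I/O, ancestry PCs;
* an evaluation grid of 12 nested linear models with incremental R²
  (percentage points), adjusted R², AIC/BIC, and two layered
  Benjamini–Hochberg FDR schemes, plus a stroke-exclusion sensitivity
  re-analysis and transfer of adult-derived PRSs to child cohorts;
* a first-class synthetic-cohort generator (`sim_config`,
  `simulate_cohort`, `simulate_external_sumstats`) that emulates the
  statistical structure of a late-adulthood birth-cohort study — 897
  training / 104 test adults, block-LD genotypes, 137 correlated
  metabolites with 15 causal, an external ~30k-sample meta-analysis — so
  the whole pipeline is testable without any data download.

The methods vignette (`vignettes/multiomics-memory-scores.Rmd`) documents
the models, defaults, and numerical choices.

## Worked example

A compact synthetic study (same pipeline as the full scale, smaller panel):

```r
library(memoscore)

config <- list(
  seed = 11,
  sim = list(n_samples = 220, n_variants = 300, n_blocks = 10,
             n_external_cohorts = 3, external_n_per_cohort = 400),
  test_n = 50, n_lasso_gwas = 150, n_lasso_mwas = 150,
  penalized = list(grid_size = 40),
  csprs = list(n_iter = 120, n_burnin = 60, thin = 2),
  children = list(cohorts = list(
    children_a = list(n = 80, age_mean = 11.9, overlap = 0.93),
    children_b = list(n = 90, age_mean = 8.6, overlap = 0.945))))

res <- run_study(config, out_dir = "study_out")

subset(res$comparisons, baseline_label == "caide" & dataset == "test_main")
```

```
  baseline_label  extended_label delta_r2_pp delta_aic delta_bic added_terms  added_p_min   dataset
6          caide caide+gwama_prs    25.34440 -17.24865 -15.33662   gwama_prs 6.389029e-05 test_main
7          caide caide+lasso_prs    21.71176 -13.99183 -12.07980   lasso_prs 2.684767e-04 test_main
```

Adding either polygenic score to the CAIDE + background baseline raises
explained variance by ~22–25 percentage points in this 50-person test set
(the synthetic heritability is 0.30 and the panel is small, so recovery is
much cleaner than in a realistic cohort), and lowers AIC/BIC. The layered
FDR table shows both PRS terms surviving the genomics-family correction:

```r
head(res$fdr$within_layer)
```

```
       term           model   dataset            p   family        p_adj
1     caide           caide test_main 8.342886e-03    caide 0.0083428863
2     caide caide+gwama_prs test_main 5.175013e-03    caide 0.0077625200
3 gwama_prs caide+gwama_prs test_main 6.389029e-05 genomics 0.0003628012
4     caide caide+lasso_prs test_main 1.369597e-03    caide 0.0041087907
5 lasso_prs caide+lasso_prs test_main 2.684767e-04 genomics 0.0007159378
6 gwama_prs       gwama_prs test_main 9.070029e-05 genomics 0.0003628012
```

while the adult-derived PRSs transfer weakly to the child cohorts
(`res$children$fdr`), which carry no shared genetic signal by default.
`run_study()` writes every stage table plus a `manifest.json` with derived
seeds; rerunning with the same seed reproduces the outputs byte for byte.

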