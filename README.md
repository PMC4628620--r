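# ecgherit

Pedigree-based heritability of electrocardiographic traits, and how much of
it known GWAS variants explain.

## The problem

In extended families, ECG intervals (PR, QRS, QT) and the voltage-duration
products used as left-ventricular-hypertrophy proxies (Sokolow–Lyon, Cornell,
12-lead sum) are heritable quantitative traits. `ecgherit` estimates the
narrow-sense heritability of each trait from pedigree relatedness and then
asks the follow-up question: when the genome-wide-significant SNPs for these
traits enter the model as fixed effects, how much does the heritability drop —
including SNPs discovered for *other* ECG traits (cross-phenotype effects)?

The core model is the polygenic variance-component model

    y = Xβ + g + e,    g ~ N(0, 2Φ σ²g),    e ~ N(0, I σ²e),

where Φ is the kinship matrix computed exactly from the pedigree by the
recursive tabular method and h² = σ²g/(σ²g + σ²e). The likelihood is
maximized after a one-time eigendecomposition of 2Φ, profiling β and the
total variance analytically and searching the single ratio h² ∈ [0, 1], so a
fit is a one-dimensional optimization. Significance of h² = 0 uses the
boundary ½χ²₀ + ½χ²₁ mixture; model comparisons use nested likelihood-ratio
tests on ML fits.

Per trait, the package fits the three conditioning models of the analysis —
model 1 (no SNPs), model 2 (trait-specific SNPs; the LVH proxies borrow the
QRS set), model 3 (all catalog SNPs) — and reports Δh², the proportion of
model-1 heritability explained, and a per-SNP-set cross-phenotype
decomposition. A gene-dropping simulator generates family cohorts
(~1500 individuals, median pairwise kinship ≈ 0.004, skewed nonzero
inbreeding) with exactly known variance composition, so the whole pipeline is
validated by parameter recovery. See the methods vignette
(`vignettes/ecg-heritability-methods.Rmd`) for the statistical details.

## Worked example

```r
library(ecgherit)

bundle <- simulate_ecg_cohort(seed = 42)      # pedigree, ECGs, dosages, catalog
kin    <- kinship(bundle$pedigree)
prep   <- prepare_traits(bundle$cohort)       # exclusions, Bazett/SL/CV/12LS,
                                              # residualize, inverse-normal
snps   <- select_index_snps(bundle$catalog,
                            available = colnames(bundle$dosages))
report <- heritability_report(prep$traits, kin, bundle$dosages, snps,
                              traits = c("QRS", "PR"))
print(report)
```

```
Three-model heritability report
 trait    n       h2 m1       h2 m2 dh2 1-2 expl %       h2 m3 dh2 2-3
   QRS 1192 0.29 (0.05) 0.25 (0.05)    0.04   12.8 0.24 (0.05)    0.02
    PR 1198 0.50 (0.05) 0.49 (0.05)    0.01    1.6 0.50 (0.06)   -0.01
```

Reading the QRS row: on this simulated cohort of 1192 analyzable individuals
the unconditioned heritability estimate is 0.29 (SE 0.05); adding the 21
QRS-associated SNP dosages lowers it to 0.25, i.e. the SNPs explain ~13 % of
the heritability, and the remaining catalog SNPs explain little more. (The
generating truth for this cohort is h² = 0.34 with a 0.06 SNP fraction;
single-cohort estimates scatter around the truth with SD ≈ 0.05, which is
what the replicate-averaged recovery studies below quantify.)

A single fit exposes the usual modelling surface:

```r
d   <- data.frame(id = prep$traits$id, QRS = prep$traits$QRS)
fit <- polygenic(QRS ~ 1, data = d, kinship = kin)
summary(fit)
```

```
Polygenic variance-component model (ML)
  n = 1192, fixed effects: 1
  h2 = 0.288 (SE 0.052)   sigma2_g = 0.288   sigma2_e = 0.712
  logLik = -1655.07   P(h2 = 0) = 7.05e-17
```

`coef()`, `logLik()`, `residuals()` (marginal or conditional on the BLUP
breeding values), `predict()`, `simulate()`, `plot()` (profile likelihood
over h²) and `anova()` (nested LRT) behave as for other fitted-model classes.

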