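---
title: "Two-trait single-step genomic evaluation of fillet yield and body weight: models, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-trait single-step genomic evaluation of fillet yield and body weight}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`troutGS` implements a complete two-trait genetic-evaluation pipeline for an
aquaculture breeding program selecting on fillet yield (FY, %) and body
weight (BW, g): pedigree BLUP (PBLUP) and single-step genomic BLUP
(ssGBLUP), AI-REML variance components, three validation schemes, weighted
ssGBLUP, window-based single-step GWAS, and a seeded breeding-program
simulator that generates data with the statistical structure the evaluation
assumes. This vignette documents the models, the numerical algorithms, and
the design decisions that were genuinely open.

## The evaluation model

Both traits are analysed jointly with the animal model

$$ \mathbf{y}_t = \mathbf{X}\mathbf{b}_t + \mathbf{Z}_1\mathbf{u}_t +
   \mathbf{Z}_2\mathbf{f}_t + \mathbf{e}, $$

where $t$ indexes the trait, $\mathbf{b}_t$ are fixed effects,
$\mathbf{u}_t$ additive genetic effects with
$\mathrm{var}(\mathbf{u}) = \Sigma_u \otimes \mathbf{A}$ (or
$\Sigma_u \otimes \mathbf{H}$ in the single-step model), $\mathbf{f}_t$
full-sib family effects with $\mathrm{var}(\mathbf{f}) = \Sigma_f \otimes
\mathbf{I}$, and $\mathbf{e}$ residuals. The FY model carries a harvest-age
covariate, line, and the harvest-year x slaughter-group interaction; the BW
model carries age, line and hatch year (`trout_model_spec()`). Records
missing one trait contribute a univariate residual; records with both traits
use the full 2x2 residual covariance. The additive, family and residual
covariance matrices are all full 2x2 by default; whether the family and
residual cross-trait covariances are estimated or fixed at zero is
configurable (`free_cov_e`), since reasonable evaluations exist either way.

Fixed-effect design matrices are built as full indicator sets per term and
reduced to full rank by pivoted QR **on the rows where the trait is
recorded**. This keeps single-level factors and interaction-only terms valid
(a cohort measured in one year still has a well-defined design) and makes
the dropped-level choice deterministic: the intercept and earlier terms win.

## Relationship matrices

* `build_A` / `build_A_inverse`: tabular-method $\mathbf{A}$ and Henderson's
  sparse $\mathbf{A}^{-1}$ with inbreeding; inbreeding coefficients come
  from the Meuwissen-Luo style recursion over Mendelian-sampling variances
  (exact, $O(n \cdot \text{ancestors})$). Unknown parents are unrelated,
  non-inbred base animals; there are no genetic groups because the
  evaluation model has none.
* `build_G`: VanRaden's genomic relationship matrix
  $\mathbf{G} = \mathbf{Z}\mathbf{D}\mathbf{Z}' / (2\sum_i d_i p_i(1-p_i))$
  with gene contents centred at twice the *base-population* allele
  frequencies. The weighted denominator keeps the trace scale stable as SNP
  weights change across weighted-ssGBLUP iterations (the unweighted case is
  unaffected). Missing genotypes are imputed to $2p$, i.e. zero after
  centring.
* `estimate_base_frequencies`: base frequencies by generalised least
  squares on gene content, $2\hat p = (\mathbf{1}'\mathbf{A}_{22}^{-1}
  \mathbf{m}) / (\mathbf{1}'\mathbf{A}_{22}^{-1}\mathbf{1})$ — the
  variance-ratio-to-zero limit of the gene-content mixed model. Frequencies
  are clamped to $[0.01, 0.99]$ to protect the denominator. A consequence
  worth knowing: with these GLS frequencies $\mathbf{Z}'\mathbf{A}_{22}^{-1}
  \mathbf{1} = \mathbf{0}$ exactly, so the raw $\mathbf{G}$ is singular by
  construction (one null vector). The default blending
  $\mathbf{G} \leftarrow 0.95\,\mathbf{G} + 0.05\,\mathbf{A}_{22}$ restores
  invertibility; `tau` is a configuration knob and `tau = 0` is available
  when base frequencies are known externally (as in simulations).
* `build_H_inverse`: the single-step inverse, $\mathbf{A}^{-1}$ plus
  $(\mathbf{G}^{-1} - \mathbf{A}_{22}^{-1})$ scattered into the genotyped
  block. It reduces to $\mathbf{A}^{-1}$ bit-for-bit with no genotyped
  animals or when $\mathbf{G} = \mathbf{A}_{22}$.

## AI-REML

`estimate_vc_aireml` maximises the restricted likelihood by
average-information updates:

* **Gradients** use exact trace terms. The traces
  $\mathrm{tr}(\mathbf{A}^{-1}\mathbf{C}^{uu}_{ab})$,
  $\mathrm{tr}(\mathbf{C}^{ff}_{ab})$ and the residual terms
  $\mathrm{tr}(\mathbf{C}^{-1}\mathbf{W}'\mathbf{R}^{-1}
  (\partial\mathbf{R})\mathbf{R}^{-1}\mathbf{W})$ need selected entries of
  the inverse coefficient matrix; these come from a Takahashi selected
  inversion of the simplicial sparse Cholesky factor (implemented in C++,
  exact on the factor's pattern — verified against dense inverses in the
  test suite).
* **The AI matrix** is built from working variates, one extra sparse solve
  per free parameter, reusing the factor.
* **Boundary handling** is an active set: when an AI step drives a variance
  through zero, the variance is pinned just off the boundary (at $10^{-8}$
  of the trait's total variance), its within-component covariances are
  pinned at zero, and the pinned parameters are excluded from subsequent
  updates until their gradient points back into the interior. Plain
  step-halving was measured to produce a geometric crawl near boundaries
  (hundreds of iterations); pinning restores fast convergence. If a
  projected step is still invalid, the additive and family matrices fall
  back to their closed-form EM update; the residual matrix has no
  closed-form EM under heterogeneous missing-trait patterns and keeps its
  current value for that iteration.
* **Convergence** is declared when the relative norm of the parameter
  change falls below `1e-8` (cap 200 iterations, non-convergence flagged).
  Standard errors come from the inverse AI matrix at convergence; the
  derived parameters ($h^2_t$, $f^2_t$, $r_g$) get delta-method standard
  errors with a numerical Jacobian.

The restricted likelihood, its analytic gradient and the Takahashi traces
are each verified against dense-matrix oracles in the test suite; a
balanced half-sib design is checked against the closed-form ANOVA
estimator through the exact sire-model reparameterisation.

## Validation

Three schemes, as produced by `validation_study` and `midparent_study`:

* **Mid-parent**: family-mean progeny phenotype (raw or adjusted) against
  the parent average (PA) of (G)EBVs from a run excluding those progeny.
  Half-sib families are removed first (families sharing a sire or dam with
  an already-kept family are dropped, first occurrence wins). The
  family-mean phenotype is regressed **on** PA, so a slope below 1 means
  over-dispersed breeding values; the opposite regression direction would
  reverse that interpretation and is inconsistent with how the dispersion
  diagnostics are read, so it is not used.
* **Adjusted phenotypes**: $\mathbf{y}^* = \mathbf{y} - \mathbf{X}\hat{\mathbf b}
  - \mathbf{Z}_2\hat{\mathbf f}$ from the whole-data pedigree run;
  accuracy $= \mathrm{cor}(\mathbf{y}^*, \hat{\mathbf u}_p)/\sqrt{h^2}$, and
  bias/dispersion from regressing $\mathbf{y}^*$ on $\hat{\mathbf u}_p$.
* **LR method**: accuracy
  $\sqrt{\mathrm{cov}(\hat u_w,\hat u_p) / ((1-\bar F)\hat\sigma^2_u)}$,
  bias $\bar{\hat u}_p - \bar{\hat u}_w$, slope
  $\mathrm{cov}(\hat u_w,\hat u_p)/\mathrm{var}(\hat u_p)$, and consistency
  $\mathrm{cor}(\hat u_w,\hat u_p)$, with $n-1$ (co)variances throughout
  and $\bar F$ the mean pedigree inbreeding of the validation animals.

The partial data sets remove **all phenotypes** of animals hatched in or
after the validation year; genotypes are retained, so validation animals
are genotyped but unphenotyped — the standard forward-prediction setting.

A practical note from the simulation studies in this package: the
adjusted-phenotype accuracy depends on a phenotypic benchmark whose
replicate-to-replicate noise at desk scale (a few hundred validation
animals) is several times the typical genomic gain, so *directions* of
model comparisons are read from the LR statistics, which compare the
evaluations directly and are far more stable. Both sets of statistics are
always computed and reported.

## Weighted ssGBLUP and GWAS

GEBVs of genotyped animals are backsolved one trait at a time into SNP
effects, $\hat{\mathbf a} = \lambda \mathbf{D}\mathbf{Z}'\mathbf{G}^{-1}
\hat{\mathbf u}_g$. The constant $\lambda$ is defined as
$1/(2\sum_i d_i p_i (1-p_i))$ — the SNP-to-genomic variance ratio implied
by the $\mathbf{G}$ construction — which makes the backsolve the exact
inverse map of $\mathbf{G}$: with `tau = 0`,
$\mathbf{Z}\hat{\mathbf a} = \hat{\mathbf u}_g$ to machine precision
(asserted in the tests).

Per-SNP sampling variances use
$\mathrm{var}(\hat{\mathbf a}) = \lambda^2 \mathbf{D}\mathbf{Z}'
\mathbf{G}^{-1}\,\mathrm{cov}(\hat{\mathbf u}_g)\,\mathbf{G}^{-1}\mathbf{Z}
\mathbf{D}$ with $\mathrm{cov}(\hat{\mathbf u}_g) = \sigma^2_u\mathbf{G} -
\mathbf{C}^{uu}$, the genotyped block of the inverse coefficient matrix
taken exactly from the stored sparse factor. P-values are two-sided normal,
$2(1-\Phi(|\hat a_i/\mathrm{SD}(\hat a_i)|))$, displayed against the
Bonferroni line $-\log_{10}(0.05/m)$ (5.8 for a 34,251-SNP panel).

Window variances use sliding windows of 20 adjacent SNPs within a
chromosome (step 1): the variance across genotyped animals of
$\sum_{i \in \text{window}} z_i \hat a_i$ as a percentage of the additive
variance. Sliding rather than disjoint windows were chosen because they are
the common practice for this statistic and make the reported maxima
insensitive to window phase.

Weighted ssGBLUP iterates nonlinear-A weights
$d_i = CT^{\min(|\hat a_i|/\mathrm{sd}(\hat{\mathbf a}),\,5) - 2}$
(the cap prevents numerically explosive weights for extreme standardised
effects). Iteration 1 is the unweighted run; each later iteration
backsolves effects, renormalises the weights to mean 1 (so the genomic
variance scale cannot drift across iterations), rebuilds $\mathbf{G}$ and
$\mathbf{H}^{-1}$, re-solves at fixed variance components, and records
validation statistics.

## The breeding-program simulator

`run_breeding_program` generates the study conditions:

* **Population design**: 3 generations x 60 single-pair full-sib families x
  15 offspring by default, from 120 founders; an upward-selected line (80%
  of families) and a downward/random line (20%), mirroring a divergent
  selection program. Selection acts on family-mean EBVs from an internal
  single-trait pedigree BLUP on the data accumulated so far; the downward
  line is selected once and mated at random afterwards.
* **Mate allocation** is a greedy constraint satisfier: candidate families
  are ranked, the selected fraction (default 0.5) contributes parents
  first, parents are interleaved across families, and each sire is paired
  with the best available dam whose expected progeny inbreeding
  $a(s,d)/2$ does not exceed the parental-generation mean plus 1%. Sires
  with no feasible dam are skipped; only if the family quota cannot be
  met at all is the constraint relaxed (with a warning) using
  minimum-kinship pairs. Realised mean inbreeding accumulation stays below
  1% per generation at the default scale.
* **Genome**: 29 chromosomes of 1 Morgan (the rainbow trout karyotype),
  300 markers and 10 QTL per chromosome by default — 8,700 markers and 290
  QTL. The marker density is the densest desk-scale emulation of a 57K
  array that stays within routine compute budgets; at much sparser panels
  the marker-based relationship matrix is measurably *noisier* than
  $\mathbf{A}_{22}$ at tracking realised relationships, which inverts the
  expected ranking of ssGBLUP and PBLUP and no longer emulates the
  57K-array setting. QTL are withheld from the genotyping panel, so
  markers tag QTL only through co-segregation. Founders are simulated in
  linkage equilibrium at frequencies uniform on (0.1, 0.9); gene drop uses
  Haldane recombination (Poisson crossovers, no interference).
* **Trait architecture**: bivariate normal QTL effects at the target
  genetic correlation (0.24), linearly rescaled so the realised founder
  breeding-value covariance equals the target additive covariance
  *exactly* (the published two-trait estimates: additive 1.99 / 17,648,
  family 0.24 / 5,679, residual 2.60 / 29,913). Exact rescaling removes
  the founder-sampling component of replicate noise and makes
  parameter-recovery checks sharp.
* **Phenotyping** mirrors the recording scheme: BW on all fish; FY on 5
  fish per family chosen by sorting the family by descending BW, excluding
  fish beyond 3 SD from the family mean, and taking every
  `floor(eligible/5)`-th fish; sampled fish are assigned to five harvest
  groups within family in descending-weight order. Fixed effects (year,
  year x group, line, age slopes) are drawn once per simulation with
  magnitudes typical of the traits (BW year SD 80 g, FY year-group SD
  0.5%, age slopes 3 g/day and 0.02 %/day); their exact values are
  immaterial because the evaluation model estimates them.
* The genotyped subset is the FY-sampled fish (5 per family) plus the
  selected parents, reproducing the "few fish per family, many families"
  stratification of the real program.

**What the simulator does not emulate**: ancestral linkage disequilibrium
(founders are in LE, so marker-QTL LD arises only within the pedigree),
genotyping error and missingness, mutation, sex-limited expression,
overlapping generations, and environmental trends. Passing tests therefore
demonstrate correctness of the machinery and directional behaviour under
pedigree-generated LD; absolute accuracy gains in real data, which also
draw on ancestral LD and far denser panels, are expected to be larger than
the simulated ones.

## Problem sizes and numerical choices

The packaged studies use: parameter recovery at the default scale (about
2,940 animals, 900 FY / 2,700 BW records) over 5 replicates; forward
validation at the same scale over 10 replicates; GWAS calibration on 2
generations x 20 families with 400-SNP panels over 20 replicates; weighted
ssGBLUP on 3 generations x 30 families. At these sizes a two-trait REML
fit takes tens of seconds and a single-step solve a few seconds.

Replicate noise at the default scale matches what the model's own standard
errors predict (per-replicate SD about 0.06-0.09 for the heritabilities and
about 0.18 for the genetic correlation), so means over 5 replicates carry
standard errors of roughly 0.03-0.04 and 0.08; recovery checks at tighter
tolerances than that are expected to fail occasionally by sampling alone.

For the GWAS null calibration the package uses breeding values drawn
multivariate-normally from the pedigree: phenotypes then carry the assumed
variance structure (so the test statistics are on their nominal scale) but
are independent of the marker genotypes given the pedigree, making every
marker effect truly null. A zero-variance null would instead over-shrink
the GEBVs and make the empirical type-I error artificially conservative;
a finite-QTL polygenic trait is not null at all — markers in strong
pedigree LD with a QTL carry real, occasionally Bonferroni-crossing,
signal.

## Known limitations

* The residual EM fallback is partial (see above); in practice the active
  set makes it nearly unreachable.
* LR-method accuracy uses the base additive variance and mean validation
  inbreeding (the standard approximation); under strong selection this
  approximation under-corrects, which shows up as LR accuracies that can
  exceed adjusted-phenotype accuracies.
* `build_A` is dense ($O(n^2)$ memory): intended for pedigrees up to a few
  tens of thousands of animals, which covers the target population size.
* The simulator's internal selection EBV uses the generating variance
  components rather than re-estimating them each generation; this
  idealisation only affects selection intensity, not the validity of the
  downstream analyses.
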