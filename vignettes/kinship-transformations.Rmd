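---
title: "Relationship-matrix transformations, REML, and the distribution of breeding values"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relationship-matrix transformations, REML, and the distribution of breeding values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinvar)
```

## The model

Everything in this package revolves around the single-trait animal
model

$$y = \mathbf{1}\mu + \mathbf{Z}u + e, \qquad
u \sim (0, \mathbf{K}\sigma^2_g), \qquad e \sim (0, \mathbf{I}\sigma^2_e),$$

with the overall mean as the only fixed effect. $\mathbf{K}$ is a
relationship matrix: the pedigree numerator matrix $\mathbf{A}$, the
VanRaden method-1 genomic matrix $\mathbf{G}$, or the single-step
hybrid $\mathbf{H}$, of which only $\mathbf{H}^{-1}$ is ever built
(`makeHinv()`: $\mathbf{A}^{-1}$ plus
$\mathbf{G}^{-1}_{blend} - \mathbf{A}_{22}^{-1}$ on the genotyped
block, with no additional tau/omega weighting). Breeding values come
from the mixed model equations with
$\lambda = \sigma^2_e/\sigma^2_g$; individuals without phenotypes
stay in the equations and receive EBVs through $\mathbf{K}^{-1}$.

The object of study is the transformation

$$\mathbf{K}^* = w\,\mathbf{K} + \alpha\,\mathbf{11}' + \beta\,\mathbf{I},$$

applied either to $\mathbf{K}$ or to $\mathbf{K}^{-1}$. Its exact
algebraic consequences anchor most of the test suite:

* $D = \mu(\mathrm{diag}) - \mu(\mathrm{offdiag})$ maps to
  $wD + \beta$; $\alpha$ cancels from $D$ entirely.
* In the SQS decomposition $\mathbf{K} = \mathbf{SQS}$
  (`sqs_decompose()`), $\alpha + \beta$ shifts $\mathbf{S}^2$ while
  $\alpha > 0$ or $\beta < 0$ push the correlations in $\mathbf{Q}$
  toward $\pm 1$ and the matrix toward singularity.
* REML on $w\mathbf{K}$ estimates $\sigma^2_g/w$, leaving
  $\hat\sigma^2_e$ unchanged, so $h^2$ moves from $1/(1+\lambda_0)$
  to $w/(w+\lambda_0)$; on $w\mathbf{K}^{-1}$ it estimates
  $w\,\sigma^2_g$. The proof is one line in the profile criterion
  (below): replacing $\mathbf{K}^{-1}\lambda$ by
  $(w\mathbf{K}^{-1})(\lambda/w)$ leaves the equations unchanged.
  Consequently a reweighted $\mathbf{K}^{-1}$ used together with its
  own variance components reproduces the baseline EBVs element by
  element — the invariance the acceptance tests verify to 1e-8.

## Parameters that matter

* **Grid** (`default_grid()`): $w \in \{0.9, 1, 1.1\}$,
  $\alpha, \beta \in \{-0.05, 0, 0.05\}$. For $\mathbf{A}$-type
  matrices two regions are marked excluded rather than run:
  $\alpha = -0.05$ (would create negative off-diagonals in a matrix
  whose minimum off-diagonal is 0) and $\alpha = 0, \beta = -0.05$
  (diagonals would drop below 1). These exclusions reflect the
  1-tailed nature of $\mathbf{A}$; 2-tailed matrices run the full
  factorial.
* **Concentration band**: fraction of off-diagonal elements of
  $\mathbf{K}^{-1}$ inside $(-0.02, 0.02)$, the open interval.
  High concentration around 0 — not the range of the elements — is
  what depresses the $h^2$ estimate, which the row-discarding
  experiment (`discard_extreme()`) probes.
* **MAF threshold** (`maf_filter()`): markers with
  $\min(p, 1-p) < 0.02$ are dropped before building $\mathbf{G}$.
* **Blend weight** (`blendGA()`): $0.95\,\mathbf{G} +
  0.05\,\mathbf{A}_{22}$, the conventional ridge that guarantees an
  invertible genomic block.
* **Allele frequencies** default to the observed frequencies of the
  input genotypes; a fixed override exists
  (`geno_matrix(allele_freqs=)`) because $\mathbf{G}$ only estimates
  pedigree expectations when referenced to base-population
  frequencies — the package's own test of the
  $\mathbf{G} \approx \mathbf{A}$ property uses founder frequencies
  for exactly this reason.
* **Genotype codings**: 0/1/2 dosages map to $-1/0/1$; 0/1 calls on
  fully inbred lines map to $-1/+1$.

## REML: numerical choices

`reml_estimate()` profiles the REML criterion down to the single
ratio $\lambda$:

$$f(\lambda) = (N-p)\log\hat\sigma^2_e(\lambda) - q\log\lambda +
\log|M(\lambda)| + c,$$

with $M(\lambda)$ the MME coefficient matrix. Two routes minimize it:

* **`method = "eigen"`** (default when possible): the likelihood
  depends on the data only through the phenotyped block
  $\mathbf{K}_{obs}$, so one symmetric eigendecomposition makes every
  $\lambda$ evaluation $O(n)$. Brent search over
  $\lambda \in [10^{-8}, 10^8]$ (on the log scale) is followed by
  Newton steps on the analytic profile gradient, which lands within
  machine precision of the stationary point — this is what makes the
  exact-identity tests at 1e-8 meaningful.
* **`method = "em"`**: expectation-maximization updates on the mixed
  model equations ($\hat\sigma^2_g \leftarrow (\hat u'K^{-1}\hat u +
  \mathrm{tr}(K^{-1}C^{uu})\sigma^2_e)/q$, residual update by
  $y'\hat e/(N-p)$), followed by the same Newton polish. This route
  needs only $\mathbf{K}^{-1}$ and is therefore the fallback for
  transformed inverses that are not positive definite, where the
  eigen route's inversion is unavailable. Both routes reach the same
  stationary point; the suite checks agreement to 1e-14.

Defaults: `tol = 1e-8` (relative change in $\lambda$), `max_iter =
500`, initial split of the phenotypic variance at $h^2 = 0.5$. A
genetic variance collapsing below $10^{-8}$ of the phenotypic
variance is clamped to the boundary with a warning rather than
chased. Matrix inversion (`invert_relmat()`) attempts a Cholesky
factorization and raises a singularity error — reporting the smallest
eigenvalue — when the factorization fails or the pivot ratio falls
below $10^{-10}$; nothing is silently regularized. Pipeline grid
cells that fail this test are reported as rows with condition
diagnostics (`condition_report()`, which also reports the indirect
symptoms: negative or huge mean and huge spread of the inverse's
elements); only a singular baseline aborts a run.

Conventions fixed once and documented: off-diagonal statistics use
each unordered pair exactly once (upper triangle); standard
deviations are sample ($n-1$) standard deviations; the regression in
`ebv_compare()` is comparison-on-reference; `discard_extreme()`
applies both thresholds in a single pass over the original matrix,
not sequentially.

## What the simulator emulates

`simulate_population()` reproduces a discrete-generation breeding
scheme: 100 male and 100 female founders, ten non-overlapping
generations, a 1:1 mating ratio in which the top half of the females
ranked on own phenotype (founder dams at random — founders carry no
phenotypes, yet must reproduce) are mated to a random half of the
males with litter size 4 and equiprobable offspring sex. Phenotypes
are missing for all founders and for 25% of later males; 10% of sire
and 5% of dam pedigree entries are masked in the released pedigree.
5,000 unlinked biallelic markers are gene-dropped from founder
alleles (per-locus founder frequencies uniform on (0.05, 0.95)) and
retained for generations 8–10 only.

True breeding values follow the pedigree recursion
$u_i = (u_s + u_d)/2 + m_i$ with Mendelian-sampling variance
$\tfrac12(1 - (F_s + F_d)/2)\sigma^2_g$, i.e. the trait is
infinitesimal and *not* driven by the simulated markers. This keeps
$\mathbf{A}$, $\mathbf{G}$ and $\mathbf{H}$ mutually consistent in
expectation, which is the property the pipeline needs. True variance
components are inputs with defaults $h^2 = 0.30$ on a phenotypic
variance of 42 (mean 48) — a stand-in chosen to be consistent with
the heritability estimates the analysis itself produces on such data.
All randomness flows from a single seed; identical configuration and
seed reproduce the population bit for bit.

What it does **not** emulate: linkage and LD (markers are
independent), QTL architectures, selection on EBVs, overlapping
generations, genotyping errors, or non-random genotyping. Passing
tests on these data therefore demonstrate the *algebraic and
statistical* behaviour of the pipeline — matrix identities, REML
responses, EBV invariance — not robustness to the LD structure or
ascertainment of real genotype panels. Realized population sizes are
realization-dependent (the min of two binomial sex counts drives a
slow drift), so totals are treated as outcomes, not targets.

One empirical finding from the suite is worth flagging: whether
masking pedigree information raises or lowers the $h^2$ estimate
depends on the analysis. Under the single-step $\mathbf{H}$ analysis
of these simulated data, masking lowers the estimate (the genotyped
block anchors the genetic variance while the sparser
$\mathbf{A}^{-1}$ loses structure); under a pedigree-only analysis
with phenotypic selection of dams, the unaccounted selection can push
the estimate the other way. The acceptance test pins the direction
under the single-step analysis, which is the analysis these
simulation settings describe.

## Problem sizes used by the tests

The suite favours the smallest sizes at which each property is
informative: oracle equivalences on random pedigrees of up to 200
individuals (A-inverse) and 50 individuals (H-inverse); REML response
identities on a ~290-individual, 3-generation population; heritability
recovery over 20 replicates of the full 10-generation design without
markers; the masking comparison over 4 paired replicates of the full
design with markers; and the off-diagonal concentration of
$\mathbf{H}^{-1}$ on the full design. These choices are the
package's own trade-off between Monte-Carlo resolution and test
runtime.

## Known limitations

* Dense algebra throughout: intended for desk-scale problems (up to a
  few thousand individuals), not national evaluations; no sparse
  $\mathbf{A}^{-1}$ machinery.
* Single trait, single random effect, mean-only fixed effects; no
  reliabilities or prediction error variances.
* No unknown-parent groups or metafounders; unknown parents simply
  contribute founder Mendelian variance.
* No imputation: genotyped individuals must be fully genotyped.
* The transformation is a probe of matrix properties, not a tuning
  device for $\mathbf{G}$–$\mathbf{A}$ compatibility; no automatic
  calibration of $w$, $\alpha$, $\beta$ is provided or intended.
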