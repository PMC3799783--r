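---
title: "Asymmetric PCA for unbalanced two-class expression data: methods and conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Asymmetric PCA for unbalanced two-class expression data: methods and conventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apcadeg)
```

## The problem

Case–control expression studies are frequently unbalanced: a disease cohort
of ten arrays against twice as many controls is typical. Ordinary PCA of
such a matrix builds its scatter from the pooled samples, which weights each
class-conditional covariance by its sample count. The majority class
therefore dominates the leading components, and structure that only the
minority (disease) class carries is pushed into late, noisy components.

Asymmetric PCA (APCA) replaces the pooled scatter with an explicitly
weighted combination

$$C \;=\; a\,C_{Sn} \;+\; (1-a)\,C_{Sd} \;+\; b\,C_S,$$

where $C_{Sn}$ and $C_{Sd}$ are the class-conditional covariances of the
control and case samples, $C_S$ is the between-class scatter of the two
class means, $0 < a < 1$, and $b$ is large (20 by default). Choosing
$a < 1/2$ up-weights the minority class regardless of its sample count, and
the large $b$ forces the component hierarchy into a useful shape: the first
component absorbs the class-mean structure (on raw intensity data this is
essentially the shared baseline profile), and the second component becomes a
*discriminant axis* carrying the dominant difference between the two
within-class variations. Setting $a = n/l$ and $b = 1$ recovers ordinary
PCA exactly — an algebraic identity the test suite checks to $10^{-10}$ —
so ordinary PCA is available as the degenerate point of the same code path
(`pca_baseline()`).

## The four phases

1. **Gram projection** (`gram_project()`). With $m$ probes and $l \ll m$
   samples, the $l \times l$ Gram matrix $S = X^\top X$ is eigendecomposed
   instead of the $m \times m$ scatter; $X\,\mathrm{EIV}_S$ spans the same
   space as the nonzero eigenvectors of $X X^\top$ (the snapshot method).
   Columns whose Gram eigenvalue falls below `tol = 1e-10` relative to the
   largest are dropped; exact duplicate columns should be collapsed
   beforehand (`collapse_duplicates()`), the tolerance only guards numerical
   deficiency.
2. **Class statistics and weighting** (`class_stats()`,
   `weighted_covariance()`). Covariances use the plain divisors $n$, $d$,
   $l$ — not $n-1$ — matching the maximum-likelihood form of the scatter
   decomposition that makes the PCA identity exact.
3. **Eigendecomposition** (`decompose_covariance()`), with proportions
   eigenvalue/trace and the second component used as the discriminant by
   default (`k = 2`).
4. **Scoring and calling** (`gene_scores()`, `score_threshold()`,
   `call_degs()`). The discriminant eigenvector is back-projected to gene
   space; each probe's coefficient is its signed score $S$, and probes with
   $|S| > \theta = \lfloor |S_{\max}|/2 \rfloor$ are called differentially
   expressed. The comparison is strict, so boundary scores are excluded,
   and calling is monotone in $\theta$.

## The two basis conventions

The literal phase-one formula projects with the *unnormalised*
$\mathrm{EIV}_L = X\,\mathrm{EIV}_S$, whose column norms are
$\sqrt{\lambda_i}$. The package exposes both conventions:

* `basis = "orthonormal"` rescales the columns to unit length. This is the
  mathematically tidy choice: the basis is orthonormal, gene-space
  components have unit norm, the PCA-equivalence identity holds, and all
  scale/permutation invariances are exact.
* `basis = "raw"` keeps the literal product. The projection then amplifies
  each sample-space direction by its singular value, which has two
  consequences that matter in practice on raw intensity data: the
  shared-intensity axis dominates the weighted matrix (the first component
  typically accounts for ~99.5 % or more of the weighted variance, with
  the discriminant cleanly second), and the scores inherit the intensity
  scale, so the *integer* floor in $\theta$ is meaningful. Under the
  orthonormal convention scores are unit-norm, $|S_{\max}| < 1$, and the
  floor rule would always yield $\theta = 0$, i.e. no selection at all.

For these reasons the low-level `apca()` defaults to `"orthonormal"` (the
right default for algebraic work), while the pipeline front-end
`apca_run()` — whose purpose is threshold-based DEG calling — defaults to
`"raw"`. The run log records the mode used.

## Choosing a and b

The selection criterion is operationalised as *strict linear separability*
of the two classes in the plane of the first two factor loadings (the
Pearson correlations of each sample's expression vector with the two
gene-space components). `separable()` solves the planar hard-margin problem
exactly by scanning the finite candidate set of separating directions
(cross-class point differences and within-class edge normals) and reports a
scale-free margin: half the widest projected gap divided by the
root-mean-square spread of the points. `select_params()` runs the
decomposition over a grid (default $a \in \{0.05, \dots, 0.95\}$,
$b \in \{1, 2, 5, 10, 20, 30\}$), keeps the separable points, and picks the
largest margin, breaking ties toward smaller $b$ then smaller $a$. A preset
pair (the default $a = 0.3$, $b = 20$) bypasses the search. No
cross-validation is attempted: the criterion is in-sample by construction.

## Evaluation conventions

* **Networks.** Pairwise Pearson correlation of the called probes is
  computed *within the case group only* (co-regulation under disease), and
  edges use the inclusive rule $cc \ge \tau$ with $\tau = 0.9$. Connected
  components (via igraph) of size $\ge 3$ are reported as subnetworks, size
  2 as pairs, size 1 as singletons.
* **ROC/AUC.** Cases are positives. The AUC is the Mann–Whitney statistic
  $U/(n_\mathrm{pos} n_\mathrm{neg})$ with ties counted half; the two-sided
  p-value uses the normal approximation of the rank-sum test with tie
  correction and no continuity correction. p-values below $10^{-15}$ are
  printed as `<1e-15`, never as 0.
* **Combinations.** No canonical rule exists for combining the genes of a
  network component into one marker, so the package uses a deliberately
  parameter-free convention, recorded in every run log: each probe is
  z-scored across all samples, sign-aligned with its discriminant score
  (so up- and down-regulated members pull the same way), and the aligned
  z-scores are averaged. The rule is monotone, symmetric in the members,
  and uses only quantities the pipeline already has. Because the global
  sign of the discriminant axis is arbitrary (only *relative* score signs
  are meaningful), the pipeline orients each combination towards the case
  class once per run, by the sign of the correlation between the
  discriminant's factor loadings and the case indicator; without this a
  perfect signature could report AUC 0 instead of 1 depending on an
  arbitrary eigenvector sign. Single-gene AUCs are reported unoriented.

## The synthetic generator

`simulate_expression()` emulates the unbalanced single-channel design the
method targets, with defaults frozen as the package's study conditions:
2000 probes, 19 controls vs 10 cases, baseline intensities
$\mathcal N(500, 300^2)$ floored at 20, i.i.d. measurement noise with
$\sigma = 100$, and 30 planted differential probes at 3$\sigma$ effects with
alternating signs.

Two generator features deserve justification:

* **Per-array scale factors** (`array_cv = 0.12`). Unnormalised array
  exports differ in overall brightness from hybridisation to hybridisation;
  this multiplicative nuisance is what makes the shared-baseline axis the
  overwhelming first component of the raw-basis decomposition. The default
  is calibrated so that the first component accounts for roughly 99.5–99.9 %
  of the weighted variance, the regime the method is designed for. Without
  it the class-mean direction itself becomes the first component and the
  `k = 2` discriminant convention would be wrong for the simulated data.
* **A majority-class nuisance factor** (`control_factor_load`, off by
  default). The scenario in which asymmetric weighting demonstrably beats
  ordinary PCA is when the *majority* class carries structured variation
  that competes for the second component. With a control-only latent factor
  (50 probes at loading 2$\sigma$) and case-only differential structure
  (`de_mode = "factor"`, a case-only latent factor over the planted
  probes), PCA's second component locks onto the majority-class factor
  while the asymmetric weighting (which down-weights it by $a = 0.3$)
  stays on the disease signal; the mean rank-recall gain is about +0.3
  over replicate simulations. With no competing structure, ordinary PCA
  recovers planted mean-shifts just as well — asymmetry is not a free
  lunch, and the package makes the comparison honestly.

What the generator does *not* emulate: probe-level hybridisation physics,
MAS5/RMA summarisation artefacts, heavy-tailed or intensity-dependent
noise, batch structure beyond the single scale factor, and annotation
ambiguity. Passing tests on this generator therefore show that the
algorithmic contract holds (recovery of planted structure under the stated
noise model), not that any particular biological dataset will behave as
cleanly.

## Numerical choices and degenerate inputs

* Duplicate samples are detected by *exact* equality — a tolerance would
  silently merge near-replicates; the representative is the first column in
  file order, and a duplicate group spanning both classes is an error.
* Eigenvector signs are fixed by orienting each gene-space component so its
  maximum-absolute coefficient is positive.
* Tiny negative eigenvalues of the (mathematically PSD) weighted matrix are
  clamped to zero before proportions are formed.
* Zero-variance sample columns make factor loadings undefined and are
  reported as errors naming the sample; zero-variance probes are excluded
  from correlation networks and combinations with a warning.
* All-zero score tables yield $\theta = 0$ with a warning; an all-zero
  expression matrix fails in `gram_project()`.
* Gene-level aggregation keys on the verbatim composite symbol string
  (`"HBA1 /// HBA2"` is one gene); unannotated probes count as their own
  gene.

## Problem sizes used by the tests

The suite exercises the algebraic identities on random matrices up to
$50 \times 10$ (tolerances $10^{-8}$/$10^{-10}$ as stated above), the
planted-recovery property at the full study design
($2000 \times 29$, 20 replicate seeds; median recall of the planted probes
among the called set is required to reach 0.9), and the PCA comparison on
10 replicate seeds of the nuisance-factor scenario. End-to-end byte-level
determinism is asserted by running the pipeline twice on the same seed.

## Known limitations

* Exactly two classes; no missing-value handling beyond reject-or-drop at
  load time; no sparse or streaming path.
* The floor-based threshold is not covariant under rescaling of the input:
  multiplying the matrix by $c$ multiplies scores by $c^2$ (raw basis) but
  $\theta$ by roughly the same factor only up to the floor. The rule is kept
  as stated; users who rescale inputs should expect slightly different call
  sets near the boundary.
* The separability criterion is in-sample and necessarily optimistic; it
  selects weights, it does not validate a classifier.
* Scores from the raw basis depend on the value scale of the input export
  (linear vs. log intensities), so absolute score values are comparable
  only within one dataset and convention.
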