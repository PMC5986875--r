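---
title: "Estimating founder genome proportions by constrained genomic regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating founder genome proportions by constrained genomic regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgreg)
```

## The model

An admixed individual's genome is a mosaic of chromosome segments inherited
from several founder populations. At a bi-allelic marker $i$ with counted
allele frequency $p_{i,k}$ in founder population $k$, an individual whose
genome derives a fraction $b_k$ from population $k$ carries the counted
allele with expected dosage

$$\mathrm{E}(y_i) = \sum_{k=1}^{N} 2\,p_{i,k}\, b_k,$$

assuming Hardy–Weinberg equilibrium within each founder population. Stacking
all $M$ markers gives an ordinary linear regression $y = Xb + e$, where
column $k$ of the $M \times N$ design matrix $X$ is the expected allele
content $2p_{\cdot,k}$ and the residuals have mean zero. The coefficients
are only interpretable as genome proportions if they are constrained to the
simplex, so the package solves

$$\hat b = \arg\min_b\; (y - Xb)'(y - Xb)
\quad \text{s.t.} \quad b_k \ge 0,\;\; \textstyle\sum_k b_k = 1,$$

or, in the relaxed "le" mode, $\sum_k b_k \le 1$. The relaxation matters
when the design may be incomplete: if a contributing population is missing
from $X$, forcing the coefficients to sum to one pushes its genome share
onto the remaining columns, whereas the inequality leaves room for
unexplained ancestry. Because founder frequencies are treated as known
constants (estimated once from labelled reference individuals), the
parameter space is $N$ per individual — independent of marker count — which
is what makes the method fast at dense marker panels, and no distributional
assumption is placed on the markers beyond the Hardy–Weinberg expectation
used to form $X$. Linkage disequilibrium between markers is tolerated (it
reduces efficiency, not unbiasedness); modelling it would require a
generalised least-squares extension with a non-diagonal residual
covariance, which is out of scope here.

## The solver

The objective is a convex quadratic and the constraints are linear, so the
global minimiser is characterised by the KKT conditions and can be found
exactly by active-set iteration on the normal equations ($Q = X'X$,
$c = X'y$):

* equality mode uses a primal active-set method started at the barycentre,
  solving the bordered system for the free coordinates and the sum
  multiplier at each step;
* inequality mode first solves the non-negativity-only problem with
  Lawson–Hanson NNLS; if that optimum's coordinate sum exceeds one the
  optimum of the restricted problem lies on the sum-to-one face, and the
  equality solver supplies it.

Numerical choices: KKT/dual tolerances are at machine-precision scale
(1e-9 relative); coefficients within 1e-8 of zero are clipped to exactly
zero on output and equality-mode vectors renormalised to sum exactly one;
constraint satisfaction is guaranteed to 1e-6. If the design has linearly
dependent columns the optimum is still attained (singular KKT systems fall
back to a pseudo-inverse solve) but individual coefficients are no longer
identifiable; such fits carry `status = "degenerate"`. An unconstrained
`"ols"` mode is available purely as a diagnostic — its coefficients can be
negative and are not proportions.

`grid_oracle()` provides an independent check: it exhaustively searches the
feasible set on a regular grid (ties broken lexicographically) and is used
in the tests to confirm that the solver's objective is never beaten by any
grid point. In inequality mode the last coordinate is minimised analytically
over its grid range — the objective restricted to one coordinate is a
scalar quadratic, so evaluating the floor and ceiling of the continuous
minimiser is an exact search of the same grid. The tests also cross-check
the solver against an independently implemented quadratic-programming
routine (`pracma::quadprog`).

## The admixture simulator

The synthetic-data generator emulates the process that produces genuinely
admixed genotypes, with exact ancestry bookkeeping:

* **Founders** (`make_synthetic_founders()`): ancestral frequencies uniform
  on [0.05, 0.95]; population frequencies Balding–Nichols
  (Beta with concentration $(1-F_{ST})/F_{ST}$) around the ancestral value;
  genotypes binomial with two trials under Hardy–Weinberg. An optional
  *planted relative* re-draws the last population's frequencies around an
  existing population's at a small differentiation, producing the highly
  correlated frequency columns that real breed panels show between related
  breeds.
* **Phasing** (`random_phase()`): heterozygotes are assigned to the two
  haplotypes by independent fair coin flips per marker; founders' origin
  labels are their own population. Missing founder genotypes are imputed by
  a Hardy–Weinberg draw from their population's frequency before phasing.
* **Gametes** (`make_gamete()`): exactly `n_crossovers` breakpoints drawn
  uniformly without replacement from the $M-1$ inter-marker intervals of a
  single concatenated marker sequence; the copied haplotype alternates at
  each breakpoint, and origin labels travel with the alleles. The crossover
  count is fixed (not Poisson) and genome-wide (no chromosome structure or
  genetic map); both are deliberate simplifications.
* **Breeding** (`breed()`): each generation draws sire/dam pairs with
  replacement from the previous generation's offspring (founders in
  generation one), with uniformly random sexes; one offspring per pair.
  All generations' offspring form the admixed set. The cattle-style preset
  is five rounds of equal pair counts; the human-style preset uses
  per-generation offspring counts (100, 150, 200, 250, 300), totalling
  1,000 with the per-parent progeny expectation rising from about one to
  two across generations.

True proportions are computed by counting origin labels over both
haplotypes, so they are exact rationals with denominator $2M$ — category
boundaries like "exactly 0" and "exactly 1" are therefore safe without an
epsilon.

What the simulator does *not* emulate: mutation, selection, genetic maps
and chromosome-level recombination heterogeneity, genotyping error, and
overlapping generations. Selfing is possible under with-replacement parent
sampling. Passing the evaluation suite on these data therefore demonstrates
correctness of the estimator under its own model assumptions; accuracy on
real panels additionally depends on how well reference samples represent
the true founders.

## Evaluation metrics

`compute_metrics()` scores estimates against truth over all
individual-by-population cells: maximum absolute error, signed bias
(true minus estimated), mean squared error, mean absolute error, and the
Pearson correlation of the flattened cell vectors centred at their single
grand means (not per-population means — that choice changes the value and
is made deliberately). Zero-variance degenerate inputs yield a missing
correlation with a warning rather than an error. Under-specified trials
score only the retained populations' cells; category breakdowns use six
bins of the omitted population's true share (exactly 0, four
upper-inclusive quarter bins, exactly 1).

## Trial designs and default study conditions

The package reproduces three experiment designs end to end:

* **Fully specified** (`run_full_trial()`): all founder columns present;
  run under both constraint modes plus the correlation between their error
  vectors.
* **Type-1, under-specified** (`run_type1_trial()`): one truly contributing
  population removed from the design, estimation under the `le` constraint;
  per-category metrics and an absorption table showing which remaining
  population soaked up the omitted genome (in practice, the closest
  relative by frequency correlation).
* **Type-2, miss-specified** (`run_type2_trial()`): a two-column design —
  the precisely known focal population plus the mean allele content of 500
  background genotypes sampled without replacement (seeded) from all
  non-focal reference genotypes; only individuals truly carrying focal
  genome are scored, on the focal column only.

The end-to-end evaluation (tests and `scripts/acceptance.R`) uses a
simulated cohort chosen to be large enough for stable statistics while
keeping a full run in tens of seconds on one CPU: 8 founder populations at
differentiation 0.1 (the eighth a planted relative of the seventh at
differentiation 0.05, frequency correlation about 0.95), 4,000 markers, 100
reference individuals per population, and cattle-style breeding of 200
pairs over 5 rounds (1,000 admixed individuals) at 25 crossovers per
gamete. Under these conditions the equality-mode fit reaches a
truth–estimate correlation near 0.97 with mean squared error near 0.001 and
essentially zero bias, the type-1 zero-category error is indistinguishable
from the full model's, the omitted population's genome is absorbed
predominantly by its planted relative, and the type-2 focal correlation
exceeds 0.9 — run `scripts/acceptance.R` to recompute all of these.

## Known limitations

* Coefficients are point estimates; no standard errors or intervals are
  provided.
* Correlated founder columns (close relatives) make individual coefficients
  of the pair poorly identified even though the fit, and the pair's summed
  share, remain stable.
* Strand-ambiguous markers (A/T, C/G) cannot be detected from allele labels
  alone; `align_markers()` harmonises by label and drops irreconcilable
  markers, reporting how many.
* Missing genotypes are handled by pairwise deletion at estimation time and
  by model-based imputation only inside the simulator's phasing step.
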