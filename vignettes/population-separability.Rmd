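---
title: "Methods: supervised and unsupervised population separability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: supervised and unsupervised population separability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`popsep` answers one question in two ways: given two labelled candidate
populations of biallelic SNP genotypes, how confidently can they be told
apart, window by window along the SNP axis?  The unsupervised arm ignores
the labels until the very last step; the supervised arm uses them from the
start.  Comparing the two quantifies how much the labels are worth, which
matters most near the detection limit of PCA.

## Data model and conventions

Genotypes are dosage counts in {0, 1, 2} of the coded allele, with `NA` for
missing calls.  The coded allele is the minor allele, and when reading PLINK
PED/MAP text it is recomputed from the file's own frequencies (ties broken
by lexicographic order of the allele symbol), so data read from files and
data from the simulator share one convention.  SNP windows are 0-based and
half-open, `[start, start + length)`; consecutive equal-length windows tile
the axis exactly once, and a trailing partial window is dropped so every
window carries the same amount of data.  Classifiers and PCA only ever see
complete real-valued matrices: missing calls are mean-imputed per SNP, which
leaves observed entries and per-SNP means unchanged.

The package assumes markers are (approximately) LD-independent, as they
would be after standard LD pruning; nothing in the methods models linkage.

## The unsupervised arm

Per window the genotype matrix is normalized per SNP: centred by `2 * p_hat`
and scaled by `sqrt(p_hat * (1 - p_hat))`, with the shrunk frequency
estimate `p_hat = (1 + sum of dosages) / (2 + 2 * n_called)`.  The shrinkage
keeps the scale factor away from zero at extreme frequencies; the plain
maximum-likelihood frequency is available (`shrink = FALSE`) for comparison.
Missing entries become 0 after centring (the column mean).  SNPs fixed at
the allele level (all dosages 0 or all 2) carry no information and are
dropped with a notice; an all-heterozygous column is kept — under the shrunk
estimate it centres to zeros.  A window in which every SNP is fixed yields a
flagged degenerate record in scans rather than an error.

PCA eigen-decomposes the M-by-M sample covariance of the normalized rows
(via the SVD of the matrix, which is both faster and more accurate than
forming the covariance).  Three summaries follow:

* **F̂_ST (ratio of sums).** Per SNP, with sample allele frequencies
  `p1, p2` over `n1, n2` non-missing allele copies, numerator
  `(p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and denominator
  `p1(1-p2) + p2(1-p1)`; the estimate is the summed numerator over the
  summed denominator.  Summing before dividing stabilises the estimator for
  small per-SNP denominators; the price is a finite-sample bias, and the
  estimate can legitimately be negative under weak divergence.  SNPs with a
  zero denominator or fewer than two non-missing calls in either class are
  excluded and reported in `n_snps_used`.  The standard error is a
  delete-one-SNP jackknife of the ratio — the natural resampling unit given
  LD-independent markers.
* **The BBP critical threshold** `fst_critical(N, M) = 1/sqrt(N*M)`: the
  spiked-eigenvalue phase transition for two equal-sized populations.  Below
  it the leading sample eigenvector is asymptotically uninformative about
  the split; above it, structure snaps into the top axis and significance
  measures collapse by many orders of magnitude.  The scan reports each
  window's F̂_ST against its own critical value — that comparison, not a
  p-value cut-off, is the operational detection rule for the unsupervised
  arm.
* **The structure test** sums the two-group one-way ANOVA F statistics along
  each of the top `k_axes` principal axes and refers the sum to a
  chi-squared distribution with `k_axes` degrees of freedom.  `k_axes`
  defaults to 10, the conventional number of axes retained by genotype-PCA
  software; it is capped by the window's rank.

A caveat worth stating plainly: the ANOVA step uses the labels, so the
structure test is not a purely unsupervised channel.  Any true divergence F
contributes noncentrality of roughly `2*F*M*k` to the summed statistic
(each axis captures about a `1/N` share of the squared standardized mean
difference `8*F*N`, and the F statistic scales it by `M/4`).  At
`F = c * fst_critical(N, M)` this is `2*c*k*sqrt(M/N)`: negligible when N
is in the thousands and M a few hundred, but not at N comparable to M.  In
compact simulations (say N = 500, M = 400) the test therefore rejects at
more than its nominal rate even below the BBP threshold — a property of the
statistic at that scale, reproduced by `scripts/acceptance.R`, not a
miscalibration of the null: with truly exchangeable labels (F = 0) the
p-value is uniform, which the test suite checks by simulation.  The F̂_ST
versus F_crit comparison is immune to this leakage and is the comparison to
trust near the threshold.

## The supervised arm

Both classifiers consume the same leakage-free features: within each window,
imputation means and normalization statistics are computed on the training
samples only and applied unchanged to the hold-out samples, so the hold-out
set cannot influence training even indirectly.  One stratified
train/hold-out split (default 4:1, rounding toward training) is shared by
every window and both methods, making accuracy spectra comparable across
windows and methods.

**Feed-forward network.**  Three layers; hidden activations
`tanh` (bounded, smooth, monotonic), output activations the identity of the
affine combination, normalised to class probabilities by softmax.  Training
minimises mean cross-entropy plus a small L2 penalty on the weights
(`l2 = 1e-4` by default) by full-batch gradient descent with a backtracking
Armijo line search (sufficient-decrease constant `1e-4`, step halved up to
40 times, doubled after success, capped at `1e3`).  The penalty keeps the
optimum finite on separable data, where bare cross-entropy would push the
weights to infinity; at `1e-4` it is far too weak to act as meaningful
regularisation, and with the iteration cap (default 500) training behaves
like early-stopped descent.  Initial weights and biases are drawn from
`Normal(0, init_scale/sqrt(fan_in))`, so a seed fixes the trained network
bit-for-bit.  Convergence is declared at a relative loss change below `tol`
(default `1e-8`) or when no Armijo step succeeds.

Because the loss surface is non-convex for `hidden > 0`, a single trained
network is an arbitrary local optimum.  The package therefore always works
with **ensembles**: `reps` independent trainings (default 10) from distinct
seeded restarts, each evaluated on the same hold-out set.  The across-
ensemble standard deviation of hold-out accuracy is the confidence band
reported everywhere, and per-sample class probabilities are ensemble means.
This band measures restart-to-restart stability only; it deliberately
excludes split-to-split and dataset-to-dataset variability (for those, see
the replicate designs below).  With `hidden = 0` the model is multinomial
logistic regression — convex, so all restarts reach the same optimum and
the band collapses; comparing `hidden = 8` against `hidden = 0` against the
SVM is the package's test of whether a detected signal is linear.

The default of 8 hidden nodes is deliberately modest: on LD-pruned SNP
windows the between-population signal is additive to good approximation, so
hidden capacity beyond a handful of nodes buys nothing (the linearity
comparison makes this measurable), while training cost grows linearly in H.

**Linear soft-margin SVM.**  `min 0.5*||w||^2 + C * sum(hinge)` with the
bias handled by feature augmentation (a constant coordinate, penalised with
the weights) and the dual solved by coordinate descent in a fixed sample
order — fully deterministic, so it provides a single reproducible accuracy
per window with no band.  Convergence is declared when the spread of
projected gradients over a sweep falls below `tol` (default `1e-8`);
exceeding `max_sweeps` raises an error reporting the duality gap rather
than returning a silently unconverged model.  The cost defaults to `C = 1`
on normalized features; decision ties on the hyperplane go to class 1 by
convention.  The margin width `2/||w||` is reported for diagnostic use.

**Evaluation.**  Accuracy is percent correct on the hold-out set (50 =
chance on balanced classes).  ROC curves sweep the decision threshold over
the sorted unique scores, tied scores sharing one step; AUC is the
trapezoid area, identical to the Mann–Whitney U statistic scaled by
`n1*n0`.  The `null_split_test` report applies both arms to an arbitrary
random split of a single population and flags windows exceeding `50 + 3
sigma` accuracy or a Bonferroni-corrected structure-test level (default
family-wise 0.01 across windows — a QC convenience, configurable, not a
claim about the right threshold).

## The simulator

`simulate_pair` implements the Balding–Nichols model: per SNP an ancestral
frequency uniform on [0.05, 0.95], subpopulation frequencies independently
Beta-distributed with mean p and variance `F*p*(1-p)`, genotypes
Binomial(2, p) per individual.  The expected divergence between the two
populations matches the F parameter, which the estimator-recovery checks
exploit.  Design points:

* `F = 0` short-circuits to identical frequencies — the null is exact, not
  a Beta limit.
* SNPs whose realised pooled minor-allele frequency falls below `maf_floor`
  (default 0.01) are redrawn individually, mirroring the MAF pruning every
  real panel has undergone, without discarding whole matrices.
* Dosages are recoded to pooled-minor-allele coding after generation; the
  F_ST estimator and both classifiers are invariant under the recoding, and
  it keeps simulated data consistent with the PED-reading convention.
* `simulate_blocks` concatenates independent per-block draws over the same
  individuals, giving chromosomes in which divergence varies along the axis
  (one differentiated block in a null background is the canonical test
  case for window scans).
* `split_null` labels two uniformly random disjoint subsets of one
  population — the homogeneity null for the whole pipeline.

What the simulator does **not** emulate: linkage disequilibrium, admixture
or family structure, genotyping error, platform/batch effects, and missing
data (missingness handling is tested on synthetically masked entries
instead).  Passing the package's checks on this generator therefore shows
the estimators and classifiers behave correctly for idealised unlinked
markers; it does not certify behaviour under batch artefacts or residual
LD, which real cohort comparisons must still confront.

## Validation designs and problem sizes

The acceptance experiments (in `tests/testthat/test-acceptance.R`, recomputed
by `scripts/acceptance.R`) use two populations of 200 individuals and
500-SNP panels — sizes at which every experiment runs in minutes on one
core — with 5000-SNP panels for estimator recovery and 20 independent seeds
wherever a rate or a mean over realisations is asserted:

* estimator recovery at F = 0.01 (5000 SNPs) and the null bias at F = 0;
* the phase transition at `5 * F_crit` (p < 1e-6 in essentially every
  realisation) against the sub-threshold regime at `F_crit / 5`;
* supervised classification at `F = F_crit / 2`, where mean ANN and SVM
  hold-out accuracy sits several standard errors above 50 while F̂_ST stays
  below F_crit;
* null-split calibration of window accuracies and AUC on a homogeneous
  population.

Two comparisons are measured over replicate datasets rather than a single
simulation, because the quantity of interest is an expected behaviour and
its single-dataset estimate is dominated by hold-out sampling noise
(roughly 4–5 accuracy points for 80 hold-out samples): the linearity
equivalence of ANN(8), ANN(0) and the SVM (10 replicates; the pooled sigma
is the RMS of the three methods' across-replicate standard deviations) and
the window-size convergence experiment (8 replicates of a 20-SNP block at
F = 0.05 inside 80 null SNPs, comparing the 100-SNP window's mean accuracy
with the informative 20-SNP window's mean against the latter's mean
ensemble sigma).

## Known limitations

* The structure test's sub-threshold leakage at small N/M ratios, discussed
  above: near the BBP threshold, compare F̂_ST with F_crit rather than
  reading the p-value as a calibrated error rate.
* The ensemble sigma understates total uncertainty whenever split or
  dataset variability matters; it is a stability measure, not a standard
  error of the accuracy.
* The network trainer is plain gradient descent; it makes no claim of
  finding global optima, and architecture selection is left to the user
  (the hold-out comparison across `hidden` values is the supported tool).
* Binary PLINK, VCF, multi-allelic sites, sex chromosomes and genetic-map
  distances are out of scope; inputs are text PED/MAP or dosage tables.
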