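# popsep

Are two candidate populations genetically distinguishable?  The question
arises whenever labelled groups of genotyped individuals are to be merged or
contrasted: cohorts collected at different sites, genotyped on different
platforms or in different laboratories, geographically separated samples, or
case/control strata in a genome-wide association study.  `popsep` quantifies
the separability of two labelled populations of biallelic SNP genotypes in
non-overlapping windows along the SNP axis, through two complementary arms:

* **Unsupervised arm** — per window, genotypes are normalized
  (centred by twice the shrunk allele-frequency estimate
  p̂ = (1 + Σdosage)/(2 + 2n), scaled by √(p̂(1−p̂))), decomposed by PCA, and
  summarised by

  * the Hudson/Reich **ratio-of-sums F_ST estimator**
    F̂ = Σ_s n_s / Σ_s d_s with
    n_s = (p̂₁−p̂₂)² − p̂₁(1−p̂₁)/(n₁−1) − p̂₂(1−p̂₂)/(n₂−1) and
    d_s = p̂₁(1−p̂₂) + p̂₂(1−p̂₁), with a delete-one-SNP jackknife standard
    error (the estimator is biased but consistent and may go negative in
    finite samples);
  * the **BBP critical threshold** F_crit = 1/√(N·M) for N SNPs and M
    individuals — the Baik–Ben Arous–Péché spiked-eigenvalue phase
    transition below which population structure is conjectured undetectable
    by PCA;
  * a **structure test** summing the one-way ANOVA F statistics for the
    group difference along each of the top-k principal axes, referred to a
    χ²_k upper tail.

* **Supervised arm** — per window, hold-out classification accuracy of

  * ensembles of **three-layer feed-forward networks**
    (h_j = tanh(Σ_i w_ij x_i + b_j); o_k = Σ_j w_jk h_j + b_k, softmax to
    class probabilities), trained by full-batch gradient descent from
    independent random restarts; the spread of hold-out accuracies across
    the ensemble is the confidence band, and `hidden = 0` degenerates to a
    purely linear classifier;
  * a deterministic **linear soft-margin SVM**
    (min ½‖w‖² + C·Σ hinge, solved by dual coordinate descent),

  plus ROC curves (trapezoid AUC) over the classifier score.

Because supervised methods use the class labels, they can separate
populations whose divergence lies *below* F_crit, where PCA sees nothing —
the package's simulations let you reproduce that contrast directly.

A **Balding–Nichols simulator** generates two-population genotype data with
controlled divergence F (subpopulation allele frequencies
Beta-distributed around an ancestral frequency with variance F·p(1−p)),
including block-structured chromosomes and homogeneous null populations.
PLINK text PED/MAP filesets and tab-separated dosage tables are read and
written natively.

## Worked example

```r
library(popsep)

## two populations, 200 individuals each, 500 unlinked SNPs,
## divergence F = 0.01 (above F_crit = 1/sqrt(500*400) ~ 0.0022)
sim <- simulate_pair(sim_spec(fst = 0.01, n_snps = 500,
                              n_per_pop = c(200, 200), seed = 1))

fst_hudson(sim$genotypes, sim$labels)
#> F_ST (ratio of sums): 0.0100537  (SE 0.000839, 500 SNPs, 200 + 200 individuals)

fst_critical(500, 400)
#> [1] 0.002236068

scan <- pca_window_scan(sim$genotypes, sim$labels, window_size = 100)
scan
#> pca_scan: 5 windows; 5 with F_ST above the BBP threshold
#>   start end  fst_hat   fst_se fst_crit global_stat dof   p_value degenerate
#> 1     0 100 0.010498 0.002006    0.005       241.0  10 4.173e-46      FALSE
#> 2   100 200 0.007273 0.001371    0.005       187.7  10 5.925e-35      FALSE
#> 3   200 300 0.009014 0.001786    0.005       216.2  10 6.589e-41      FALSE
#> 4   300 400 0.013452 0.002322    0.005       354.6  10 4.212e-70      FALSE
#> 5   400 500 0.010133 0.001743    0.005       249.0  10 8.673e-48      FALSE

ann <- classifier_window_scan(sim$genotypes, sim$labels, window_size = 100,
                              method = "ann",
                              config = ann_config(hidden = 8, reps = 10),
                              seed = 2)
ann
#> window_scan (ann): 5 windows, hold-out accuracy 71.9%..78.1%
#>   start end mean_acc  sigma
#> 1     0 100    71.88 0.6588
#> 2   100 200    72.50 2.8868
#> 3   200 300    77.00 2.2205
#> 4   300 400    74.62 2.7670
#> 5   400 500    78.12 1.2148
```

The estimated F̂_ST hovers around the simulated 0.01; every window sits
above its critical value 0.005 and the structure-test p-values collapse (the
phase transition has occurred).  The network ensembles classify held-out
individuals at ~72–78% against a 50% chance level, with ±1σ bands from the
10 random-restart repetitions.  On data
simulated *below* the threshold (`fst = fst_critical(500, 400) / 2`) the
estimated F̂_ST stays under F_crit in essentially every realisation, yet the
classifiers still score significantly above 50% — the supervised arm
operating past the unsupervised limit.

A command-line wrapper with `simulate`, `scan-pca`, `scan-ann`, `scan-svm`,
`null-test`, `roc` and `convergence` subcommands is installed at
`system.file("scripts", "popsep", package = "popsep")`; every run writes a
`manifest.json` (configuration, seed, version) from which its artifacts can
be regenerated.

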