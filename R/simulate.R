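#' Simulation specification for a two-population dataset
#'
#' Parameters of the Balding-Nichols generative model: subpopulation allele
#' frequencies are Beta-distributed around an ancestral frequency with
#' variance `fst * p * (1 - p)`, so the expected divergence between the two
#' populations is approximately `fst`.
#'
#' @param fst target divergence, in `[0, 1)`.  `fst = 0` is handled exactly
#'   (both populations share the ancestral frequency), giving a structurally
#'   deterministic null.
#' @param n_snps number of unlinked biallelic SNPs.
#' @param n_per_pop integer pair `(n1, n2)` of individuals per population.
#' @param ancestral_freq_range interval in (0,1) from which ancestral
#'   frequencies are drawn uniformly.
#' @param maf_floor SNPs whose realised pooled minor-allele frequency falls
#'   below this are redrawn (mirrors upstream MAF pruning of real panels).
#' @param seed optional integer seed; the same spec and seed reproduce the
#'   dataset exactly.
#' @return An object of class `sim_spec`.
#' @export
sim_spec <- function(fst, n_snps, n_per_pop = c(200L, 200L),
                     ancestral_freq_range = c(0.05, 0.95),
                     maf_floor = 0.01, seed = NULL) {
  stopifnot(length(fst) == 1L, fst >= 0, fst < 1,
            n_snps >= 1L, length(n_per_pop) == 2L, all(n_per_pop >= 2L),
            length(ancestral_freq_range) == 2L,
            ancestral_freq_range[1] > 0, ancestral_freq_range[2] < 1,
            ancestral_freq_range[1] < ancestral_freq_range[2],
            maf_floor >= 0, maf_floor < 0.5)
  structure(list(fst = fst, n_snps = as.integer(n_snps),
                 n_per_pop = as.integer(n_per_pop),
                 ancestral_freq_range = ancestral_freq_range,
                 maf_floor = maf_floor, seed = seed),
            class = "sim_spec")
}

#' Draw diverged subpopulation allele frequencies
#'
#' For `fst > 0`, each subpopulation frequency is an independent draw from
#' `Beta(p(1-F)/F, (1-p)(1-F)/F)`, which has mean `p` and variance
#' `F p (1-p)`.  For `fst = 0` both frequencies equal `p_anc` exactly.
#' Vectorised over `p_anc`.
#'
#' @param p_anc ancestral frequency (or vector), in (0,1).
#' @param fst divergence parameter in `[0, 1)`.
#' @return A list with numeric vectors `p1`, `p2` in (0,1).
#' @export
draw_population_freqs <- function(p_anc, fst) {
  if (any(p_anc <= 0) || any(p_anc >= 1)) stop("p_anc must lie in (0,1)")
  if (fst < 0 || fst >= 1) stop("fst must lie in [0,1)")
  if (fst == 0) return(list(p1 = p_anc, p2 = p_anc))
  a <- p_anc * (1 - fst) / fst
  b <- (1 - p_anc) * (1 - fst) / fst
  eps <- 1e-9
  p1 <- pmin(pmax(stats::rbeta(length(p_anc), a, b), eps), 1 - eps)
  p2 <- pmin(pmax(stats::rbeta(length(p_anc), a, b), eps), 1 - eps)
  list(p1 = p1, p2 = p2)
}

# dosages for one population: n individuals x length(p) SNPs
.draw_dosages <- function(n, p) {
  matrix(stats::rbinom(n * length(p), 2L, rep(p, each = n)), nrow = n)
}

#' Simulate a labelled two-population genotype dataset
#'
#' Per SNP: the ancestral frequency is uniform on the spec's range,
#' subpopulation frequencies come from [draw_population_freqs()], and each
#' individual's dosage is Binomial(2, p) in its population.  SNPs whose
#' realised pooled minor-allele frequency falls below `maf_floor` are redrawn.
#' Dosages are recoded so that the coded allele is the pooled minor allele
#' (the convention PED/MAP reading also uses); the F_ST estimator and the
#' classifiers are invariant under this recoding.
#'
#' @param spec a [sim_spec()].
#' @return A list with `genotypes` (a [genotype_matrix()], populations
#'   stacked, no missing data) and `labels` (a [label_set()], class 0 =
#'   population 1).
#' @export
simulate_pair <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n1 <- spec$n_per_pop[1]; n2 <- spec$n_per_pop[2]
  n_snps <- spec$n_snps
  lo <- spec$ancestral_freq_range[1]; hi <- spec$ancestral_freq_range[2]
  d1 <- matrix(0L, n1, n_snps); d2 <- matrix(0L, n2, n_snps)
  need <- seq_len(n_snps)
  for (iter in seq_len(100L)) {
    p_anc <- stats::runif(length(need), lo, hi)
    ps <- draw_population_freqs(p_anc, spec$fst)
    d1[, need] <- .draw_dosages(n1, ps$p1)
    d2[, need] <- .draw_dosages(n2, ps$p2)
    pooled <- (colSums(d1[, need, drop = FALSE]) +
               colSums(d2[, need, drop = FALSE])) / (2 * (n1 + n2))
    maf <- pmin(pooled, 1 - pooled)
    need <- need[maf < spec$maf_floor]
    if (!length(need)) break
  }
  if (length(need))
    stop("could not satisfy the MAF floor after 100 redraw rounds")
  dos <- rbind(d1, d2)
  # recode to pooled-minor-allele dosage; ties keep the original coding
  pooled <- colMeans(dos) / 2
  flip <- pooled > 0.5
  if (any(flip)) dos[, flip] <- 2L - dos[, flip]
  snps <- data.frame(
    snp_id = sprintf("snp%05d", seq_len(n_snps)), chromosome = "1",
    position = seq_len(n_snps),
    allele_a = ifelse(flip, "B", "A"), allele_b = ifelse(flip, "A", "B"),
    stringsAsFactors = FALSE
  )
  sample_ids <- c(sprintf("P1_%04d", seq_len(n1)), sprintf("P2_%04d", seq_len(n2)))
  gm <- genotype_matrix(dos, snps = snps, sample_ids = sample_ids)
  labels <- label_set(sample_ids, rep(c(0L, 1L), c(n1, n2)),
                      class_names = c("pop1", "pop2"))
  list(genotypes = gm, labels = labels)
}

#' Simulate a block-structured chromosome
#'
#' Concatenates per-block [simulate_pair()] draws over the same individuals,
#' so divergence can vary along the SNP axis (e.g. one differentiated block
#' embedded in a null background).  Population frequency draws are independent
#' per block; SNP positions run consecutively across blocks.
#'
#' @param block_sizes integer vector of SNPs per block.
#' @param block_fst numeric vector of per-block divergence values, parallel to
#'   `block_sizes`.
#' @param n_per_pop integer pair of individuals per population.
#' @param ancestral_freq_range,maf_floor as in [sim_spec()].
#' @param seed optional integer seed.
#' @return As [simulate_pair()]; an attribute `blocks` on the genotype matrix
#'   records the block boundaries.
#' @export
simulate_blocks <- function(block_sizes, block_fst, n_per_pop = c(200L, 200L),
                            ancestral_freq_range = c(0.05, 0.95),
                            maf_floor = 0.01, seed = NULL) {
  if (length(block_sizes) == 0L) stop("at least one block is required")
  block_sizes <- as.integer(block_sizes)
  if (length(block_sizes) != length(block_fst))
    stop("block_sizes and block_fst must have equal length")
  if (!is.null(seed)) set.seed(seed)
  parts <- vector("list", length(block_sizes))
  for (k in seq_along(block_sizes)) {
    spec <- sim_spec(block_fst[k], block_sizes[k], n_per_pop,
                     ancestral_freq_range, maf_floor, seed = NULL)
    parts[[k]] <- simulate_pair(spec)
  }
  dos <- do.call(cbind, lapply(parts, function(p) p$genotypes$dosages))
  n_total <- ncol(dos)
  snps <- do.call(rbind, lapply(parts, function(p) p$genotypes$snps))
  snps$snp_id <- sprintf("snp%05d", seq_len(n_total))
  snps$position <- seq_len(n_total)
  gm <- genotype_matrix(dos, snps = snps,
                        sample_ids = parts[[1]]$genotypes$sample_ids)
  attr(gm, "blocks") <- data.frame(
    start = cumsum(c(0L, utils::head(block_sizes, -1L))),
    length = as.integer(block_sizes), fst = block_fst
  )
  list(genotypes = gm, labels = parts[[1]]$labels)
}

#' Random null split of one population
#'
#' Labels two uniformly random disjoint subsets of the samples 0/1, leaving
#' the rest unlabelled: the intra-population homogeneity test of the scan
#' pipelines (any detected "structure" is then a false positive).
#'
#' @param gm a [genotype_matrix()].
#' @param n_a,n_b subset sizes; `n_a + n_b` must not exceed the sample count.
#' @param seed optional integer seed.
#' @return A [label_set()] covering `n_a + n_b` samples.
#' @export
split_null <- function(gm, n_a, n_b, seed = NULL) {
  m <- length(gm$sample_ids)
  if (n_a + n_b > m)
    stop(sprintf("n_a + n_b = %d exceeds sample count %d", n_a + n_b, m))
  if (!is.null(seed)) set.seed(seed)
  picked <- sample(gm$sample_ids, n_a + n_b)
  label_set(picked, rep(c(0L, 1L), c(n_a, n_b)),
            class_names = c("splitA", "splitB"))
}
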