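#' Genotype matrix container
#'
#' Bundles an individuals-by-SNPs dosage matrix with per-SNP metadata.  Dosages
#' count copies of the coded allele (`allele_a`, by convention the minor
#' allele) and take values 0, 1, 2 or `NA` for a missing call.  SNPs are kept
#' in map order, position-sorted within chromosome for data read from PED/MAP.
#'
#' @param dosages integer matrix, one row per sample, one column per SNP;
#'   entries in `{0, 1, 2, NA}`.  Row names are taken as sample ids when
#'   `sample_ids` is not given.
#' @param snps data frame of SNP records with columns `snp_id`, `chromosome`,
#'   `position`, `allele_a`, `allele_b`.  Defaults are synthesised (chromosome
#'   "1", consecutive positions, alleles A/B) when omitted.
#' @param sample_ids character vector of unique sample identifiers.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages`, `snps`, `sample_ids`.
#' @export
genotype_matrix <- function(dosages, snps = NULL, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "integer"
  m <- nrow(dosages)
  n <- ncol(dosages)
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- sprintf("S%04d", seq_len(m))
  }
  if (is.null(snps)) {
    ids <- colnames(dosages)
    if (is.null(ids)) ids <- sprintf("snp%05d", seq_len(n))
    snps <- data.frame(
      snp_id = ids, chromosome = "1", position = seq_len(n),
      allele_a = "A", allele_b = "B", stringsAsFactors = FALSE
    )
  }
  snps <- as.data.frame(snps, stringsAsFactors = FALSE)
  rownames(snps) <- NULL
  dimnames(dosages) <- list(sample_ids, snps$snp_id)
  gm <- structure(
    list(dosages = dosages, snps = snps, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
  validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  d <- gm$dosages
  if (nrow(d) != length(gm$sample_ids))
    stop("row count does not match number of sample ids")
  if (ncol(d) != nrow(gm$snps))
    stop("column count does not match number of SNP records")
  if (anyDuplicated(gm$sample_ids))
    stop("duplicate sample ids")
  if (anyDuplicated(gm$snps$snp_id))
    stop("duplicate SNP ids")
  if (any(!is.na(gm$snps$snp_id) & !nzchar(gm$snps$snp_id)))
    stop("empty SNP id")
  if (any(gm$snps$position <= 0))
    stop("SNP positions must be positive")
  bad <- d[!is.na(d)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  invisible(gm)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' @export
print.genotype_matrix <- function(x, ...) {
  d <- x$dosages
  miss <- sum(is.na(d))
  cat(sprintf(
    "genotype_matrix: %d samples x %d SNPs (%d missing calls, %.2f%%)\n",
    nrow(d), ncol(d), miss, 100 * miss / max(1, length(d))
  ))
  chr <- unique(x$snps$chromosome)
  cat(sprintf("  chromosomes: %s\n", paste(utils::head(chr, 5), collapse = ", ")))
  invisible(x)
}

#' Two-class sample labels
#'
#' Maps sample ids to class 0/1, the supervision signal for the classifier arm
#' and the grouping for the F_ST estimator and ANOVA structure test.
#'
#' @param sample_ids character vector of labelled sample ids.
#' @param classes integer vector of 0/1 class codes, parallel to `sample_ids`.
#' @param class_names length-2 character vector naming classes 0 and 1.
#' @return An object of class `label_set`: list with `labels` (named integer
#'   vector of 0/1) and `class_names`.
#' @export
label_set <- function(sample_ids, classes, class_names = c("pop0", "pop1")) {
  classes <- as.integer(classes)
  if (length(sample_ids) != length(classes))
    stop("sample_ids and classes must have equal length")
  if (any(!classes %in% c(0L, 1L)))
    stop("classes must be 0 or 1")
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in label set")
  if (sum(classes == 0L) < 2L || sum(classes == 1L) < 2L)
    stop("each class needs at least 2 members")
  labels <- stats::setNames(classes, sample_ids)
  structure(list(labels = labels, class_names = as.character(class_names)),
            class = "label_set")
}

#' @export
print.label_set <- function(x, ...) {
  tab <- table(factor(x$labels, levels = c(0L, 1L)))
  cat(sprintf("label_set: %s=%d, %s=%d\n",
              x$class_names[1], tab[["0"]], x$class_names[2], tab[["1"]]))
  invisible(x)
}

# labels aligned to gm sample order; errors on ids absent from gm
align_labels <- function(gm, labels) {
  ids <- names(labels$labels)
  missing_ids <- setdiff(ids, gm$sample_ids)
  if (length(missing_ids))
    stop("labelled ids absent from genotype matrix: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  keep <- gm$sample_ids[gm$sample_ids %in% ids]
  labels$labels[keep]
}

#' Read PLINK text PED/MAP files
#'
#' Parses a PLINK text fileset into a [genotype_matrix()].  Dosage counts the
#' minor allele, with the minor allele determined from the file's own allele
#' frequencies (ties broken by lexicographic order of the allele symbol); the
#' PLINK missing genotype "0 0" becomes `NA`.  Column order follows the MAP
#' file.
#'
#' @param ped_path path to the .ped file (6 mandatory leading columns, then
#'   two space-separated alleles per SNP).
#' @param map_path path to the .map file (chromosome, SNP id, genetic
#'   distance, base-pair position).
#' @return A [genotype_matrix()].
#' @export
read_ped_map <- function(ped_path, map_path) {
  map <- utils::read.table(map_path, header = FALSE, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "integer"))
  names(map) <- c("chromosome", "snp_id", "gdist", "position")
  n <- nrow(map)
  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  m <- length(lines)
  alle <- matrix("0", nrow = m, ncol = 2L * n)
  sample_ids <- character(m)
  for (i in seq_len(m)) {
    f <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * n)
      stop(sprintf("PED row %d has %d fields, expected %d (6 + 2 x %d SNPs)",
                   i, length(f), 6L + 2L * n, n))
    sample_ids[i] <- f[2]
    alle[i, ] <- f[-(1:6)]
  }
  if (anyDuplicated(sample_ids))
    sample_ids <- paste(sample_ids, seq_len(m), sep = "_")
  dos <- matrix(NA_integer_, nrow = m, ncol = n)
  allele_a <- character(n)
  allele_b <- character(n)
  for (s in seq_len(n)) {
    a1 <- alle[, 2L * s - 1L]
    a2 <- alle[, 2L * s]
    half <- xor(a1 == "0", a2 == "0")
    if (any(half))
      stop(sprintf("SNP %s: half-missing genotype in PED row %d",
                   map$snp_id[s], which(half)[1]))
    obs <- c(a1, a2)
    obs <- obs[obs != "0"]
    syms <- sort(unique(obs))
    if (length(syms) > 2L)
      stop(sprintf("SNP %s has >2 alleles: %s", map$snp_id[s],
                   paste(syms, collapse = ",")))
    if (length(syms) == 0L) {          # all missing
      allele_a[s] <- "0"; allele_b[s] <- "0"
      next
    }
    if (length(syms) == 1L) {
      minor <- "0"; major <- syms[1]   # monomorphic: minor unseen
    } else {
      cnt <- c(sum(obs == syms[1]), sum(obs == syms[2]))
      # minor = rarer allele; tie -> lexicographically first symbol
      minor <- if (cnt[1] <= cnt[2]) syms[1] else syms[2]
      major <- setdiff(syms, minor)
    }
    allele_a[s] <- minor
    allele_b[s] <- major
    d <- (a1 == minor) + (a2 == minor)
    d[a1 == "0"] <- NA_integer_
    dos[, s] <- as.integer(d)
  }
  snps <- data.frame(snp_id = map$snp_id, chromosome = map$chromosome,
                     position = map$position, allele_a = allele_a,
                     allele_b = allele_b, stringsAsFactors = FALSE)
  genotype_matrix(dos, snps = snps, sample_ids = sample_ids)
}

#' Write PLINK text PED/MAP files
#'
#' Inverse of [read_ped_map()].  Dosage 2 is written as two copies of
#' `allele_a`, 0 as two copies of `allele_b`, `NA` as "0 0".  Output is
#' byte-stable given fixed input ordering.
#'
#' @param gm a [genotype_matrix()].
#' @param ped_path,map_path output paths.
#' @export
write_ped_map <- function(gm, ped_path, map_path) {
  snps <- gm$snps
  map <- data.frame(snps$chromosome, snps$snp_id, 0, snps$position)
  utils::write.table(map, map_path, quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  d <- gm$dosages
  m <- nrow(d); n <- ncol(d)
  a <- snps$allele_a; b <- snps$allele_b
  rows <- character(m)
  for (i in seq_len(m)) {
    g <- d[i, ]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1L, a, b))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2L, a, b))
    rows[i] <- paste(c(gm$sample_ids[i], gm$sample_ids[i], "0", "0", "0", "-9",
                       as.vector(rbind(a1, a2))), collapse = " ")
  }
  writeLines(rows, ped_path)
  invisible(gm)
}

#' Read a delimited dosage table
#'
#' Tab-separated text with a header row of SNP ids, one row per sample:
#' sample id, an optional `label` column (0/1), then dosage entries in
#' `{0, 1, 2, NA}`.  Lines starting with `#` are comments (the simulator
#' records its seed there).
#'
#' @param path input path.
#' @return A list with elements `genotypes` (a [genotype_matrix()]) and
#'   `labels` (a [label_set()] or `NULL` when no label column is present).
#' @export
read_dosage_table <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE, colClasses = "character")
  if (ncol(tab) < 2L) stop("dosage table needs a sample id column and SNPs")
  has_label <- identical(names(tab)[2], "label")
  sample_ids <- tab[[1]]
  first_snp <- if (has_label) 3L else 2L
  snp_ids <- names(tab)[first_snp:ncol(tab)]
  raw <- as.matrix(tab[, first_snp:ncol(tab), drop = FALSE])
  ok <- raw %in% c("0", "1", "2", "NA") | is.na(raw)
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop(sprintf("invalid dosage token '%s' at row %d, column %s",
                 raw[bad[1], bad[2]], bad[1], snp_ids[bad[2]]))
  }
  dos <- matrix(NA_integer_, nrow = nrow(raw), ncol = ncol(raw))
  dos[] <- suppressWarnings(as.integer(raw))
  gm <- genotype_matrix(dos, sample_ids = sample_ids,
                        snps = data.frame(
                          snp_id = snp_ids, chromosome = "1",
                          position = seq_along(snp_ids),
                          allele_a = "A", allele_b = "B",
                          stringsAsFactors = FALSE))
  labels <- NULL
  if (has_label) {
    cls <- suppressWarnings(as.integer(tab[[2]]))
    if (any(is.na(cls)) || any(!cls %in% c(0L, 1L)))
      stop("label column must contain 0/1")
    labels <- label_set(sample_ids, cls)
  }
  list(genotypes = gm, labels = labels)
}

#' Write a delimited dosage table
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @param labels optional [label_set()]; adds a `label` column.
#' @param comment optional character vector written as `#`-prefixed header
#'   comments (e.g. the simulation seed).
#' @export
write_dosage_table <- function(gm, path, labels = NULL, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment))
    writeLines(paste0("# ", comment), con)
  header <- c("sample_id", if (!is.null(labels)) "label", gm$snps$snp_id)
  writeLines(paste(header, collapse = "\t"), con)
  d <- gm$dosages
  lab <- if (!is.null(labels)) labels$labels[gm$sample_ids]
  for (i in seq_len(nrow(d))) {
    row <- c(gm$sample_ids[i], if (!is.null(labels)) lab[i],
             ifelse(is.na(d[i, ]), "NA", as.character(d[i, ])))
    writeLines(paste(row, collapse = "\t"), con)
  }
  invisible(gm)
}

#' Extract a contiguous SNP window
#'
#' Windows use 0-based, half-open indexing `[start_index, start_index +
#' length)`: consecutive windows of equal length tile the SNP axis exactly
#' once.  Sample order is preserved.
#'
#' @param gm a [genotype_matrix()].
#' @param start_index 0-based index of the first SNP in the window.
#' @param length number of SNPs.
#' @return A [genotype_matrix()] holding the SNP slice.
#' @export
subset_window <- function(gm, start_index, length) {
  n <- ncol(gm$dosages)
  if (start_index < 0L || length < 1L || start_index + length > n)
    stop(sprintf("window [%d, %d) out of range for %d SNPs",
                 start_index, start_index + length, n))
  idx <- seq.int(start_index + 1L, start_index + length)
  genotype_matrix(gm$dosages[, idx, drop = FALSE],
                  snps = gm$snps[idx, , drop = FALSE],
                  sample_ids = gm$sample_ids)
}

#' Mean-impute missing dosages
#'
#' Replaces each missing call by the SNP's mean dosage over non-missing calls,
#' leaving observed entries (and hence per-SNP means) unchanged.  Classifiers
#' and PCA only ever see complete real-valued matrices.
#'
#' @param gm a [genotype_matrix()].
#' @return A numeric matrix (samples x SNPs) with no missing values.
#' @export
impute_missing_mean <- function(gm) {
  d <- gm$dosages
  x <- matrix(as.numeric(d), nrow = nrow(d), dimnames = dimnames(d))
  nmiss <- colSums(!is.na(x))
  if (any(nmiss == 0L))
    stop("all calls missing at SNP(s): ",
         paste(utils::head(gm$snps$snp_id[nmiss == 0L], 3), collapse = ", "))
  mu <- colMeans(x, na.rm = TRUE)
  idx <- which(is.na(x), arr.ind = TRUE)
  if (nrow(idx)) x[idx] <- mu[idx[, 2]]
  x
}
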