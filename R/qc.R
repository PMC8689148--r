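#' Quality-control thresholds
#'
#' Default values reproduce the usual SNP-array editing rules for livestock
#' panels: individuals and SNPs with more than 5% missing genotypes are
#' dropped, SNPs with minor allele frequency below 5% (or monomorphic) are
#' dropped within each population, and SNPs failing the Hardy-Weinberg exact
#' test at a Bonferroni-style cutoff of 5.7e-7 are excluded.
#'
#' @param max_missing_individual maximum missing-call fraction per individual.
#' @param max_missing_snp maximum missing-call fraction per SNP.
#' @param min_maf minimum minor allele frequency (monomorphic SNPs are always
#'   dropped).
#' @param hwe_p_cutoff SNPs with exact-test p <= this value are removed.
#' @param hwe_scope `"per_population"` (default) tests HWE within each
#'   population before merging; `"merged"` tests on the pooled post-missingness
#'   data.
#' @param hwe_midp use the mid-p variant of the exact test?
#' @return a list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_missing_individual = 0.05,
                          max_missing_snp = 0.05,
                          min_maf = 0.05,
                          hwe_p_cutoff = 5.7e-7,
                          hwe_scope = c("per_population", "merged"),
                          hwe_midp = FALSE) {
  stopifnot(max_missing_individual > 0, max_missing_individual < 1,
            max_missing_snp > 0, max_missing_snp < 1,
            min_maf > 0, min_maf < 1, hwe_p_cutoff > 0, hwe_p_cutoff < 1)
  structure(list(max_missing_individual = max_missing_individual,
                 max_missing_snp = max_missing_snp,
                 min_maf = min_maf,
                 hwe_p_cutoff = hwe_p_cutoff,
                 hwe_scope = match.arg(hwe_scope),
                 hwe_midp = isTRUE(hwe_midp)),
            class = "qc_thresholds")
}

#' Minor allele frequency of a dosage vector
#'
#' @param dosages vector of alternate-allele counts in `{0, 1, 2, NA}`.
#' @return `min(p, 1 - p)` where `p` is the alternate-allele frequency over
#'   non-missing calls.
#' @examples
#' minor_allele_frequency(c(2, 1, 0, NA))  # 3 alt alleles / 6 -> 0.5
#' @export
minor_allele_frequency <- function(dosages) {
  ok <- !is.na(dosages)
  if (!any(ok)) stop("minor allele frequency undefined: all calls missing")
  p <- sum(dosages[ok]) / (2 * sum(ok))
  min(p, 1 - p)
}

# Conditional distribution of the heterozygote count given allele totals, and
# the two-sided exact p-value for every possible heterozygote count.
# n_minor = minor allele count, n = genotyped individuals.  Returns a list
# with `hets` (possible heterozygote counts), `probs`, and `pvals`.
.hwe_pvals <- function(n_minor, n) {
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  n_major <- 2L * n - n_minor
  # log P(het = h | allele counts) via the hypergeometric-style closed form
  lp <- lgamma(n + 1) - lgamma((n_minor - hets) / 2 + 1) -
    lgamma(hets + 1) - lgamma((n_major - hets) / 2 + 1) +
    hets * log(2) +
    lgamma(n_minor + 1) + lgamma(n_major + 1) - lgamma(2 * n + 1)
  probs <- exp(lp - max(lp))
  probs <- probs / sum(probs)
  ord <- order(probs)
  sorted <- probs[ord]
  cum <- cumsum(sorted)
  # p(obs) = sum of probabilities <= P(obs); tolerate float ties
  idx <- findInterval(probs * (1 + 1e-12), sorted)
  pvals <- pmin(cum[idx], 1)
  list(hets = hets, probs = probs, pvals = pvals)
}

#' Hardy-Weinberg exact test
#'
#' The standard two-sided conditional exact test: given the observed allele
#' counts, the p-value is the total conditional probability of all
#' heterozygote counts whose probability does not exceed that of the observed
#' count.  An optional mid-p variant subtracts half the probability of the
#' observed configuration.
#'
#' @param n_hom_ref,n_het,n_hom_alt genotype counts.
#' @param midp use the mid-p variant?
#' @return the exact p-value.
#' @examples
#' hwe_exact_test(25, 50, 25)   # observed het count at the conditional mode
#' hwe_exact_test(50, 0, 50)    # extreme heterozygote deficit
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt, midp = FALSE) {
  counts <- c(n_hom_ref, n_het, n_hom_alt)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts)))
    stop("genotype counts must be non-negative integers")
  n <- sum(counts)
  if (n < 1) stop("total genotype count must be >= 1")
  n_alt <- 2 * n_hom_alt + n_het
  n_minor <- min(n_alt, 2 * n - n_alt)
  dist <- .hwe_pvals(n_minor, n)
  i <- match(n_het, dist$hets)
  p <- dist$pvals[i]
  if (midp) p <- p - dist$probs[i] / 2
  p
}

#' Per-population genotype QC and common-marker merge
#'
#' Applies, in order: (1) drop individuals with missing fraction above
#' `max_missing_individual`; (2) drop SNPs with missing fraction above
#' `max_missing_snp`; (3) drop SNPs with Hardy-Weinberg exact p <=
#' `hwe_p_cutoff` (within each population by default); (4) drop, within each
#' population, monomorphic SNPs and SNPs with MAF below `min_maf`; (5)
#' restrict all populations to the common marker set.  Remaining missing calls
#' are filled by per-population mode imputation (ties favour the
#' reference-homozygote) unless `impute = FALSE`.
#'
#' @param datasets a [genotype_dataset()] or list of them (one per
#'   population/genetic group).
#' @param thresholds a [qc_thresholds()] object.
#' @param impute fill residual missing calls by per-population mode
#'   imputation?
#' @return list with `datasets` (filtered, same order) and `report`
#'   (a `qc_report`).
#' @export
run_qc <- function(datasets, thresholds = qc_thresholds(), impute = TRUE) {
  single <- inherits(datasets, "genotype_dataset")
  if (single) datasets <- list(datasets)
  if (length(datasets) < 1) stop("need at least one dataset")
  labels <- vapply(datasets, function(d)
    paste(unique(d$samples$population), collapse = "+"), "")

  ind_removed <- 0L
  snp_missing_removed <- 0L
  snp_hwe_removed <- 0L
  snp_maf_removed <- stats::setNames(integer(length(datasets)), labels)

  # (1) individual call rate
  datasets <- lapply(seq_along(datasets), function(k) {
    ds <- datasets[[k]]
    frac <- rowMeans(is.na(ds$calls))
    drop <- frac > thresholds$max_missing_individual
    ind_removed <<- ind_removed + sum(drop)
    if (all(drop))
      stop("population ", labels[k],
           " lost all individuals to the individual call-rate filter")
    if (any(drop)) subset_dataset(ds, i = which(!drop)) else ds
  })

  # (2) SNP call rate
  datasets <- lapply(seq_along(datasets), function(k) {
    ds <- datasets[[k]]
    frac <- colMeans(is.na(ds$calls))
    drop <- frac > thresholds$max_missing_snp
    snp_missing_removed <<- snp_missing_removed + sum(drop)
    if (all(drop))
      stop("population ", labels[k],
           " lost all markers to the SNP call-rate filter")
    if (any(drop)) subset_dataset(ds, j = which(!drop)) else ds
  })

  # (3) HWE
  hwe_drop_count <- function(ds) {
    p <- apply(ds$calls, 2, function(d) {
      d <- d[!is.na(d)]
      if (length(d) == 0) return(1)
      hwe_exact_test(sum(d == 0), sum(d == 1), sum(d == 2),
                     midp = thresholds$hwe_midp)
    })
    which(p <= thresholds$hwe_p_cutoff)
  }
  if (thresholds$hwe_scope == "per_population") {
    datasets <- lapply(seq_along(datasets), function(k) {
      ds <- datasets[[k]]
      drop <- hwe_drop_count(ds)
      snp_hwe_removed <<- snp_hwe_removed + length(drop)
      if (length(drop) == ncol(ds$calls))
        stop("population ", labels[k],
             " lost all markers to the Hardy-Weinberg filter")
      if (length(drop)) subset_dataset(ds, j = -drop) else ds
    })
  } else {
    common <- if (length(datasets) > 1)
      intersect_on_common_markers(datasets) else datasets
    merged_calls <- do.call(rbind, lapply(common, function(d) d$calls))
    merged <- common[[1]]
    merged$calls <- merged_calls
    merged$samples <- do.call(rbind, lapply(common, function(d) d$samples))
    merged$haplotypes <- NULL; merged$phased <- FALSE
    drop_keys <- with(merged$variants[hwe_drop_count(merged), , drop = FALSE],
                      paste(id, chrom, pos_bp))
    snp_hwe_removed <- length(drop_keys)
    datasets <- lapply(datasets, function(ds) {
      keys <- with(ds$variants, paste(id, chrom, pos_bp))
      keep <- !(keys %in% drop_keys)
      if (!any(keep)) stop("Hardy-Weinberg filter removed all markers")
      subset_dataset(ds, j = which(keep))
    })
  }

  # (4) MAF / monomorphic, per population
  datasets <- lapply(seq_along(datasets), function(k) {
    ds <- datasets[[k]]
    maf <- apply(ds$calls, 2, function(d)
      if (all(is.na(d))) 0 else minor_allele_frequency(d))
    drop <- maf == 0 | maf < thresholds$min_maf
    snp_maf_removed[k] <<- sum(drop)
    if (all(drop))
      stop("population ", labels[k],
           " lost all markers to the MAF/monomorphic filter")
    if (any(drop)) subset_dataset(ds, j = which(!drop)) else ds
  })

  # (5) common-marker merge
  if (length(datasets) > 1) datasets <- intersect_on_common_markers(datasets)
  snps_after_merge <- ncol(datasets[[1]]$calls)
  total_rate <- mean(unlist(lapply(datasets, function(d) !is.na(d$calls))))

  if (impute) datasets <- lapply(datasets, impute_mode)

  report <- structure(list(
    individuals_removed = ind_removed,
    snps_removed_missing = snp_missing_removed,
    snps_removed_hwe = snp_hwe_removed,
    snps_removed_maf = snp_maf_removed,
    snps_after_merge = snps_after_merge,
    total_genotyping_rate = total_rate,
    thresholds = thresholds), class = "qc_report")

  list(datasets = if (single) datasets else datasets, report = report)
}

# Mode imputation per SNP; ties broken toward the smaller dosage, so the
# reference homozygote wins an exact tie.
impute_mode <- function(ds) {
  miss <- is.na(ds$calls)
  if (!any(miss)) return(ds)
  for (j in which(colSums(miss) > 0)) {
    d <- ds$calls[, j]
    tab <- tabulate(d + 1L, nbins = 3L)  # counts of dosage 0, 1, 2
    mode_d <- which.max(tab) - 1L
    fill <- is.na(d)
    ds$calls[fill, j] <- mode_d
    if (!is.null(ds$haplotypes)) {
      rows <- which(fill)
      ds$haplotypes[2L * rows - 1L, j] <- as.integer(mode_d >= 1L)
      ds$haplotypes[2L * rows, j] <- as.integer(mode_d == 2L)
    }
  }
  ds
}

#' @export
print.qc_report <- function(x, ...) {
  cat("Genotype QC report\n")
  cat("  individuals removed (call rate):", x$individuals_removed, "\n")
  cat("  SNPs removed (call rate):       ", x$snps_removed_missing, "\n")
  cat("  SNPs removed (HWE):             ", x$snps_removed_hwe, "\n")
  cat("  SNPs removed (MAF/monomorphic): ",
      paste(sprintf("%s=%d", names(x$snps_removed_maf), x$snps_removed_maf),
            collapse = ", "), "\n")
  cat("  SNPs after merge:               ", x$snps_after_merge, "\n")
  cat("  total genotyping rate:          ",
      format(x$total_genotyping_rate, digits = 4), "\n")
  invisible(x)
}
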