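#' Haplotype and allele frequencies for one SNP pair
#'
#' Direct gamete counting on phased data.  Allele "A" (and "B") is the
#' alternate allele (coded 1) at the first (second) locus, so the sign of the
#' derived r matches the dosage-correlation sign.
#'
#' @param hap_i,hap_j gamete allele vectors in `{0, 1}`, one entry per gamete
#'   (two per diploid sample), equal length.
#' @return list of class `haplotype_freqs` with `freq_A`, `freq_a`, `freq_B`,
#'   `freq_b`, `freq_AB`, `n_gametes`.
#' @examples
#' # 100 gametes: AB = 40, Ab = 10, aB = 10, ab = 40
#' hi <- rep(c(1, 1, 0, 0), c(40, 10, 10, 40))
#' hj <- rep(c(1, 0, 1, 0), c(40, 10, 10, 40))
#' haplotype_freqs_phased(hi, hj)
#' @export
haplotype_freqs_phased <- function(hap_i, hap_j) {
  if (length(hap_i) != length(hap_j))
    stop("gamete vectors must have equal length")
  ok <- !is.na(hap_i) & !is.na(hap_j)
  hap_i <- hap_i[ok]; hap_j <- hap_j[ok]
  if (length(hap_i) == 0) stop("no complete gametes")
  if (any(!(hap_i %in% 0:1)) || any(!(hap_j %in% 0:1)))
    stop("gamete alleles must be 0/1")
  m <- length(hap_i)
  fA <- mean(hap_i)
  fB <- mean(hap_j)
  fAB <- mean(hap_i == 1 & hap_j == 1)
  structure(list(freq_A = fA, freq_a = 1 - fA,
                 freq_B = fB, freq_b = 1 - fB,
                 freq_AB = fAB, n_gametes = m),
            class = "haplotype_freqs")
}

#' LD statistics from haplotype frequencies
#'
#' Computes the classical two-locus disequilibrium statistics:
#' `D = freq_AB - freq_A * freq_B`, the correlation
#' `r = D / sqrt(freq_A * freq_a * freq_B * freq_b)`, `r2 = r^2`, and
#' Lewontin's `D' = |D| / D_max`, where `D_max = min(freq_A * freq_b,
#' freq_a * freq_B)` when `D > 0` and `min(freq_A * freq_B, freq_a * freq_b)`
#' when `D < 0` (`D' = 0` when `D = 0`).
#'
#' @param f a `haplotype_freqs` object (or list with the same fields).
#' @return list with `D`, `D_prime`, `r`, `r2`.
#' @examples
#' f <- haplotype_freqs_phased(rep(c(1, 1, 0, 0), c(40, 10, 10, 40)),
#'                             rep(c(1, 0, 1, 0), c(40, 10, 10, 40)))
#' ld_from_freqs(f)  # D = 0.15, r2 = 0.36, D' = 0.6
#' @export
ld_from_freqs <- function(f) {
  fr <- c(f$freq_A, f$freq_a, f$freq_B, f$freq_b)
  if (any(fr <= 0))
    stop("LD undefined: at least one locus is monomorphic")
  D <- f$freq_AB - f$freq_A * f$freq_B
  r <- D / sqrt(f$freq_A * f$freq_a * f$freq_B * f$freq_b)
  if (D > 0) {
    d_max <- min(f$freq_A * f$freq_b, f$freq_a * f$freq_B)
  } else if (D < 0) {
    d_max <- min(f$freq_A * f$freq_B, f$freq_a * f$freq_b)
  } else {
    return(list(D = 0, D_prime = 0, r = 0, r2 = 0))
  }
  list(D = D, D_prime = abs(D) / d_max, r = r, r2 = r^2)
}

#' Signed r between two loci from unphased dosages
#'
#' The product-moment correlation of the two dosage vectors over samples with
#' both calls present — the genotype-level stand-in for the gametic r when
#' phase is unknown (pair with `beta = 1` in [adjust_r2()]).
#'
#' @param dosages_i,dosages_j dosage vectors in `{0, 1, 2, NA}`.
#' @return the signed correlation.
#' @export
r_unphased <- function(dosages_i, dosages_j) {
  if (length(dosages_i) != length(dosages_j))
    stop("dosage vectors must have equal length")
  ok <- !is.na(dosages_i) & !is.na(dosages_j)
  if (sum(ok) < 2) stop("need at least two complete sample pairs")
  x <- dosages_i[ok]; y <- dosages_j[ok]
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("LD undefined: zero variance at one locus")
  stats::cor(x, y)
}

#' Sample-size / phase correction of r-squared
#'
#' Subtracts the finite-sample expectation of r-squared under no LD:
#' `r2_adj = r2 - 1/(beta * n)`, with `beta = 2` when the gametic phase is
#' known and `beta = 1` when it is not.  Negative results are returned as-is
#' (callers skip or flag them).
#'
#' @param r2 raw r-squared value(s).
#' @param n number of individuals sampled.
#' @param phased was the gametic phase known?
#' @return adjusted r-squared (vectorised over `r2`).
#' @examples
#' adjust_r2(0.34, n = 15, phased = FALSE)  # 0.2733...
#' adjust_r2(0.36, n = 10, phased = TRUE)   # 0.31
#' @export
adjust_r2 <- function(r2, n, phased = FALSE) {
  if (length(n) != 1 || is.na(n) || n < 1)
    stop("n must be a single count >= 1")
  beta <- if (isTRUE(phased)) 2 else 1
  r2 - 1 / (beta * n)
}

# ---------------------------------------------------------------------------
# vectorised pairwise engine

#' Pairwise LD statistics for a dataset
#'
#' The workhorse behind [adjacent_ld_summary()], [ld_decay()] and [pldp()]:
#' computes D, D', signed r, r-squared and adjusted r-squared for marker
#' pairs, vectorised per chromosome.  With `scheme = "adjacent"` only
#' consecutive markers in map order are paired; with `scheme = "all"`, all
#' intra-chromosomal pairs separated by at most `max_bp`.  Pairs involving a
#' locus monomorphic in this dataset get `NA` statistics and are counted in
#' the `n_skipped` attribute; D and D' are only available on the phased path.
#'
#' @inheritParams adjacent_ld_summary
#' @param scheme `"adjacent"` or `"all"`.
#' @param max_bp largest pair separation retained (scheme `"all"`).
#' @return data frame with one row per pair (`chrom`, `variant_i`,
#'   `variant_j`, `distance_bp`, `D`, `D_prime`, `r`, `r2`, `r2_adj`) and
#'   attributes `n`, `beta`, `n_skipped`, `skipped_chromosomes`.
#' @export
ld_pair_stats <- function(ds, scheme = c("adjacent", "all"), max_bp = Inf,
                          phased = NULL, autosomes_only = FALSE) {
  scheme <- match.arg(scheme)
  if (is.null(phased)) phased <- ds$phased
  if (phased && is.null(ds$haplotypes))
    stop("phased = TRUE requires a dataset with haplotypes")
  n <- nrow(ds$calls)
  beta <- if (phased) 2 else 1

  chroms <- unique(ds$variants$chrom)
  if (autosomes_only) chroms <- chroms[!is_x_chromosome(chroms)]
  out <- vector("list", length(chroms))
  skipped_chroms <- character(0)
  n_skipped <- 0L

  for (ci in seq_along(chroms)) {
    idx <- which(ds$variants$chrom == chroms[ci])
    if (length(idx) < 2) {
      skipped_chroms <- c(skipped_chroms, chroms[ci])
      next
    }
    pos <- ds$variants$pos_bp[idx]
    if (phased) {
      H <- ds$haplotypes[, idx, drop = FALSE]
      m <- nrow(H)
      p <- colMeans(H)
      poly <- p > 0 & p < 1
      pAB <- crossprod(H) / m
      Dm <- pAB - tcrossprod(p)
      v <- p * (1 - p)
      rm_ <- Dm / sqrt(tcrossprod(v))
      pos_dmax <- pmin(tcrossprod(p, 1 - p), tcrossprod(1 - p, p))
      neg_dmax <- pmin(tcrossprod(p, p), tcrossprod(1 - p, 1 - p))
      Dpm <- ifelse(Dm > 0, abs(Dm) / pos_dmax,
                    ifelse(Dm < 0, abs(Dm) / neg_dmax, 0))
    } else {
      X <- ds$calls[, idx, drop = FALSE]
      sds <- apply(X, 2, stats::sd, na.rm = TRUE)
      poly <- !is.na(sds) & sds > 0
      rm_ <- suppressWarnings(stats::cor(X, use = "pairwise.complete.obs"))
      Dm <- Dpm <- NULL
    }

    if (scheme == "adjacent") {
      i <- seq_len(length(idx) - 1L)
      j <- i + 1L
    } else {
      dmat <- abs(outer(pos, pos, "-"))
      sel <- which(upper.tri(dmat) & dmat <= max_bp, arr.ind = TRUE)
      i <- sel[, 1]; j <- sel[, 2]
    }
    if (length(i) == 0) next
    usable <- poly[i] & poly[j]
    n_skipped <- n_skipped + sum(!usable)
    lin <- cbind(i, j)
    r <- rm_[lin]
    r[!usable] <- NA_real_
    df <- data.frame(
      chrom = chroms[ci],
      variant_i = ds$variants$id[idx[i]],
      variant_j = ds$variants$id[idx[j]],
      distance_bp = abs(pos[j] - pos[i]),
      D = if (phased) ifelse(usable, Dm[lin], NA_real_) else NA_real_,
      D_prime = if (phased) ifelse(usable, Dpm[lin], NA_real_) else NA_real_,
      r = r, r2 = r^2,
      stringsAsFactors = FALSE)
    df$r2_adj <- df$r2 - 1 / (beta * n)
    out[[ci]] <- df
  }
  res <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  if (is.null(res))
    res <- data.frame(chrom = character(0), variant_i = character(0),
                      variant_j = character(0), distance_bp = integer(0),
                      D = numeric(0), D_prime = numeric(0), r = numeric(0),
                      r2 = numeric(0), r2_adj = numeric(0))
  rownames(res) <- NULL
  attr(res, "n") <- n
  attr(res, "beta") <- beta
  attr(res, "n_skipped") <- n_skipped
  attr(res, "skipped_chromosomes") <- skipped_chroms
  res
}

#' Adjacent-SNP LD summary per chromosome
#'
#' For consecutive markers in map order on each chromosome: mean spacing,
#' mean and sd of adjusted r-squared and of D', and the fraction of adjacent
#' pairs with adjusted r-squared above each threshold.  A final `"all"` row
#' aggregates genome-wide.  Pairs with undefined LD (a monomorphic locus) are
#' excluded from the statistics and counted.
#'
#' @param ds a QC'd [genotype_dataset()].
#' @param phased use gamete counting (`beta = 2`)?  Defaults to the dataset's
#'   phase flag.
#' @param thresholds adjusted-r-squared thresholds for the
#'   fraction-above columns.
#' @param autosomes_only exclude X-chromosome markers?
#' @return data frame of class `adjacent_ld_summary`, one row per chromosome
#'   plus an `"all"` row.
#' @export
adjacent_ld_summary <- function(ds, phased = NULL, thresholds = c(0.2, 0.3),
                                autosomes_only = FALSE) {
  pairs <- ld_pair_stats(ds, scheme = "adjacent", phased = phased,
                         autosomes_only = autosomes_only)
  for (ch in attr(pairs, "skipped_chromosomes"))
    message("adjacent_ld_summary: chromosome ", ch,
            " has fewer than two markers; skipped")
  summarise <- function(df, label) {
    use <- !is.na(df$r)
    row <- data.frame(
      chromosome = label,
      n_snps = if (label == "all") nrow(ds$variants)
               else sum(ds$variants$chrom == label),
      n_pairs = sum(use),
      n_undefined = sum(!use),
      mean_spacing_kb = mean(df$distance_bp) / 1e3,
      mean_r2_adj = mean(df$r2_adj[use]),
      sd_r2_adj = stats::sd(df$r2_adj[use]),
      mean_D_prime = mean(df$D_prime[use]),
      sd_D_prime = stats::sd(df$D_prime[use]),
      stringsAsFactors = FALSE)
    for (t in thresholds)
      row[[sprintf("frac_r2_adj_gt_%g", t)]] <-
        if (any(use)) mean(df$r2_adj[use] > t) else NA_real_
    row
  }
  parts <- lapply(split(pairs, pairs$chrom), function(df)
    summarise(df, df$chrom[1]))
  parts <- parts[order(match(names(parts), unique(ds$variants$chrom)))]
  res <- do.call(rbind, c(parts, list(summarise(pairs, "all"))))
  rownames(res) <- NULL
  attr(res, "n") <- attr(pairs, "n")
  attr(res, "beta") <- attr(pairs, "beta")
  class(res) <- c("adjacent_ld_summary", "data.frame")
  res
}

#' Distance-binned LD decay
#'
#' All intra-chromosomal marker pairs with separation at most `max_bp` are
#' grouped into contiguous physical-distance bins `(k*bin_bp, (k+1)*bin_bp]`
#' and the unweighted mean of raw and adjusted r-squared is reported per bin.
#'
#' @inheritParams adjacent_ld_summary
#' @param max_bp largest pair separation considered (default 15 Mb).
#' @param bin_bp bin width (default 100 kb).
#' @return data frame of class `ld_decay` with one row per bin: `lower_bp`,
#'   `upper_bp`, `n_pairs`, `mean_distance_bp`, `mean_r2`, `mean_r2_adj`.
#'   Empty bins carry `NA` means.  Attributes record `n`, `beta` and the
#'   number of skipped (monomorphic) pairs.
#' @export
ld_decay <- function(ds, max_bp = 15e6, bin_bp = 1e5, phased = NULL,
                     autosomes_only = FALSE) {
  if (bin_bp <= 0) stop("bin_bp must be positive")
  if (max_bp < bin_bp) stop("max_bp must be at least one bin wide")
  n_bins <- floor(max_bp / bin_bp)
  pairs <- ld_pair_stats(ds, scheme = "all", max_bp = n_bins * bin_bp,
                         phased = phased, autosomes_only = autosomes_only)
  use <- !is.na(pairs$r)
  bin <- ceiling(pairs$distance_bp[use] / bin_bp)
  r2 <- pairs$r2[use]; r2a <- pairs$r2_adj[use]; d <- pairs$distance_bp[use]
  res <- data.frame(
    lower_bp = (seq_len(n_bins) - 1) * bin_bp,
    upper_bp = seq_len(n_bins) * bin_bp,
    n_pairs = as.integer(tabulate(bin, nbins = n_bins)),
    mean_distance_bp = as.numeric(tapply_bins(d, bin, n_bins)),
    mean_r2 = as.numeric(tapply_bins(r2, bin, n_bins)),
    mean_r2_adj = as.numeric(tapply_bins(r2a, bin, n_bins)))
  attr(res, "n") <- attr(pairs, "n")
  attr(res, "beta") <- attr(pairs, "beta")
  attr(res, "n_skipped") <- attr(pairs, "n_skipped")
  class(res) <- c("ld_decay", "data.frame")
  res
}

# mean of x within integer bins 1..n_bins (NA where empty)
tapply_bins <- function(x, bin, n_bins) {
  s <- rep(0, n_bins); cnt <- rep(0L, n_bins)
  if (length(x)) {
    agg <- rowsum(x, bin)
    cnt_agg <- rowsum(rep(1L, length(x)), bin)
    k <- as.integer(rownames(agg))
    s[k] <- agg[, 1]; cnt[k] <- cnt_agg[, 1]
  }
  ifelse(cnt > 0, s / pmax(cnt, 1L), NA_real_)
}

#' @export
print.ld_decay <- function(x, ...) {
  cat("LD decay:", sum(x$n_pairs), "pairs in", nrow(x), "bins of",
      format((x$upper_bp[1] - x$lower_bp[1]) / 1e3), "kb",
      sprintf("(n = %d, beta = %d)\n", attr(x, "n"), attr(x, "beta")))
  print.data.frame(utils::head(x[x$n_pairs > 0, ], 10))
  if (sum(x$n_pairs > 0) > 10) cat("...\n")
  invisible(x)
}

#' @export
plot.ld_decay <- function(x, adjusted = TRUE, ...) {
  use <- x$n_pairs > 0
  mid <- (x$lower_bp + x$upper_bp) / 2e6
  y <- if (adjusted) x$mean_r2_adj else x$mean_r2
  graphics::plot(mid[use], y[use], type = "b", pch = 16, cex = 0.6,
                 xlab = "distance (Mb)",
                 ylab = if (adjusted) expression(adjusted ~ r^2)
                        else expression(r^2), ...)
  invisible(x)
}
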