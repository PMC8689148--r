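#' Reconcile allele coding between two datasets
#'
#' Signed r is only comparable across populations when both datasets count
#' the same allele at every marker.  For each marker where dataset B's
#' ref/alt pair is the reverse of A's, B's dosages are complemented
#' (`2 - dosage`) and its haplotype alleles flipped; A/T and C/G markers,
#' whose strand cannot be resolved from the allele pair, are flagged.
#'
#' @param ds_a,ds_b datasets with identical marker sets (run
#'   [intersect_on_common_markers()] first).
#' @return list with elements `a`, `b` (aligned datasets), `flipped`
#'   (marker ids complemented in B) and `ambiguous` (strand-ambiguous ids).
#' @export
align_alleles <- function(ds_a, ds_b) {
  va <- ds_a$variants; vb <- ds_b$variants
  if (!identical(paste(va$id, va$chrom, va$pos_bp),
                 paste(vb$id, vb$chrom, vb$pos_bp)))
    stop("datasets must carry identical marker sets in identical order; ",
         "run intersect_on_common_markers() first")
  same <- va$ref == vb$ref & va$alt == vb$alt
  swapped <- va$ref == vb$alt & va$alt == vb$ref
  bad <- !(same | swapped)
  if (any(bad))
    stop("allele pairs irreconcilable (even after ref/alt flip) at: ",
         paste(utils::head(va$id[bad], 10), collapse = ", "))
  ambiguous <- va$id[(va$ref == "A" & va$alt == "T") |
                     (va$ref == "T" & va$alt == "A") |
                     (va$ref == "C" & va$alt == "G") |
                     (va$ref == "G" & va$alt == "C")]
  flip <- which(swapped)
  if (length(flip)) {
    ds_b$calls[, flip] <- 2L - ds_b$calls[, flip]
    if (!is.null(ds_b$haplotypes))
      ds_b$haplotypes[, flip] <- 1L - ds_b$haplotypes[, flip]
    ds_b$variants$ref[flip] <- va$ref[flip]
    ds_b$variants$alt[flip] <- va$alt[flip]
  }
  list(a = ds_a, b = ds_b, flipped = va$id[flip], ambiguous = ambiguous)
}

#' Persistence of LD phase between two populations
#'
#' For every shared SNP pair the signed r (the signed root of r-squared,
#' carrying the sign of D — for unphased data, the sign of the dosage
#' correlation) is computed in each population; per physical-distance bin the
#' product-moment correlation between the two populations' signed-r vectors
#' is reported:
#' `r_bin = sum((rA - mean(rA)) * (rB - mean(rB))) / (S_A * S_B)`.
#' A correlation near 1 means marker phase — and hence marker effects —
#' transfer between the populations at that distance.
#'
#' @param ds_a,ds_b aligned datasets (see [align_alleles()]) with identical
#'   marker maps.
#' @param scheme `"all"` (default): all intra-chromosomal pairs within
#'   `max_bp`; `"adjacent"`: consecutive-marker pairs only.
#' @param bin_bp distance bin width (default 100 kb).
#' @param max_bp largest pair separation (default 1 Mb).
#' @param phased use gametic r (requires haplotypes in both datasets)?
#'   Defaults to `TRUE` only when both datasets are phased.
#' @param autosomes_only exclude X-chromosome markers?
#' @return object of class `pldp`: list with `populations`, `bins` (data
#'   frame: `lower_bp`, `upper_bp`, `n_pairs`, `correlation` — `NA` when a
#'   bin has fewer than 3 usable pairs) and `n_dropped` (pairs monomorphic
#'   in at least one population).
#' @export
pldp <- function(ds_a, ds_b, scheme = c("all", "adjacent"), bin_bp = 1e5,
                 max_bp = 1e6, phased = NULL, autosomes_only = FALSE) {
  scheme <- match.arg(scheme)
  va <- ds_a$variants; vb <- ds_b$variants
  if (!identical(paste(va$id, va$chrom, va$pos_bp),
                 paste(vb$id, vb$chrom, vb$pos_bp)))
    stop("datasets must share an identical marker map; run ",
         "intersect_on_common_markers() and align_alleles() first")
  if (is.null(phased)) phased <- ds_a$phased && ds_b$phased
  if (bin_bp <= 0) stop("bin_bp must be positive")
  if (max_bp < bin_bp) stop("max_bp must be at least one bin wide")
  n_bins <- floor(max_bp / bin_bp)

  pa <- ld_pair_stats(ds_a, scheme = scheme, max_bp = n_bins * bin_bp,
                      phased = phased, autosomes_only = autosomes_only)
  pb <- ld_pair_stats(ds_b, scheme = scheme, max_bp = n_bins * bin_bp,
                      phased = phased, autosomes_only = autosomes_only)
  # identical maps and scheme -> identical pair lists, row for row
  stopifnot(identical(pa$variant_i, pb$variant_i),
            identical(pa$variant_j, pb$variant_j))
  if (scheme == "adjacent") {
    keep <- pa$distance_bp <= n_bins * bin_bp
    pa <- pa[keep, ]; pb <- pb[keep, ]
  }
  usable <- !is.na(pa$r) & !is.na(pb$r)
  n_dropped <- sum(!usable)
  bin <- ceiling(pa$distance_bp / bin_bp)

  bins <- data.frame(lower_bp = (seq_len(n_bins) - 1) * bin_bp,
                     upper_bp = seq_len(n_bins) * bin_bp,
                     n_pairs = 0L, correlation = NA_real_)
  for (k in seq_len(n_bins)) {
    sel <- usable & bin == k
    bins$n_pairs[k] <- sum(sel)
    if (sum(sel) >= 3)
      bins$correlation[k] <- phase_correlation(pa$r[sel], pb$r[sel])
  }
  structure(list(populations = c(paste(unique(ds_a$samples$population),
                                       collapse = "+"),
                                 paste(unique(ds_b$samples$population),
                                       collapse = "+")),
                 bins = bins, n_dropped = n_dropped,
                 scheme = scheme, phased = phased),
            class = "pldp")
}

# Product-moment correlation of two signed-r vectors, written out as the
# phase-persistence formula; identical vectors return exactly 1.
phase_correlation <- function(r_a, r_b) {
  if (identical(r_a, r_b)) return(1)
  da <- r_a - mean(r_a)
  db <- r_b - mean(r_b)
  ssa <- sum(da^2); ssb <- sum(db^2)
  if (ssa == 0 || ssb == 0) return(NA_real_)
  sum(da * db) / (sqrt(ssa) * sqrt(ssb))
}

#' @export
print.pldp <- function(x, ...) {
  cat("Persistence of LD phase:", x$populations[1], "vs", x$populations[2],
      sprintf("(%s pairs, %s)\n", x$scheme,
              if (x$phased) "phased" else "unphased"))
  if (x$n_dropped > 0)
    cat("  pairs dropped (monomorphic in a population):", x$n_dropped, "\n")
  b <- x$bins
  lab <- sprintf("%g-%g kb", b$lower_bp / 1e3, b$upper_bp / 1e3)
  print.data.frame(data.frame(bin = lab, n_pairs = b$n_pairs,
                              correlation = round(b$correlation, 4)))
  invisible(x)
}

#' @export
plot.pldp <- function(x, ...) {
  b <- x$bins
  mid <- (b$lower_bp + b$upper_bp) / 2e3
  graphics::plot(mid, b$correlation, type = "b", pch = 16, ylim = c(-0.2, 1),
                 xlab = "distance (kb)", ylab = "phase correlation",
                 main = paste(x$populations, collapse = " vs "), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
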