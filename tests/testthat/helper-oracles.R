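# Independent oracles and small fixture builders shared across the suite.

# Build a genotype_dataset from a dosage matrix with minimal metadata.
make_dataset <- function(calls, chrom = "1", pos_bp = NULL,
                         population = "popA", ref = "A", alt = "C",
                         haplotypes = NULL, phased = FALSE) {
  calls <- as.matrix(calls)
  L <- ncol(calls)
  if (is.null(pos_bp)) pos_bp <- seq_len(L) * 1000L
  chrom <- rep_len(chrom, L)
  variants <- data.frame(id = paste0("m", seq_len(L)), chrom = chrom,
                         pos_bp = pos_bp, ref = rep_len(ref, L),
                         alt = rep_len(alt, L), stringsAsFactors = FALSE)
  samples <- data.frame(id = paste0("i", seq_len(nrow(calls))),
                        population = population, stringsAsFactors = FALSE)
  genotype_dataset(calls, variants, samples, haplotypes = haplotypes,
                   phased = phased)
}

# Build a phased dataset directly from a gamete matrix (2n x L in {0,1}).
make_phased_dataset <- function(hap, ...) {
  d <- hap[seq(1, nrow(hap), 2), , drop = FALSE] +
    hap[seq(2, nrow(hap), 2), , drop = FALSE]
  make_dataset(d, haplotypes = hap, phased = TRUE, ...)
}

# Brute-force LD oracle: enumerate the 2x2 gamete table and evaluate the
# textbook formulas without any shared code with the package's vectorised
# engine.
ld_oracle <- function(hap_i, hap_j) {
  nAB <- sum(hap_i == 1 & hap_j == 1)
  nAb <- sum(hap_i == 1 & hap_j == 0)
  naB <- sum(hap_i == 0 & hap_j == 1)
  nab <- sum(hap_i == 0 & hap_j == 0)
  m <- nAB + nAb + naB + nab
  pA <- (nAB + nAb) / m; pB <- (nAB + naB) / m
  D <- nAB / m - pA * pB
  r <- D / sqrt(pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D > 0) min(pA * (1 - pB), (1 - pA) * pB)
          else if (D < 0) min(pA * pB, (1 - pA) * (1 - pB)) else 1
  list(D = D, D_prime = if (D == 0) 0 else abs(D) / dmax, r = r, r2 = r^2)
}

# Full-enumeration HWE oracle: conditional probability of each heterozygote
# count given allele totals via the Wigginton-style recurrence from the
# distribution mode, then two-sided probability-mass summation by explicit
# looping.  Independent of the package's direct log-gamma evaluation.
hwe_oracle_pvals <- function(n_minor, n) {
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  k <- length(hets)
  probs <- numeric(k)
  # start at the (approximate) mode and fill outward with the recurrence
  # P(h+2)/P(h) = ... derived from the closed-form ratios
  mode_i <- which.min(abs(hets - n_minor * (2 * n - n_minor) / (2 * n)))
  probs[mode_i] <- 1
  if (mode_i < k)
    for (i in mode_i:(k - 1)) {
      h <- hets[i]
      hom_r <- (n_minor - h) / 2
      hom_c <- (2 * n - n_minor - h) / 2
      probs[i + 1] <- probs[i] * 4 * hom_r * hom_c / ((h + 2) * (h + 1))
    }
  if (mode_i > 1)
    for (i in mode_i:2) {
      h <- hets[i]
      hom_r <- (n_minor - h) / 2
      hom_c <- (2 * n - n_minor - h) / 2
      probs[i - 1] <- probs[i] * h * (h - 1) / (4 * (hom_r + 1) * (hom_c + 1))
    }
  probs <- probs / sum(probs)
  ord <- order(probs)
  cum <- cumsum(probs[ord])
  pvals <- pmin(cum[findInterval(probs * (1 + 1e-12), probs[ord])], 1)
  list(hets = hets, probs = probs, pvals = pvals)
}

# A deterministic toy with one bad individual and one monomorphic SNP:
# individual 2 misses 2/5 calls (fraction 0.4 > 0.05); SNP 5 is monomorphic.
qc_toy_dataset <- function() {
  calls <- rbind(c(0L, 1L, 2L, 1L, 0L),
                 c(NA, NA, 1L, 0L, 0L),
                 c(1L, 0L, 2L, 1L, 0L),
                 c(2L, 1L, 1L, 0L, 0L))
  make_dataset(calls)
}
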