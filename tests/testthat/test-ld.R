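# canonical worked example: 100 gametes with AB = 40, Ab = 10, aB = 10, ab = 40
hap_ex <- list(i = rep(c(1, 1, 0, 0), c(40, 10, 10, 40)),
               j = rep(c(1, 0, 1, 0), c(40, 10, 10, 40)))

test_that("gamete counting recovers haplotype and allele frequencies", {
  f <- haplotype_freqs_phased(hap_ex$i, hap_ex$j)
  expect_equal(f$freq_A, 0.5)
  expect_equal(f$freq_B, 0.5)
  expect_equal(f$freq_AB, 0.40)
  expect_equal(f$n_gametes, 100)

  all_AB <- haplotype_freqs_phased(rep(1, 8), rep(1, 8))
  expect_equal(all_AB$freq_AB, 1)
  expect_equal(all_AB$freq_A, 1)

  eq <- haplotype_freqs_phased(rep(c(1, 1, 0, 0), 25), rep(c(1, 0, 1, 0), 25))
  expect_equal(eq$freq_AB, eq$freq_A * eq$freq_B)
  expect_error(haplotype_freqs_phased(0:1, 0), "equal length")
})

test_that("LD statistics follow the textbook formulas", {
  ld <- ld_from_freqs(haplotype_freqs_phased(hap_ex$i, hap_ex$j))
  expect_equal(ld$D, 0.15)
  expect_equal(ld$r2, 0.36)
  expect_equal(ld$r, 0.6)
  expect_equal(ld$D_prime, 0.6)

  perfect <- ld_from_freqs(list(freq_A = 0.5, freq_a = 0.5, freq_B = 0.5,
                                freq_b = 0.5, freq_AB = 0.5))
  expect_equal(perfect$D, 0.25)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$D_prime, 1)

  indep <- ld_from_freqs(list(freq_A = 0.3, freq_a = 0.7, freq_B = 0.6,
                              freq_b = 0.4, freq_AB = 0.18))
  expect_equal(indep$D, 0)
  expect_equal(indep$r2, 0)
  expect_equal(indep$D_prime, 0)

  expect_error(ld_from_freqs(list(freq_A = 1, freq_a = 0, freq_B = 0.5,
                                  freq_b = 0.5, freq_AB = 0.5)),
               "monomorphic")
})

test_that("LD engine agrees with the 2x2 gamete-table oracle", {
  set.seed(101)
  checked <- 0
  for (rep in 1:200) {
    m <- 2 * sample(2:10, 1)
    hi <- rbinom(m, 1, runif(1, 0.2, 0.8))
    hj <- ifelse(rbinom(m, 1, 0.6) == 1, hi, rbinom(m, 1, 0.5))
    if (sum(hi) %in% c(0, m) || sum(hj) %in% c(0, m)) next
    got <- ld_from_freqs(haplotype_freqs_phased(hi, hj))
    want <- ld_oracle(hi, hj)
    for (f in c("D", "D_prime", "r", "r2"))
      expect_equal(got[[f]], want[[f]], tolerance = 1e-12)
    expect_lte(abs(got$r), got$D_prime + 1e-12)
    checked <- checked + 1
  }
  expect_gt(checked, 100)
})

test_that("unphased r is the dosage correlation and matches phased r in law", {
  d <- c(0, 1, 2, 1, 0, 2)
  expect_equal(r_unphased(d, d), 1)
  expect_equal(r_unphased(d, 2 - d), -1)
  expect_error(r_unphased(d, rep(1, 6)), "zero variance")
  expect_error(r_unphased(c(0, NA), c(NA, 1)), "at least two")

  # random pairing of the 40/10/10/40 gametes into 50 diploids: dosage r
  # estimates the same +0.6 correlation
  set.seed(7)
  rs <- replicate(40, {
    perm <- sample(100)
    hi <- hap_ex$i[perm]; hj <- hap_ex$j[perm]
    di <- hi[seq(1, 99, 2)] + hi[seq(2, 100, 2)]
    dj <- hj[seq(1, 99, 2)] + hj[seq(2, 100, 2)]
    r_unphased(di, dj)
  })
  expect_equal(mean(rs), 0.6, tolerance = 0.05)
})

test_that("finite-sample correction is linear in 1/n with beta = 1 or 2", {
  expect_equal(adjust_r2(0.34, 15, phased = FALSE), 0.34 - 1 / 15)
  expect_equal(adjust_r2(0.36, 10, phased = TRUE), 0.31)
  expect_equal(adjust_r2(0.05, 10, phased = FALSE), -0.05)
  expect_error(adjust_r2(0.1, 0), ">= 1")
  # phased correction is exactly half the unphased one
  r2 <- 0.2
  for (n in c(5, 12, 33))
    expect_equal(r2 - adjust_r2(r2, n, TRUE),
                 (r2 - adjust_r2(r2, n, FALSE)) / 2)
})

test_that("pairwise engine matches scalar statistics pair by pair", {
  set.seed(21)
  hap <- matrix(rbinom(40 * 8, 1, runif(8, 0.2, 0.8)), 40, 8, byrow = TRUE)
  ds <- make_phased_dataset(hap)
  pairs <- ld_pair_stats(ds, scheme = "all", max_bp = Inf)
  for (k in seq_len(nrow(pairs))) {
    i <- match(pairs$variant_i[k], ds$variants$id)
    j <- match(pairs$variant_j[k], ds$variants$id)
    want <- ld_oracle(hap[, i], hap[, j])
    expect_equal(pairs$r[k], want$r, tolerance = 1e-12)
    expect_equal(pairs$D_prime[k], want$D_prime, tolerance = 1e-12)
    expect_equal(pairs$r2_adj[k], want$r2 - 1 / (2 * 20), tolerance = 1e-12)
  }
  expect_true(all(pairs$r2 >= 0 & pairs$r2 <= 1))
  expect_true(all(pairs$D_prime >= 0 & pairs$D_prime <= 1 + 1e-12))
  expect_true(all(abs(pairs$r) <= pairs$D_prime + 1e-12))
})

test_that("permuting sample order changes no LD statistic", {
  set.seed(31)
  hap <- matrix(rbinom(30 * 6, 1, 0.4), 30, 6)
  ds <- make_phased_dataset(hap)
  perm <- sample(15)
  ds2 <- popld:::subset_dataset(ds, i = perm)
  p1 <- ld_pair_stats(ds, scheme = "all")
  p2 <- ld_pair_stats(ds2, scheme = "all")
  expect_equal(p1$r, p2$r)
  expect_equal(p1$D_prime, p2$D_prime)
})

test_that("adjacent summary reproduces the perfect-LD worked example", {
  # 3 equally spaced markers in perfect mutual LD, n = 20, phased
  one <- rep(c(1L, 0L), each = 20)
  hap <- cbind(one, one, one)
  ds <- make_phased_dataset(hap, pos_bp = c(10000L, 20000L, 30000L))
  s <- adjacent_ld_summary(ds)
  expect_equal(nrow(s), 2)  # chromosome row + genome-wide row
  expect_equal(s$mean_r2_adj, rep(1 - 1 / 40, 2))
  expect_equal(s$frac_r2_adj_gt_0.2, rep(1, 2))
  expect_equal(s$mean_D_prime, rep(1, 2))
  expect_equal(s$mean_spacing_kb, rep(10, 2))
  # single-chromosome dataset: genome-wide row equals the chromosome row
  expect_equal(unname(unlist(s[1, -1])), unname(unlist(s[2, -1])))
})

test_that("adjacent summary excludes and counts undefined pairs", {
  set.seed(41)
  hap <- matrix(rbinom(20 * 4, 1, 0.5), 20, 4)
  hap[, 2] <- 0L  # monomorphic locus kills pairs (1,2) and (2,3)
  ds <- make_phased_dataset(hap)
  s <- adjacent_ld_summary(ds)
  expect_equal(s$n_undefined[1], 2)
  expect_equal(s$n_pairs[1], 1)
})

test_that("LD decay bins pairs by physical distance", {
  set.seed(51)
  hap <- matrix(rbinom(30 * 3, 1, 0.5), 30, 3)
  ds <- make_phased_dataset(hap, pos_bp = c(100L, 150100L, 20000100L))
  dec <- ld_decay(ds, max_bp = 1e6, bin_bp = 1e5)
  expect_equal(nrow(dec), 10)
  # the single in-range pair (150 kb apart) sits in bin (100 kb, 200 kb]
  expect_equal(dec$n_pairs, c(0L, 1L, rep(0L, 8)))
  expect_true(is.na(dec$mean_r2[1]))
  expect_false(is.na(dec$mean_r2[2]))

  far <- make_phased_dataset(hap, pos_bp = c(1L, 2000001L, 4000001L))
  dec2 <- ld_decay(far, max_bp = 1e6, bin_bp = 1e5)
  expect_equal(sum(dec2$n_pairs), 0L)
  expect_error(ld_decay(ds, bin_bp = 0), "positive")
  expect_error(ld_decay(ds, max_bp = 1e4, bin_bp = 1e5), "bin wide")
})

test_that("null-LD calibration: unlinked loci give mean r2 near 1/(2n)", {
  # linkage-equilibrium phased data: burn-in 0 draws sites independently
  sim <- simulate_wf(sim_config(n_diploids = 50, n_chromosomes = 4,
                                n_loci_per_chromosome = 75,
                                chrom_length_morgans = 1,
                                burn_in_generations = 0,
                                sample_sizes = 50, seed = 61))
  ds <- sim$dataset
  hap <- ds$haplotypes
  # disjoint cross-chromosome pairs
  r2 <- vapply(seq_len(150), function(k) {
    i <- k; j <- 150 + k
    if (length(unique(hap[, i])) < 2 || length(unique(hap[, j])) < 2)
      return(NA_real_)
    ld_from_freqs(haplotype_freqs_phased(hap[, i], hap[, j]))$r2
  }, 0)
  r2 <- r2[!is.na(r2)]
  se <- sd(r2) / sqrt(length(r2))
  expect_lt(abs(mean(r2) - 1 / 100), 3 * se)
  expect_lt(abs(mean(adjust_r2(r2, 50, phased = TRUE))), 3 * se + 1e-4)
})

test_that("LD decay declines with distance in a drifting population", {
  sim <- simulate_wf(sim_config(n_loci_per_chromosome = 400, seed = 71))
  ds <- run_qc(sim$dataset)$datasets[[1]]
  dec <- ld_decay(ds, max_bp = 5e6, bin_bp = 1e6)
  expect_true(all(dec$n_pairs > 0))
  # monotone trend up to sampling noise: first bin clearly above the last
  expect_gt(dec$mean_r2_adj[1], dec$mean_r2_adj[5])
  fit <- stats::lm(dec$mean_r2_adj ~ seq_len(5))
  expect_lt(stats::coef(fit)[2], 0)
})
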