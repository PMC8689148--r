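test_that("simulator honours the shape contract and is seed-deterministic", {
  cfg <- sim_config(n_diploids = 50, n_chromosomes = 2,
                    n_loci_per_chromosome = 50, burn_in_generations = 10,
                    sample_sizes = 20, seed = 5)
  sim <- simulate_wf(cfg)
  ds <- sim$dataset
  expect_equal(nrow(ds$samples), 20)
  expect_equal(nrow(ds$variants), 100)
  expect_true(ds$phased)
  expect_equal(dim(ds$haplotypes), c(40, 100))
  expect_equal(length(sim$truth$true_ne_by_generation), 10)
  expect_true(all(sim$truth$true_ne_by_generation == 50))
  # bp positions equal Morgans x 1e8 (+1) at the 1 cM/Mb map
  expect_equal(sim$truth$map$pos_bp,
               as.integer(round(sim$truth$map$pos_morgans * 1e8)) + 1L)

  sim2 <- simulate_wf(cfg)
  expect_identical(ds$calls, sim2$dataset$calls)
  expect_identical(ds$haplotypes, sim2$dataset$haplotypes)

  sim3 <- simulate_wf(sim_config(n_diploids = 50, n_chromosomes = 2,
                                 n_loci_per_chromosome = 50,
                                 burn_in_generations = 10,
                                 sample_sizes = 20, seed = 6))
  expect_false(identical(ds$calls, sim3$dataset$calls))

  expect_error(sim_config(n_diploids = 10, sample_sizes = 20),
               "cannot sample")
})

test_that("simulation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(simulate_wf(sim_config(n_diploids = 20,
                                   n_loci_per_chromosome = 10,
                                   burn_in_generations = 2,
                                   sample_sizes = 5, seed = 1)))
  expect_identical(.Random.seed, before)
})

test_that("an Ne schedule changes the census at the stated generations", {
  cfg <- sim_config(n_diploids = 40, ne_schedule = list(c(6, 20), c(9, 10)),
                    n_loci_per_chromosome = 10, burn_in_generations = 10,
                    sample_sizes = 10, seed = 8)
  sim <- simulate_wf(cfg)
  expect_equal(sim$truth$true_ne_by_generation,
               c(rep(40L, 5), rep(20L, 3), rep(10L, 2)))
})

test_that("zero genetic length means whole haplotypes are co-inherited", {
  cfg <- sim_config(n_diploids = 30, chrom_length_morgans = 0,
                    n_loci_per_chromosome = 40, burn_in_generations = 1,
                    sample_sizes = 30, seed = 13)
  sim <- simulate_wf(cfg)
  # after one generation every gamete must equal one of the founder
  # haplotypes exactly (no recombination can mix them)
  founders <- popld:::with_sim_seed(13, {
    popld:::sim_init_haplotypes(cfg, popld:::sim_marker_map(cfg))
  })
  fkeys <- apply(founders, 1, paste, collapse = "")
  gkeys <- apply(sim$dataset$haplotypes, 1, paste, collapse = "")
  expect_true(all(gkeys %in% fkeys))
})

test_that("drift variance scales like p(1-p)/(2N) per generation", {
  # many unlinked loci (one per chromosome pair), few generations
  g <- 5
  reps <- lapply(1:4, function(s) {
    cfg <- sim_config(n_diploids = 100, n_chromosomes = 60,
                      n_loci_per_chromosome = 2, chrom_length_morgans = 5,
                      init_maf_range = c(0.45, 0.5),
                      burn_in_generations = g, sample_sizes = 100,
                      seed = 200 + s)
    sim <- simulate_wf(cfg)
    colMeans(sim$dataset$haplotypes)
  })
  p1 <- unlist(reps)
  # E[var of freq change over g generations] ~ p0 (1 - p0) g / (2N)
  expected <- 0.475 * 0.525 * g / 200
  ratio <- stats::var(p1) / expected
  expect_gt(ratio, 0.6)
  expect_lt(ratio, 1.7)
})

test_that("cross-chromosome LD is at the sampling floor", {
  sim <- simulate_wf(sim_config(n_diploids = 100, n_chromosomes = 2,
                                n_loci_per_chromosome = 40,
                                chrom_length_morgans = 1,
                                burn_in_generations = 50,
                                sample_sizes = 50, seed = 17))
  hap <- sim$dataset$haplotypes
  poly <- apply(hap, 2, function(h) length(unique(h)) == 2)
  i_set <- which(poly[1:40]); j_set <- 40 + which(poly[41:80])
  r2a <- outer(i_set, j_set, Vectorize(function(i, j)
    ld_from_freqs(haplotype_freqs_phased(hap[, i], hap[, j]))$r2)) -
    1 / (2 * 50)
  se <- stats::sd(r2a) / sqrt(length(r2a))
  # population-level background LD ~ 1/(3N) remains; allow for it
  expect_lt(abs(mean(r2a)), 1 / (3 * 100) + 3 * se)
})

test_that("split simulation is deterministic with identical maps", {
  cfg <- sim_config(n_diploids = 40, n_loci_per_chromosome = 30,
                    chrom_length_morgans = 0.5, burn_in_generations = 10,
                    split_generations = 5, sample_sizes = c(10, 15),
                    seed = 19)
  s1 <- simulate_split(cfg)
  s2 <- simulate_split(cfg)
  expect_identical(s1$dataset_a$calls, s2$dataset_a$calls)
  expect_identical(s1$dataset_b$calls, s2$dataset_b$calls)
  expect_equal(nrow(s1$dataset_a$samples), 10)
  expect_equal(nrow(s1$dataset_b$samples), 15)
  expect_identical(s1$dataset_a$variants, s1$dataset_b$variants)
  expect_false(identical(s1$dataset_a$calls[1:10, ],
                         s1$dataset_b$calls[1:10, ]))
  expect_error(simulate_split(sim_config()), "split_generations")
})

test_that("fixture writers round-trip through every supported format", {
  sim <- simulate_wf(sim_config(n_diploids = 20, n_loci_per_chromosome = 12,
                                n_chromosomes = 2, burn_in_generations = 5,
                                sample_sizes = 8, seed = 23))
  ds <- sim$dataset
  dir <- withr::local_tempdir()

  write_fixture(ds, "plink_text", file.path(dir, "t"))
  expect_equal(unname(read_plink(file.path(dir, "t"))$calls),
               unname(ds$calls))

  write_fixture(ds, "plink_binary", file.path(dir, "b"))
  expect_equal(unname(read_plink(file.path(dir, "b"))$calls),
               unname(ds$calls))

  write_fixture(ds, "vcf", file.path(dir, "v.vcf"))
  back <- read_vcf(file.path(dir, "v.vcf"))
  expect_equal(unname(back$calls), unname(ds$calls))
  expect_true(back$phased)

  expect_error(write_fixture(ds, "vcf", file.path(dir, "no/dir/x.vcf")),
               "no such directory")
})

test_that("text PLINK output matches a hand-constructed reference", {
  ds <- make_dataset(rbind(c(0L, 1L), c(2L, NA)), pos_bp = c(10L, 20L))
  prefix <- file.path(withr::local_tempdir(), "hand")
  write_fixture(ds, "plink_text", prefix)
  expect_identical(readLines(paste0(prefix, ".ped")),
                   c("popA\ti1\t0\t0\t0\t-9\tA\tA\tA\tC",
                     "popA\ti2\t0\t0\t0\t-9\tC\tC\t0\t0"))
  expect_identical(readLines(paste0(prefix, ".map")),
                   c("1\tm1\t0\t10", "1\tm2\t0\t20"))
})
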