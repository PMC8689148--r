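#' Wright-Fisher simulation configuration
#'
#' Parameters of the forward-time diploid Wright-Fisher simulator used to
#' generate genotype data with known effective-size history and
#' recombination-driven LD.  Defaults describe the calibration population
#' used throughout the package's property tests: a census of 100 diploids
#' evolved for 400 generations on a single 1-Morgan chromosome carrying 1000
#' evenly spaced loci (one per 100 kb at the 1 cM/Mb map) initialised at allele frequencies uniform in
#' (0.1, 0.5), with 40 individuals sampled at the end.  Physical positions
#' are derived from genetic positions at exactly 1 cM = 1 Mb, so the
#' pipeline's default map is exact on simulated data.
#'
#' @param n_diploids census size per generation (the drift Ne proxy).
#' @param ne_schedule optional list of `c(generation, size)` change points;
#'   from each listed generation (1-based) onward the census takes that size.
#' @param n_chromosomes number of independently segregating chromosomes.
#' @param chrom_length_morgans genetic length of each chromosome; 0 gives
#'   complete co-inheritance within a chromosome.
#' @param n_loci_per_chromosome evenly spaced loci per chromosome.
#' @param init_maf_range range (within (0, 0.5]) of the uniform initial
#'   alternate-allele frequencies.
#' @param burn_in_generations generations evolved before sampling.
#' @param split_generations for [simulate_split()]: generations each daughter
#'   population evolves independently after the ancestral burn-in.
#' @param sample_sizes diploid individuals sampled per output population.
#' @param seed integer seed; every run is fully reproducible from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_diploids = 100, ne_schedule = NULL,
                       n_chromosomes = 1, chrom_length_morgans = 1,
                       n_loci_per_chromosome = 1000,
                       init_maf_range = c(0.1, 0.5),
                       burn_in_generations = 400,
                       split_generations = NULL,
                       sample_sizes = 40, seed = 1) {
  stopifnot(n_diploids >= 1, n_chromosomes >= 1,
            n_loci_per_chromosome >= 1, chrom_length_morgans >= 0,
            burn_in_generations >= 0, all(sample_sizes >= 1),
            length(init_maf_range) == 2,
            init_maf_range[1] > 0, init_maf_range[2] <= 0.5,
            init_maf_range[1] <= init_maf_range[2])
  if (any(sample_sizes > n_diploids))
    stop("cannot sample more individuals than the census size")
  if (!is.null(split_generations) && split_generations < 0)
    stop("split_generations must be >= 0")
  structure(list(n_diploids = as.integer(n_diploids),
                 ne_schedule = ne_schedule,
                 n_chromosomes = as.integer(n_chromosomes),
                 chrom_length_morgans = chrom_length_morgans,
                 n_loci_per_chromosome = as.integer(n_loci_per_chromosome),
                 init_maf_range = init_maf_range,
                 burn_in_generations = as.integer(burn_in_generations),
                 split_generations = if (is.null(split_generations)) NULL
                                     else as.integer(split_generations),
                 sample_sizes = as.integer(sample_sizes),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# evaluate RNG-dependent code under a seed, restoring the caller's RNG state
with_sim_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# marker map: loci evenly spaced along each chromosome
sim_marker_map <- function(config) {
  L <- config$n_loci_per_chromosome
  len <- config$chrom_length_morgans
  pos_m <- if (L == 1) len / 2 else seq(0, len, length.out = L)
  do.call(rbind, lapply(seq_len(config$n_chromosomes), function(cc) {
    bp <- if (len > 0) as.integer(round(pos_m * 1e8)) + 1L else seq_len(L)
    data.frame(chrom = as.character(cc), index = seq_len(L),
               pos_morgans = pos_m, pos_bp = bp,
               stringsAsFactors = FALSE)
  }))
}

# one transmitted gamete from parent haplotypes h1, h2 over one chromosome
recombine_gamete <- function(h1, h2, pos_m, len_m) {
  k <- if (len_m > 0) stats::rpois(1L, len_m) else 0L
  start <- stats::runif(1) < 0.5
  if (k == 0L) return(if (start) h1 else h2)
  xo <- sort(stats::runif(k, 0, len_m))
  seg <- findInterval(pos_m, xo)
  use1 <- xor(seg %% 2L == 0L, !start)
  out <- h2
  out[use1] <- h1[use1]
  out
}

# evolve haplotype matrix H (2N x L) for `sizes` (census per generation)
evolve_population <- function(H, sizes, chrom_index, pos_m, len_m) {
  chrom_idx <- split(seq_along(chrom_index), chrom_index)
  pos_by_chrom <- split(pos_m, chrom_index)
  for (g in seq_along(sizes)) {
    N <- nrow(H) %/% 2L
    N_next <- sizes[g]
    out <- matrix(0L, 2L * N_next, ncol(H))
    parents <- cbind(sample.int(N, N_next, replace = TRUE),
                     sample.int(N, N_next, replace = TRUE))
    for (i in seq_len(N_next)) {
      for (side in 1:2) {
        p <- parents[i, side]
        h1 <- H[2L * p - 1L, ]; h2 <- H[2L * p, ]
        g_row <- 2L * i - 2L + side
        for (cc in seq_along(chrom_idx)) {
          idx <- chrom_idx[[cc]]
          out[g_row, idx] <- recombine_gamete(h1[idx], h2[idx],
                                              pos_by_chrom[[cc]], len_m)
        }
      }
    }
    H <- out
  }
  H
}

sim_init_haplotypes <- function(config, map) {
  L <- nrow(map)
  n <- config$n_diploids
  f <- stats::runif(L, config$init_maf_range[1], config$init_maf_range[2])
  matrix(stats::rbinom(2L * n * L, 1L, rep(f, each = 2L * n)), 2L * n, L)
}

sim_sizes <- function(config) {
  sizes <- rep(config$n_diploids, config$burn_in_generations)
  if (!is.null(config$ne_schedule))
    for (ch in config$ne_schedule) {
      g <- ch[1]
      if (g >= 1 && g <= length(sizes)) sizes[g:length(sizes)] <- ch[2]
    }
  as.integer(sizes)
}

haplotypes_to_dataset <- function(H, sampled, map, population) {
  hrows <- as.vector(rbind(2L * sampled - 1L, 2L * sampled))
  hap <- H[hrows, , drop = FALSE]
  calls <- hap[seq(1, nrow(hap), 2), , drop = FALSE] +
    hap[seq(2, nrow(hap), 2), , drop = FALSE]
  variants <- data.frame(
    id = sprintf("snp%s_%d", map$chrom, map$index),
    chrom = map$chrom, pos_bp = map$pos_bp,
    ref = "A", alt = "C", stringsAsFactors = FALSE)
  samples <- data.frame(id = sprintf("%s_%03d", population,
                                     seq_along(sampled)),
                        population = population, stringsAsFactors = FALSE)
  genotype_dataset(calls, variants, samples, haplotypes = hap, phased = TRUE,
                   sort_variants = FALSE)
}

#' Forward Wright-Fisher simulation of one population
#'
#' Discrete generations of random mating among `n_diploids` parents: each
#' offspring draws two parents uniformly (with replacement) and receives one
#' recombined gamete from each, with crossover counts Poisson in the
#' chromosome's genetic length and crossover positions uniform.  Initial
#' haplotypes are drawn site-independently at frequencies uniform in
#' `init_maf_range`; no new mutations arise, so all LD is generated by drift
#' and recombination from the standing variation.  After the burn-in,
#' `sample_sizes[1]` individuals are drawn without replacement.  Monomorphic
#' sites are retained (QC removes them downstream).
#'
#' @param config a [sim_config()].
#' @return list with `dataset` (a phased [genotype_dataset()]) and `truth`
#'   (census size per generation, the marker map in bp and Morgans, the seed).
#' @examples
#' sim <- simulate_wf(sim_config(n_diploids = 30, n_loci_per_chromosome = 20,
#'                               burn_in_generations = 5, sample_sizes = 10,
#'                               seed = 42))
#' sim$dataset
#' @export
simulate_wf <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  map <- sim_marker_map(config)
  sizes <- sim_sizes(config)
  with_sim_seed(config$seed, {
    H <- sim_init_haplotypes(config, map)
    H <- evolve_population(H, sizes, map$chrom, map$pos_morgans,
                           config$chrom_length_morgans)
    N_final <- if (length(sizes)) sizes[length(sizes)] else config$n_diploids
    n_samp <- config$sample_sizes[1]
    if (n_samp > N_final)
      stop("cannot sample ", n_samp, " individuals from a final census of ",
           N_final)
    sampled <- sort(sample.int(N_final, n_samp))
    ds <- haplotypes_to_dataset(H, sampled, map, "sim")
    truth <- list(true_ne_by_generation = sizes,
                  split_generations = NULL,
                  map = map, seed = config$seed)
    list(dataset = ds, truth = truth)
  })
}

#' Simulate two populations splitting from a common ancestor
#'
#' One ancestral population is evolved for `burn_in_generations`, duplicated,
#' and each copy evolved independently for `split_generations` more before
#' sampling.  With `split_generations = 0` the two outputs are the *same*
#' sample drawn from the ancestral generation (so phase persistence is 1 by
#' construction).  The marker maps are identical.
#'
#' @param config a [sim_config()] with `split_generations` set;
#'   `sample_sizes` may give one size per population (recycled if scalar).
#' @return list with `dataset_a`, `dataset_b` and `truth`.
#' @export
simulate_split <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(config$split_generations))
    stop("split_generations must be set for simulate_split()")
  map <- sim_marker_map(config)
  sizes <- sim_sizes(config)
  n_samp <- rep(config$sample_sizes, length.out = 2)
  split_g <- config$split_generations
  with_sim_seed(config$seed, {
    H <- sim_init_haplotypes(config, map)
    H <- evolve_population(H, sizes, map$chrom, map$pos_morgans,
                           config$chrom_length_morgans)
    N_anc <- config$n_diploids
    if (split_g == 0) {
      sampled <- sort(sample.int(N_anc, n_samp[1]))
      ds_a <- haplotypes_to_dataset(H, sampled, map, "popA")
      ds_b <- haplotypes_to_dataset(H, sampled, map, "popB")
    } else {
      post <- rep(N_anc, split_g)
      Ha <- evolve_population(H, post, map$chrom, map$pos_morgans,
                              config$chrom_length_morgans)
      Hb <- evolve_population(H, post, map$chrom, map$pos_morgans,
                              config$chrom_length_morgans)
      ds_a <- haplotypes_to_dataset(Ha, sort(sample.int(N_anc, n_samp[1])),
                                    map, "popA")
      ds_b <- haplotypes_to_dataset(Hb, sort(sample.int(N_anc, n_samp[2])),
                                    map, "popB")
    }
    truth <- list(true_ne_by_generation = sizes,
                  split_generations = split_g,
                  map = map, seed = config$seed)
    list(dataset_a = ds_a, dataset_b = ds_b, truth = truth)
  })
}
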