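---
title: "Methods: LD decay, phase persistence and LD-based Ne"
author: "popld"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: LD decay, phase persistence and LD-based Ne}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(popld)
```

## The problem

Medium-density SNP arrays are routinely used to characterise small, often
endangered, livestock populations — a few dozen animals per breed genotyped
at 50–90 K markers.  Three linked questions drive such studies: how much
linkage disequilibrium (LD) the array captures between neighbouring markers
(which decides whether genomic selection and GWAS are feasible), whether the
*phase* of that LD is shared between related populations (which decides
whether marker effects estimated in one breed transfer to another), and what
the trajectory of effective population size (Ne) looks like over past
generations (which decides how urgent conservation measures are).  `popld`
implements this entire workflow as reusable, tested R functions, together
with a forward simulator that generates data with known truth so every stage
can be validated end to end.

## Statistical model

### Pairwise LD

For two biallelic loci with alleles A/a and B/b, writing `freq AB` for the
frequency of the AB gamete,

* `D = freq_AB − freq_A · freq_B`
* `r = D / sqrt(freq_A · freq_a · freq_B · freq_b)`, and `r² = r²`
* `D′ = |D| / D_max`, with `D_max = min(freq_A·freq_b, freq_a·freq_B)` for
  `D > 0` and `min(freq_A·freq_B, freq_a·freq_b)` for `D < 0` (Lewontin's
  normalisation; `D′ = 0` when `D = 0`).

With phased haplotypes these are computed by direct gamete counting
(`haplotype_freqs_phased()` + `ld_from_freqs()`, vectorised per chromosome
in `ld_pair_stats()`).  Without phase, `r` is the product-moment correlation
of the two dosage vectors (`r_unphased()`); `D` and `D′` are genuinely
gametic quantities and are reported as `NA` on that path.

### The finite-sample correction

`r²` estimated from `n` individuals is inflated by sampling: under no LD its
expectation is approximately `1/(βn)` with `β = 2` when the gametic phase is
known and `β = 1` when it is not.  `adjust_r2()` subtracts this term:
`r²_adj = r² − 1/(βn)`.  At `n = 15` with unknown phase the correction is
`1/15 ≈ 0.07` — sizeable relative to typical adjacent-marker LD of 0.2–0.35,
which is why small-sample studies must apply it.  Negative adjusted values
can occur at long distances and are deliberately *not* clamped: decay-curve
bins with non-positive means are skipped (and counted) rather than silently
truncated, because clamping would bias Ne upward exactly where the signal is
weakest.

### LD decay and Ne

`ld_decay()` groups all intra-chromosomal pairs up to 15 Mb into 100 kb bins
(both defaults configurable) and reports the unweighted mean of raw and
adjusted `r²` per bin.  `ne_trajectory()` converts each bin into one point
of an Ne history through three steps:

1. physical → genetic distance at a constant rate (default 1 cM per Mb, the
   usual coarse assumption for cattle-mapped genomes): `c = bp · 1e-8`;
2. the distance dates the estimate: `T = 1/(2c)` generations ago;
3. Sved's drift-recombination expectation `E[r²] = 1/(1 + 4 Ne c)` is
   inverted: `Ne = (1/(4c)) · (1/r²_adj − 1)`.

The bin *midpoint* defines `c` by default — it is deterministic and does not
depend on which pairs happened to survive QC; `distance = "mean"` switches
to the mean observed pair separation.  Note that at fixed `r²` the formula
is decreasing in `c`: distant bins (small `T`, recent past) translate the
same LD into smaller Ne.

`expected_diversity_loss()` complements the trajectory with the standard
compounding of heterozygosity loss, `100·(1 − (1 − 1/(2Ne))^g)` percent over
`g` generations.  At `Ne = 25, 50, 125` and `g = 10` this gives 18.3%, 9.6%
and 3.9% — the familiar conservation-genetics reference points (tabulated
values for very large Ne are sometimes quoted as 1.6% and 0.8% at Ne = 250
and 500; the compounding formula gives 1.98% and 1.00%, and this package
reports the formula).

### Persistence of LD phase

For two populations sharing a marker panel, `pldp()` computes the *signed*
r (the square root of `r²` carrying the sign of `D`, or of the dosage
correlation when phase is unknown) for every shared pair, and per distance
bin reports

```
r_bin = Σ (r_A − r̄_A)(r_B − r̄_B) / (S_A · S_B)
```

the product-moment correlation of the two populations' signed-r vectors.
Signed roots matter: with unsigned `|r|` the statistic could never fall to
zero at long range, where related breeds genuinely lose phase agreement.
Using signed r requires the two datasets to count the same allele at every
marker, which is what `align_alleles()` enforces (complementing dosages
where ref/alt are swapped, and flagging A/T and C/G markers whose strand
cannot be resolved from the allele pair alone).  Bins with fewer than three
usable pairs report `NA` rather than a meaningless two-point correlation,
and pairs monomorphic in either population are dropped, not zero-filled.

## Quality control

`run_qc()` reproduces the canonical two-step editing of multi-population
array data, in this order within each population: individuals with > 5%
missing calls, then SNPs with > 5% missing calls, then SNPs failing the
Hardy-Weinberg exact test at p ≤ 5.7e-7 (a Bonferroni-style cutoff for
~90 K markers), then monomorphic SNPs and SNPs with MAF < 5%; finally all
populations are restricted to their common marker set.  Filtering before
merging matters: a SNP monomorphic in one breed must not enter the shared
panel merely because it segregates elsewhere.

Decisions that were genuinely open:

* **HWE test.**  The exact conditional test with probability-mass ordering
  is the field standard and is what `hwe_exact_test()` implements (a mid-p
  variant is available, off by default).  The implementation evaluates the
  conditional distribution of the heterozygote count directly through
  log-gamma terms; the test suite checks it against an independent
  recurrence-based enumeration for every allele count with up to 200
  genotyped individuals at 1e-12.
* **HWE scope.**  Default is per population (`hwe_scope = "per_population"`),
  consistent with the per-population MAF filter; a merged-scope option
  exists because genotyping artefacts are sometimes better detected on the
  pooled sample.
* **Imputation.**  Residual missing calls after filtering are mode-imputed
  per population (ties resolved to the reference homozygote) so downstream
  LD code can assume complete data.  This is a deliberate simplification —
  haplotype-based imputation is out of scope — and simulated data are
  complete, so tests do not depend on it.

## The simulator

`simulate_wf()` is a discrete-generation diploid Wright-Fisher engine on
phased haplotypes: each offspring draws two parents uniformly with
replacement; each transmitted gamete recombines with a Poisson number of
crossovers (mean = chromosome length in Morgans) at uniform positions.
Initial haplotypes are drawn site-independently with allele frequencies
uniform in `init_maf_range`, and **no new mutations** arise: all LD is
generated by drift and recombination from standing variation.  This is
sufficient to put Sved's relation to the test without introducing a
mutation-rate nuisance parameter, at the cost of a slow loss of segregating
sites over the burn-in.  `simulate_split()` duplicates the population after
the burn-in and evolves the copies independently, giving the
shared-ancestry structure that phase-persistence analysis assumes; a split
of zero generations returns the *same* sample twice, the degenerate case in
which phase persistence is exactly 1.

Default configuration (and why):

| parameter | default | rationale |
|---|---|---|
| `n_diploids` | 100 | census = Ne proxy; small enough to drift visibly, large enough for stable LD means |
| `chrom_length_morgans` | 1 | one full Morgan spans T = 1/(2c) from thousands of generations down to < 1 |
| `n_loci_per_chromosome` | 1000 | one marker per 100 kb at 1 cM/Mb — one per decay bin, array-like density at desk scale |
| `init_maf_range` | (0.1, 0.5) | post-QC arrays carry MAF ≥ 0.05; starting higher leaves sites segregating after the burn-in |
| `burn_in_generations` | 400 | ≥ 2N·2 generations, long enough for drift-recombination equilibrium at the distances analysed |
| `sample_sizes` | 40 | a realistic "large" sample for livestock studies of this kind |

Physical positions are derived from genetic positions at exactly 1 cM = 1 Mb,
so the package's default map introduces no conversion error on simulated
data.  All randomness flows from a single integer seed, and the caller's RNG
stream is restored afterwards.

What the simulator does *not* emulate — and therefore what passing tests do
not certify about real data: mutation, selection, migration and admixture,
sex chromosomes and male hemizygosity, overlapping generations, genotyping
error, and non-uniform recombination maps.  Real array data also carry
ascertainment bias in the MAF spectrum that a uniform initial distribution
only caricatures.

## Numerical choices and degenerate inputs

* Monomorphic loci make `r` undefined; pairs containing one are skipped and
  counted everywhere (`n_skipped` / `n_undefined` fields), never treated as
  `r² = 0`.
* Decay bins are half-open `(k·bin, (k+1)·bin]`, so each pair lands in
  exactly one bin and zero distances (co-located markers) are excluded by
  the uniqueness-of-position invariant.
* Identical signed-r vectors short-circuit to a phase correlation of
  exactly 1, avoiding a 1-ulp wobble in the self-comparison case.
* The exact-test p-value sums all configurations with probability ≤ that of
  the observed count, with a `1 + 1e-12` relative tolerance on the
  comparison to absorb floating-point ties.
* Chromosome labels are strings; `"30"` and `"X"` both denote the X
  chromosome by default (`options(popld.x_chromosomes = ...)`), matching
  arrays mapped to the bovine assembly, and an `autosomes_only` flag
  excludes X pairs where male hemizygosity would distort LD.
* Text PLINK carries no allele metadata, so the reader assigns ref/alt
  alphabetically; dosages round-trip exactly whenever ref sorts before alt
  (always true for simulator output).  Binary PLINK and VCF are lossless.

## Problem sizes used in the shipped tests

The validation suites run the simulator at a census of 100 diploids, one
1-Morgan chromosome of 250–1000 loci, 100–400 burn-in generations and
samples of 30–50 — large enough for the asymptotic expectations
(`E[r²] ≈ 1/(2n)` at linkage equilibrium; `E[r²_adj] ≈ 1/(1 + 4Nc)`) to
hold within Monte-Carlo tolerance, and small enough that the whole suite
runs in about a minute.  Parameter recovery is judged on the median Ne over
bins dated `T ∈ [10, 100]` generations across five replicate seeds, with a
factor-of-two acceptance band: LD-based Ne is an order-of-magnitude
instrument, not a precision estimator.

## Known limitations

* Sved's relation assumes a closed population at drift-recombination
  equilibrium; migration and admixture bias Ne upward, strong recent
  selection biases it downward.  The trajectory should be read as a smooth
  summary, not generation-resolved history.
* The `T = 1/(2c)` dating is a heuristic; adjacent bins share pairs of
  similar distance, so trajectory points are not independent.
* With `β` mis-specified (phase assumed known when it was imputed), the
  correction is off by a factor of two — material when `n < 25`.  The
  `phased` flag is therefore explicit in every LD function rather than
  silently inherited.
* Mode imputation attenuates LD slightly relative to haplotype-aware
  imputation; with the default 5% missingness ceiling the effect is small.
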