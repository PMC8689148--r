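# popld

Linkage disequilibrium (LD) analysis for SNP-array genotypes from small,
structured populations — the situation typical of local livestock breeds,
where a few dozen animals per population are genotyped on a medium-density
array and three questions matter:

1. **How much LD does the array capture?**  Mean adjusted r² between
   adjacent markers decides whether the panel supports GWAS (r² > 0.3 is the
   usual bar) and genomic selection (r² > 0.2).
2. **Does LD phase persist across populations?**  If the correlation of
   signed r between two breeds stays near 1 at short distances, marker
   effects estimated in one breed transfer to the other.
3. **What has effective population size (Ne) been doing?**  LD at
   recombination distance *c* Morgans reflects Ne roughly *T = 1/(2c)*
   generations ago, so a distance-binned decay curve unrolls into an Ne
   trajectory.

## The statistics at the core

For a pair of biallelic loci with gamete frequency *f(AB)*:

```
D  = f(AB) − f(A) f(B)
r  = D / sqrt(f(A) f(a) f(B) f(b)),   r² = r²
D′ = |D| / Dmax,  Dmax = min(f(A)f(b), f(a)f(B)) if D > 0
                         min(f(A)f(B), f(a)f(b)) if D < 0
```

Because r² from *n* individuals is inflated by sampling, every summary uses
the corrected value **r²adj = r² − 1/(βn)** (β = 2 with known gametic phase,
β = 1 without).  Ne comes from Sved's relation applied per distance bin:

```
Ne = (1 / 4c) (1 / r²adj − 1),   T = 1 / (2c),   c = bp · 1e-8  (1 cM ≈ 1 Mb)
```

Phase persistence between populations A and B is the per-bin product-moment
correlation of their signed-r vectors over shared SNP pairs.

The package also ships a seedable Wright–Fisher forward simulator
(recombination, arbitrary Ne schedules, population splits) so the whole
pipeline is testable against known truth, plus readers/writers for binary
PLINK, text PLINK and VCF, and the standard per-population QC
(call rate, MAF, Hardy–Weinberg exact test, common-marker merge).

## Worked example

Two populations split 20 generations ago from a common ancestor of 100
diploids, 30 animals sampled from each:

```r
library(popld)
sim <- simulate_split(sim_config(n_diploids = 100, n_loci_per_chromosome = 250,
                                 chrom_length_morgans = 0.25,
                                 burn_in_generations = 100,
                                 split_generations = 20,
                                 sample_sizes = 30, seed = 42))
qc <- run_qc(list(sim$dataset_a, sim$dataset_b))
qc$report
#> Genotype QC report
#>   individuals removed (call rate): 0
#>   SNPs removed (call rate):        0
#>   SNPs removed (HWE):              0
#>   SNPs removed (MAF/monomorphic):  popA=94, popB=94
#>   SNPs after merge:                141
#>   total genotyping rate:           1
```

Drift over 100+20 generations fixed or rarefied 94 of the 250 simulated
loci per population; 141 markers segregate in both and form the shared
panel.  LD decay and the Ne trajectory for population A:

```r
a <- qc$datasets[[1]]
dec <- ld_decay(a, max_bp = 2e6, bin_bp = 1e5)
head(ne_trajectory(dec), 4)
#>   c_morgans T_generations n_pairs mean_r2_adj        ne
#> 1    0.0195      25.64103      68   0.1376334  80.32921
#> 2    0.0185      27.02703      75   0.1126699 106.42542
#> 3    0.0175      28.57143      75   0.1451839  84.11166
#> 4    0.0165      30.30303      82   0.1465426  88.24176
```

The estimates hover around the true census of 100 — LD-based Ne is an
order-of-magnitude instrument.  Phase persistence between the two daughters
stays high at short range and erodes with distance, as 20 generations of
independent drift predict:

```r
pldp(a, qc$datasets[[2]], max_bp = 1e6)
#> Persistence of LD phase: popA vs popB (all pairs, phased)
#>            bin n_pairs correlation
#> 2   100-200 kb      78      0.9475
#> 3   200-300 kb      85      0.8699
#> ...
#> 10 900-1000 kb      78      0.7761
```

(The 0–100 kb bin is empty here because the simulated markers sit exactly
100 kb apart.)  Real filesets enter the same way through `read_plink()` /
`read_vcf()`, and `run_ld_pipeline()` drives all stages from one
configuration object, writing one self-describing TSV per stage.

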