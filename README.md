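# phylotrends

Phylostratigraphy of protein-domain properties on time-calibrated species
trees, for molecular evolution researchers who want to ask: *do sequence
properties trend with evolutionary age, and are those trends universal or
lineage-specific?*

The package implements a domain-based phylostratigraphy pipeline end to
end: per-sequence property metrics, transmembrane classification,
quality/contamination filtering, time-tree dating with ancient-strata
rules, homology aggregation, and the trend statistics — plus a synthetic
data generator that plants known trends so every stage can be validated
without any external download.

## The statistics at its core

**Hydrophobic clustering (normalized index of dispersion).** Residues are
encoded ±1 (hydrophobic L, I, V, F, M, W = +1; other standard residues
−1). For block size *s* = 6 and truncated length *N* = *s*⌊*L*/*s*⌋, with
block sums σ<sub>k</sub> totalling *M*,

ψ = (s/N) Σ<sub>k</sub> (σ<sub>k</sub> − sM/N)² / K,  K = s(N² − M²)/(N² − N) · (1 − s/N),

averaged over *p* = *L* mod 6 reading frames. K is exactly the block-sum
variance under a random arrangement, so ψ has expectation 1 for randomly
interspersed hydrophobic residues, ψ > 1 means clustering, ψ < 1
over-dispersion.

**Dating.** A domain family is dated halfway between the MRCA of its
carrier species and the previous node; families older than the tree are
pinned at printed calibrations (LUCA 4090 MY; post-LUCA 3145 MY;
first-eukaryote via the Excavata outgroup 2230 MY), with LECA (2101 MY) and
the plant split (1496 MY) cutting lineage subsets.

**Contamination test.** Dollo parsimony counts losses as maximal absent
subtrees below the MRCA; a Monte-Carlo null draws the same number of
carriers uniformly at random, and families with z > −2 (indistinguishable
from random scatter) are rejected.

**Trends.** One datapoint per homology group (the mean over all instances),
ordinary least squares of the raw property on age in billions of years,
per-amino-acid slope profiles, Spearman/Pearson profile correlations with
Fisher-transform errors, consensus recruitment-order recomputation, and
minimum-age sweeps.

## Worked example

Simulate a small dataset with planted trends (animal-only disorder trend,
universal clustering trend, injected contaminants and filter decoys), run
the whole pipeline, and read the slope table:

```r
library(phylotrends)

sim <- simulate_dataset(sim_config(
  seed = 42, n_animal = 10, n_plant = 6, n_fungi = 4, n_excavata = 2,
  pfam_counts = c(luca = 10, post_luca = 12, feca = 12, basal = 12,
                  recent_animal = 60, recent_plant = 24, recent_fungi = 8),
  n_contaminants = 10))
sim
#> <phylostrat_sim> 22 species, 172 pfams (10 contaminants, 24 decoys), 1594 genes, seed 42

res <- run_phylostrat(sim, n_reps = 500, seed = 42)
res
#> <phylostrat_result> 142/172 pfams kept, 139 datapoints
#> # A tibble: 8 × 9
#>   property subset         slope      se r_squared p_value     n  ci_low  ci_high
#>   <chr>    <chr>          <dbl>   <dbl>     <dbl>   <dbl> <int>   <dbl>    <dbl>
#> 1 mean_isd all         -0.0112  0.00223   0.169   1.71e-6   126 -0.0156 -0.00679
#> 2 psi      all         -0.0522  0.0127    0.120   7.28e-5   126 -0.0774 -0.0270
#> 3 mean_isd ancient      0.00104 0.00572   0.00110 8.57e-1    32 -0.0106  0.0127
#> 4 psi      ancient     -0.110   0.0235    0.421   5.93e-5    32 -0.158  -0.0618
#> 5 mean_isd recent_ani… -0.0509  0.0175    0.135   5.38e-3    56 -0.0860 -0.0157
#> 6 psi      recent_ani… -0.164   0.103     0.0448  1.17e-1    56 -0.370   0.0425
#> 7 mean_isd recent_pla…  0.0137  0.0207    0.0226  5.15e-1    21 -0.0297  0.0571
#> 8 psi      recent_pla… -0.0336  0.146     0.00279 8.20e-1    21 -0.338   0.271
```

Reading the table: slopes are property units per billion years on one
datapoint per domain family, non-transmembrane only. The planted structure
is recovered qualitatively — mean disorder falls with age only in the
recent-animal subset (−0.051 per BY, p = 0.005; flat for ancient and
recent-plant), while the clustering index ψ declines in every subset (−0.052
per BY overall, p = 7×10⁻⁵). The filter report shows the decoys caught per
stage and all 10 random-presence contaminants rejected by the Dollo z-test:

```r
dplyr::count(res$filter_report, stage_dropped)
#> # A tibble: 4 × 2
#>   stage_dropped     n
#> 1 annotation        8
#> 2 dollo            10
#> 3 kept            142
#> 4 keyword          12
```

Scalar primitives are exported too:

```r
clustering_index("LLLLLLAAAAAA")
#> <clustering_index> psi = 11.0000 (L = 12, 1 frame of block size 6)
```

(Fully separated hydrophobic/hydrophilic halves of a 12-mer give ψ = 11,
the hand-computable worst case; `"LLLAAALLLAAA"` gives ψ = 0.)

Datasets round-trip to disk in plain formats (`tree.nwk`, FASTA, TSVs) via
`write_dataset()` / `read_dataset()`, and
`inst/scripts/simulate_dataset.R` wraps the generator for shell use. See
the vignette (`vignettes/phylostratigraphy-methods.Rmd`) for the models,
parameter defaults, and design decisions.

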