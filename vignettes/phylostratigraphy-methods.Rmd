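---
title: "Phylostratigraphy of domain properties: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phylostratigraphy of domain properties: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phylotrends)
```

## The analysis

Phylostratigraphy assigns an evolutionary age to each protein-coding unit
from the phylogenetic distribution of its homologs, and then asks whether
sequence properties trend with that age. `phylotrends` implements this
analysis with the protein *domain* (a pfam family) as the unit of homology:
domains are annotated per gene with residue coordinates, every instance of a
family across species is averaged into a single homology datapoint (avoiding
pseudoreplication), the family is dated on a time-calibrated species tree,
and properties are regressed on age. The properties are chosen to be largely
orthogonal to homology detectability: intrinsic structural disorder (ISD),
amino-acid composition, and the spatial clustering of hydrophobic residues
along the chain.

### The clustering index

Residues are encoded ±1 (Leu, Ile, Val, Phe, Met, Trp score +1; all other
standard residues −1; ambiguity codes follow the residues they stand for,
and unknown `X` is scored −1 as the conservative majority choice). For block
size $s = 6$ the index compares the variance of block sums against its
exact expectation under a uniform random arrangement of the same
composition:

$$\psi_f = \frac{s}{N}\sum_{k=1}^{N/s} \frac{(\sigma_{k,f} - sM_f/N)^2}{K},
\qquad
K = \frac{s\,(N^2 - M_f^2)}{N^2 - N}\Bigl(1 - \frac{s}{N}\Bigr),$$

where $\sigma_{k,f}$ are block sums in frame $f$, $M_f$ their total, and
$N = s\lfloor L/s\rfloor$ the truncated length. $K$ equals the variance of a
block sum under sampling without replacement, so $\mathbb{E}[\psi] = 1$
*exactly* for a random arrangement — the calibration the test suite checks
both by exhaustive enumeration (every arrangement of 6 hydrophobic residues
among 12) and by Monte-Carlo at length 120.

When $L$ is not a multiple of $s$, the index is averaged over
$p = L \bmod s$ frames. Two readings are arithmetically possible ($p$ or
$p+1$ starting offsets); we take the stated $p$ literally, using starting
offsets $0..p-1$ and truncating the tail, with $p = 1$ when $L \bmod s = 0$.
Sequences shorter than $2s$, or frames containing a single sign (where
$K = 0$), yield a *missing* index rather than an arbitrary value; missing
values are excluded from datapoint averages with a recorded count.

### Disorder and composition

Per-residue disorder scores in $[0,1]$ are consumed as an input (the
predictor itself is treated as a black box); the packaged surrogate — a
moving-average of per-residue propensities, monotone in local
hydrophilicity — makes the pipeline self-contained and testable, but it is
a surrogate, not a reimplementation of any energy-based predictor. A
domain's ISD is the mean score over its residue interval. Because
structure-trained predictors score cysteine (usually disulfide-bonded in
training data) as strongly order-promoting, the pipeline also rescores
sequences after excising all cysteines (`mean_isd_noC`); when external
scores cannot be recomputed, the surrogate performs the rescoring.
Composition is the fraction of each of the 20 standard residues among the
standard residues of the interval; ambiguity codes are excluded from both
numerator and denominator.

### Dating rules

A family is dated halfway between the most recent common ancestor (MRCA) of
the species carrying it and the previous node. Strata older than the tree
are pinned by calibration constants: families on a curated LUCA list are
4090 MY old; families present in eukaryotes and exactly one prokaryotic
domain of life are 3145 MY (the midpoint between LUCA and the emergence of
eukaryotes at 2200 MY); families present in non-protist eukaryotes *and* the
Excavata outgroup are 2230 MY. Three conventions resolve cases the rules
leave open: (i) families annotated in all three domains but absent from the
LUCA list get 3145 MY — the LUCA list is the sole authority for the oldest
stratum; (ii) a single-species family takes its leaf as the MRCA (half the
terminal branch's parent age) — such families are removed by the two-species
filter anyway; (iii) a family whose MRCA is the root, with no Excavata
presence and no domain flags, has no "previous node" and takes the root's
own age. Lineage subsets use two printed cutoffs: *ancient* above the LECA
age (2101 MY), *recent animal/plant* below the plant split (1496 MY) with
presence in the respective kingdom (animal checked first; joint presence
below 1496 MY cannot arise on the tree), *intermediate* between them.
Protists date families but never contribute property datapoints.

### Quality filters

Four pure predicates applied in a fixed order (any order gives the same
kept set): families annotated prokaryote-only or lacking species annotation
are dropped; abstract keyword screens drop organellar families and
prokaryote/viral-flavoured shared families unless a eukaryote-context term
rescues them (`*` patterns are prefix wildcards inside case-insensitive
substring matching, so `bacter*` matches "bacterial" and "Bacterium");
families in fewer than two species are dropped; and families whose
presence/absence pattern is indistinguishable from random contamination are
removed by a Dollo-parsimony z-test. Under Dollo parsimony (one gain, any
number of losses) the inferred loss count is the number of maximal absent
subtrees below the MRCA. The null draws the same number of carrier species
uniformly without replacement (`n_reps = 1000` by default; the replicate
count is a package choice) and one null is computed per carrier count and
cached, since the null depends only on $k$. Families with
$z = (\text{obs} - \mu_0)/\sigma_0 > -2$ are rejected; the test applies
only to families in fewer than half the species, and a degenerate null
($\sigma_0 = 0$, possible on tiny trees) keeps the family with a warning.
Genes containing any excluded family are excluded entirely.

### Homology datapoints and gene grouping

One datapoint per family: the unweighted mean over all instances in scope
(optionally restricted to one clade's instances, as in animal-only or
plant-only profiles), with a flat mean across species rather than a
per-species pre-average. Genes are dated by their oldest family and keyed by
it; when several families tie as oldest, single-link components of the
co-occurrence graph (families linked when
$P(\text{both} \mid \text{either}) \ge 50\%$ over all genes) provide the
key. Equally-old families falling in *different* components have no defined
group; the smallest group id is used, with a warning. Co-occurrence is
computed on retained genes, after filtering. Transmembrane and
non-transmembrane units are never pooled: a gene is transmembrane when
merged helix predictions cover strictly more than 18 residues, a domain
when a single helix overlaps it by at least half the domain's length or at
least half the helix's length (evaluated per helix — the criterion speaks
of *a* helix — with exact integer arithmetic at the 50% boundary).

### Trend statistics

Slopes come from ordinary least squares of the raw property on age in
billions of years, so units read directly (ISD score per BY, percentage
points per BY, clustering units per BY); outliers are retained and no
multiple-testing correction is applied to the reported raw p-values.
Box-Cox (profile-likelihood lambda) and arcsine-square-root transforms are
available for normality checks but are never the default. Spearman
correlations use average ranks for ties with the t-approximation for
p-values; the standard error of $\rho$ uses the Fisher transform with
$\sqrt{1.06/(n-3)}$ on the z scale, back-transformed to $\rho$ bounds. The
consensus recruitment order of amino acids is the mean rank across
criteria columns (after excluding composition-derived criteria), with no
smoothing step. The one-tailed sign test reports the exact binomial tail
(for 6 positives of 9 that is $130/512 \approx 0.254$). The set of
animal-essential amino acids is supplied as data, not hard-coded.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes, not
molecular evolution: no substitution models, no indels, no real homology
search. A clade-labelled ultrametric tree (animals, plants, fungi, an
Excavata outgroup attaching at the root) uses the calibration ages above as
internal nodes, with random coalescent subdivision inside clades (default
crown ages 700/900/800/1800 MY, opisthokont split 1105 MY — TimeTree-scale
round numbers). Families are born at stratum-specific nodes and lose whole
subtrees via a Poisson process on branches.

Planted trends, all configurable per lineage:

* **Composition** — the target hydrophobic fraction is
  `baseline + 0.03/BY × age` for animal-born families, flat elsewhere.
  Ancient-strata families get a constant offset (+0.045) equal to the
  animal slope times the age of the plant split, keeping the planted
  property continuous where the recent trend meets the flat ancient regime;
  this also reproduces the level structure seen in real data, where ancient
  domains are more hydrophobic and less disordered than young animal ones.
* **Disorder** — per-residue propensities are a monotone function of local
  hydrophilicity (0.90 hydrophilic / 0.05 hydrophobic), so the planted ISD
  slope is −0.85 × (hydrophobic slope) per BY, animal-only by default; an
  additive per-lineage term is available but zero by default.
* **Clustering** — planted through the *arrangement*, not the composition:
  hydrophobic/hydrophilic states follow a two-state Markov chain whose
  persistence is set from the family's target index via a pre-calibrated,
  cached simulation map (grid of persistence values, cubic smoothing,
  numeric inversion; the map is built under an internal fixed seed so
  datasets are byte-reproducible regardless of cache state). The default
  target is `1.35 − 0.07/BY × age` in every lineage. The magnitude is about
  twice the slope reported for real data, chosen so that sign recovery per
  lineage subset has adequate statistical power at the ~60-species scale
  the package simulates; composition and clustering trends remain
  independently controllable because no causal path links them.

Loss rate defaults to 0.01 events per branch per 100 MY. This was fixed
together with the generator's accuracy contract: under defaults, at least
95% of non-contaminant families must be dated within one stratum of truth.
At twice this rate, whole-stem losses collapse enough ancient families into
young tags to break that contract (and to seed spurious recent-lineage
trends through misdated, offset-carrying datapoints) — an instructive
artifact, but not the regime the analysis is meant to be validated in.

Contaminants draw carrier sets uniformly at random (3–10 species, below
half the species count) with baseline, trend-free sequences — exactly the
null the Dollo z-test simulates. Metadata decoys exercise each filter stage
(prokaryote-only annotation, missing annotation, missing abstract,
organellar and viral abstracts, and a rescued bacterial-plus-yeast
abstract that must survive). Truth tables record birth ages, lineages,
targets, and injected flags for every family.

What passing recovery tests show — and what they do not: the pipeline
recovers *planted* linear trends, lineage specificity, and random-presence
contamination under a generator whose sequences are conditionally
independent given their targets. They do not show robustness to homology
detection bias, annotation error, alignment artifacts, GC-content
confounding, or any property of real predictors: those require real data.

## Problem sizes and runtime choices

Defaults simulate ~60 species and ~860 families (~25k instances), which
exercises every code path in about half a minute. The recovery experiment
in the test suite runs 100 independent end-to-end simulations at reduced
scale (22 species, 140 families each, no contaminants) and checks that each
planted slope lies inside the fitted 95% CI in at least 90 of them;
contamination operating characteristics use a balanced 64-leaf tree with
1000-replicate nulls. The exhaustive Dollo oracle enumerates every gain
node and every loss placement on all presence subsets of seven trees with
up to 8 leaves (~1300 cases).

## Known limitations

* The Dollo null's loss count is monotone in the carrier count only away
  from the half-species boundary; the z-test is applied only below that
  boundary, where the direction of the comparison is well defined.
* The surrogate disorder model is intentionally simple (local
  hydrophilicity plus smoothing); it shares only the input/output contract
  with real predictors.
* Gene-level grouping averages whole-gene metrics across genes sharing an
  oldest-family key; families of different ages inside one gene make the
  gene-level trend a conservative, diluted version of the domain-level one.
* The per-helix reading of the 50% transmembrane overlap rule and the
  `p`-frame reading of the clustering average are single defensible choices
  among printed alternatives; both are isolated behind small functions if a
  different convention is ever needed.
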