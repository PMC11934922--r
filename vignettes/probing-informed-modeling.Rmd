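---
title: "Probing-informed RNA structure modeling with probefold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing-informed RNA structure modeling with probefold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(probefold)
```

## Overview

Chemical probing reagents modify RNA nucleotides at structure-dependent
rates: SHAPE reagents react with the 2'-hydroxyl of flexible (mostly
unpaired) riboses at every position, while DMS methylates the Watson–Crick
face and is informative mainly at A and C. After normalization, a
*reactivity* near 0 suggests a paired position and a reactivity near 1 a
flexible one. `probefold` turns per-nucleotide reactivity files into
secondary-structure models in five stages — preprocessing, replicate
aggregation, multi-condition prediction, differential footprinting, and
model comparison — plus a synthetic-data generator that makes every stage
testable against a known ground truth.

Positions with no usable signal carry the sentinel value `-10`
("undetermined") and are ignored by every computation downstream.

## Preprocessing: outlier removal and normalization

Raw reactivities contain large spikes from intrinsic reverse-transcriptase
stops. Two mutually exclusive treatments are provided; a project uses
exactly one throughout, for consistency:

* **simple** (default, recommended below ~300 nt): the top
  `ceil(0.02 n)` of the `n` valid values are outliers and become
  undetermined; the next `ceil(0.08 n)` values are averaged and all
  remaining values are divided by that average. After normalization the
  reference set has mean exactly 1.
* **interquartile** (for longer molecules): values above
  `Q3 + 1.5 * IQR` are outliers; the top `ceil(0.10 n)` of the remaining
  values are averaged into the divisor.

Finally, negative values down to `-0.3` are set to zero and anything below
`-0.3` becomes undetermined. The negative-value rules run **after**
normalization, so the `-0.3` floor applies to normalized values — worth
knowing because the alternative order gives different results.

Numerical conventions fixed here: quartiles use linear interpolation
(quantile type 7); outlier/reference counts use the ceiling of
fraction × valid count; ties at a rank cutoff are broken by position
index (earlier positions rank as more reactive), making the ranking
deterministic. The method/length guideline is advisory: the package
warns, it never switches methods silently.

A preprocessed profile records its state, and `preprocess_profile()` is a
no-op on an already-preprocessed profile. This is what makes
preprocessing idempotent: a second *arithmetic* pass would trim a fresh
2% of the remaining values (rank-based trimming always finds a new top
2%), so idempotence by state is the only consistent behavior for a
pipeline that may revisit intermediate files.

## Replicate aggregation

Replicates of the same RNA × probe × condition are aggregated position by
position. A position with fewer than `min_ndata` (default 2, clamped to 1
for single-replicate conditions) valid values is undetermined. Otherwise
the mean and sample (n−1) standard deviation are computed and the position
is **accepted** when the standard deviation is at most `min_std` (default
0.15) or when all pairwise means of replicate values fall in the same
reactivity class as the total mean. Classes (used throughout for coloring
as well) are: `low` below 0.4, `medium` in the closed interval
[0.4, 0.7], `high` above 0.7, `undefined` for the sentinel.

Two facts about this rule that the test suite pins down:

* With two replicates the single pairwise mean *is* the total mean, so the
  class criterion would accept everything; a guard applies instead —
  accepted only if the standard deviation passes or the two replicate
  values themselves share a class.
* The **warning** category ("all pairwise means share one class that is
  not the total mean's class") is provably empty: the total mean is the
  average of the pairwise means and classes are intervals, so if every
  pairwise mean lies in one class the total mean lies in it too and the
  position is accepted. The category is kept in the schema — it exists in
  the field's reporting conventions and could be reached under other
  class-boundary conventions — but under this package's rules a position
  that fails both criteria is flagged `nonconsistent`.

Only accepted positions feed structure modeling; everything else
contributes no pseudo-energy. Pairwise Pearson/Spearman correlations are
reported as QC only — excluding a replicate is the user's decision, made
by marking it `discarded` in the samples table.

Multi-primer experiments are concatenated onto full-length coordinates;
overlaps average the means when both sides are accepted (standard
deviations combined conservatively as the maximum), keep the accepted
side when only one is, and otherwise keep the more severe flag.

## The folding engine

Accepted reactivities become per-nucleotide pseudo-energies
`m * ln(r + 1) + b` (defaults m = 2.6, b = −0.8 kcal/mol, the constants
commonly used with this soft-constraint scheme), added once per paired
nucleotide. Undetermined positions contribute nothing, so an
all-undetermined profile reproduces the unconstrained ensemble exactly.

The built-in thermodynamic model is deliberately small: Watson–Crick and
GU pairs only, pair energies by type (GC −3, AU −2, GU −1 kcal/mol), a
minimum hairpin loop of 3, RT = 0.616 kcal/mol, and a **stacking bonus**
(default −1.5 kcal/mol) for every pair adjacency `(i,j)`/`(i+1,j−1)`. The
stacking term is the minimal helix-cooperativity ingredient of
nearest-neighbor models; without it, an isolated long-range pair (say,
joining the ends of two different hairpins) is exactly as favorable as a
helix-terminal pair, the ensemble smears over such lone pairs, and
terminal pairs of real helices drop below the 50% centroid threshold. A
pair-only model is therefore not just less accurate but qualitatively
misleading, which is why the stacking term is part of the default model
rather than an option.

The partition function over all nested structures is computed by an exact
O(n³) two-table dynamic program; stochastic traceback of the tables draws
i.i.d. Boltzmann samples, reproducible under a seed. Pair probabilities
use an outside pass that is only run on request, since sampling needs the
inside tables alone. The test suite checks the tables against exhaustive
enumeration (to ten significant digits on sequences up to 12 nt) and the
sampler against the exact structure distribution (total-variation distance
on 50 000 samples). The engine is pluggable: the prediction stage depends
only on the sampled structures, so any sampler producing the same objects
— e.g. an adapter around a full nearest-neighbor engine — can stand behind
it.

## Multi-condition prediction

Each probing condition contributes `n_samples` (default 1000) samples from
its constrained ensemble. An optional multiple sequence alignment becomes
one more "pseudo-condition": column pairs are scored by the mean pair
energy over sequences that can pair there, a covariation bonus (−1.0
kcal/mol per distinct observed pair type beyond the first) and an
inconsistency penalty (+0.5 kcal/mol per sequence that cannot pair,
including gapped ones); the scored columns are folded and sampled with the
same machinery and mapped to reference coordinates (pairs touching a
reference gap are dropped). Compensatory mutations — the phylogenetic
signature of a conserved pair — thus lower the consensus energy of true
pairs.

The pooled samples are clustered by base-pair distance (symmetric
difference of pair sets) with average-linkage agglomerative clustering.
The number of clusters maximizes the mean silhouette width over
k = 2..10, with one cluster when the pool's mean pairwise distance is
below 2 (a near-degenerate ensemble). Distinct structures are ordered
canonically before clustering, so the result does not depend on pool
order. Each cluster is scored multiplicatively across conditions:
`score = prod_c (occupancy_c + 0.01)`, where `occupancy_c` is the fraction
of condition c's samples in the cluster. The product rewards clusters
supported by *every* condition: occupancies of 50%/50% score
(0.51)² ≈ 0.26, far above a 100%/0% cluster at (1.01)(0.01) ≈ 0.01. The
ε = 0.01 keeps absence in one condition a penalty rather than a veto.
Ties break by total occupancy, then by lower mean sample energy. These
are this package's own concrete choices — published cluster-based
multi-probe predictors leave room for several instantiations
(multiplicative, additive or Pareto scoring; other linkages), and results
here are not claimed to be bit-identical to any of them.

The reported models are the centroids (pairs with intra-cluster frequency
strictly above 0.5 — two conflicting pairs cannot both exceed 50% among
nested structures, so centroids are guaranteed valid) of the two
top-ranked clusters; best and second always come from different clusters
when at least two exist.

## Footprinting

Two conditions are compared position by position on replicate-level
preprocessed reactivities: ΔR = |R1 − R2|, the relative difference
ΔR/(R1 + R2) (defined as 0 when the sum is 0), and a two-sided Welch
(unequal-variance) t-test — the paper-trail default where only "two-sided
t-test" is standard. A position is significant only when ΔR > 0.2,
relative > 0.2 and p < 0.05. The dual effect-size thresholds exclude both
small changes between weakly reactive nucleotides and large-but-meaningless
changes between highly reactive ones; because they act as the effect-size
guard, no multiple-testing correction is applied by default (a
Benjamini–Hochberg option exists). Undetermined positions are excluded;
positions with fewer than two valid replicates on either side are reported
with a `no-test` flag and never called significant.

## Synthetic data: what it emulates, and what it does not

`simulate_profiles()` draws a base reactivity per position — unpaired from
Gamma(shape 3, scale 0.27) (mean ≈ 0.8), paired from Gamma(shape 2,
scale 0.05) (mean 0.1), both right-skewed and nonnegative like real
normalized reactivities — then applies mean-one log-normal replicate noise
(sdlog 0.3), ×10 spikes at rate 0.01 (emulating the intrinsic RT stops
that outlier removal targets) and sentinel dropouts at rate 0.02. DMS-like
profiles blank all non-A/C positions. `simulate_msa()` mutates
non-reference rows at a chosen rate; mutations at paired positions are
compensatory with probability 0.9, replacing the pair by a random WC/GU
type, and gaps appear at rate 0.01.

The generator reproduces the *statistical* structure the pipeline assumes
— probe observability, paired/unpaired separation, replicate noise,
spikes, dropouts — but not several features of real data: no 5'/3' signal
decay or primer-proximal blind zones, no sequence-dependent reactivity
biases, no correlated noise along the molecule, no partially melted or
alternative conformations, and reactivities generated *from* the very
secondary-structure model the predictor assumes (no tertiary-contact
protections). Recovery results on synthetic data therefore demonstrate the
pipeline's internal consistency — that the sampling/clustering machinery
extracts what the data contain — not field accuracy on real probing data.

The recovery benchmark (`benchmark_structure()`) is a 62-nt three-hairpin
RNA with GC-rich, mutually non-complementary 7-bp stems and A/C-rich loops
and linkers, so the designed fold is thermodynamically dominant and DMS
observability still covers informative positions. The validation suite
simulates SHAPE-like and DMS-like conditions (3 replicates, noise 0.3) over
20 seeds with 500 samples per condition, and compares single-condition,
integrated, and MSA-augmented predictions by base-pair F1 against the
design. Footprint power/size use 100 simulated 100-nt RNAs with ten
positions shifted by 0.6 at replicate noise 0.1 (3+3 replicates). These
sizes make the whole suite run in a couple of minutes while keeping the
Monte-Carlo error far from every threshold tested.

## Projects and traceability

`init_project()` lays out resources/ and per-stage results/ folders, a
samples.tsv and a config.yaml; `run_pipeline()` executes
preprocess → aggregate → predict/footprint. Every output is a plain-text
file with fixed numeric formatting; stage outputs record a content hash of
their inputs and configuration, so re-running recomputes only what
changed (hashes, not timestamps — robust to file copying), and two runs
with identical inputs, configuration and seed produce byte-identical
results. Sampling uses one RNG stream per condition, derived
deterministically from the master seed and the condition name, so adding a
condition never perturbs another condition's samples.

## Limitations

* Nested structures only: no pseudoknots.
* The built-in energy model is a teaching-grade stand-in: no full
  nearest-neighbor parameter tables, loop penalties or dangles. Use the
  engine adapter point for production-accuracy thermodynamics.
* The MSA consensus scorer is a simplified covariation heuristic, not a
  substitute for principled covariation statistics; alignments with many
  gapped or divergent rows will dilute its signal.
* One normalization method per project is enforced by construction;
  mixing differently normalized inputs is the user's responsibility when
  importing externally processed reactivity files.
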