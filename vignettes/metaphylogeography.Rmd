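---
title: "Community and intraspecific structure from metabarcoding ESVs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community and intraspecific structure from metabarcoding ESVs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaphylo)
```

## The problem

Bulk-sample COI metabarcoding of freshwater invertebrates yields, after
denoising, a table of exact sequence variants (ESVs): unique amplicon
sequences with read counts per sample and field replicate. Because COI is a
single-copy mitochondrial marker, distinct ESVs within a species can be read
as haplotypes, so the same dataset supports two levels of inference:

* **community β-diversity** — which species (proxied by clusters of ESVs)
  occur where, and
* **intraspecific genetic variation** — which haplotypes of each species
  occur where.

`metaphylo` implements the full path from a denoised ESV table to
permutation tests of both levels against geographic region groups, plus a
scrambled-cluster null model that makes the two levels comparable despite
their very different dimensionality.

## Quality filters

The filter chain runs in a fixed order and is idempotent:

1. **Frameshift screen.** COI is protein coding, so genuine amplicons align
   to each other without internal gaps. We align against the modal-length
   sequence block with internal gap opening prohibitively penalised, which
   reduces to keeping exactly the sequences of modal length: any shorter or
   longer sequence would need a leading gap or leave unaligned trailing
   sequence, and is removed as a putative pseudogene or PCR/sequencing
   artifact. The modal length is computed on the raw input (ties go to the
   length with more reads, then to the shorter).
2. **Total-read filter.** ESVs with fewer than 100 reads summed over all
   samples and replicates are removed; genuine templates amplify
   exponentially and should be abundant.
3. **Replicate-cell filter.** Any (sample, replicate) cell with fewer than
   5 reads is zeroed, guarding against tag-switching.
4. **Pooling.** Replicates are pooled to presence/absence per sample.
   Feature columns that end up empty are dropped; empty samples are kept so
   the sample axis stays aligned with the metadata.

All thresholds are arguments; the defaults above are the package defaults
throughout.

## Clustering and species-bound clusters

Clusters are the connected components of the graph joining two ESVs whenever
their Levenshtein distance (substitutions and indels each cost one) is at
most `d` — single-linkage transitive closure with no cluster breaking.
Distances are edit distances rather than Hamming distances for fidelity to
the "number of differences" semantics of the clustering tools used in this
field, although after the length filter the two coincide within an amplicon.

* **OTUs** use a single `d` chosen by `select_otu_d()`: the integer whose
  ratio to the amplicon length is closest to 3% (ties toward the smaller,
  more conservative `d`). For a 229-nt amplicon this gives `d = 7`
  (7/229 = 3.06%); for 313 nt, `d = 9` (2.88%).
* **The hierarchy** starts at `d = 0` and raises `d` by one until a single
  cluster remains. Because the edge set only grows, each partition nests in
  the next; `build_hierarchy()` exploits this by adding edges incrementally
  to a union-find structure.
* **Species-bound clusters (SBCs).** ESVs are assigned to a species when
  their classifier species-level bootstrap proportion is at least 0.8.
  For each species, `find_sbcs()` looks anywhere in the hierarchy for a
  cluster containing all of that species' assigned ESVs and none assigned
  to any other species; unassigned ESVs may be absorbed. A species with a
  single assigned ESV always yields an SBC (its singleton at `d = 0`).

When several nested member-sets qualify for one species, the reported SBC
is the set persisting over the widest `d` range (ties: more members, then
lexicographic order). The hierarchy's nesting guarantees that a qualifying
set present at `d_min` and `d_max` is a cluster at every `d` between. The
lowest-`d` qualifying set is available by argument for sensitivity checks.

## Dissimilarity matrices

Community matrices apply Sørensen dissimilarity,
$\beta_{sor} = (b + c) / (2a + b + c)$, to the presence/absence profiles of
ESVs, OTU-merged columns, or SBC-merged columns.

Intraspecific matrices are built per qualifying cluster. A cluster
qualifies when it has at least 2 member ESVs and is present in at least 2
region groups with at least 3 occupied samples each (hence at least six
samples). Each cluster's Sørensen matrix is computed **only over the
samples containing the cluster**: a dissimilarity of 1 against a sample
where the species is absent would measure occupancy, not intraspecific
variation. This restriction is what generates missing sample pairs. The
per-cluster matrices are averaged entry-wise over the matrices in which
each pair is defined, and the mean matrix is completed by repeatedly
removing the sample with the most missing pairs (ties: lexicographically
smallest id) until none remain.

## Scrambled-cluster null model

Community profiles live in thousands of dimensions; per-cluster matrices in
a handful. Distance concentration alone therefore pushes community
dissimilarities toward 1, making raw comparisons of pseudo-F values between
the levels misleading. The null model re-creates the intraspecific
construction after destroying species identity: ESV membership is shuffled
uniformly among the selected clusters, preserving the number of clusters
and every cluster size. Each scramble rebuilds per-cluster matrices, the
mean matrix, its completion, restricts to the observed intraspecific sample
set, and records a statistic (PERMANOVA pseudo-F against regions, or the
Spearman correlation with geodesic distance). Scrambling permutes only the
ESVs of the qualifying clusters, and the qualification criterion is not
re-applied to scrambles — re-filtering would change the cluster count and
defeat the size-preservation that makes the null comparable. Replicates
whose completed matrix can no longer support the statistic are excluded
and counted. A master seed spawns one substream per replicate, so
individual replicates are reproducible.

## Permutation statistics

* **PERMANOVA.** One-way partition of the squared dissimilarities:
  $SS_T = \sum_{i<j} d_{ij}^2 / n$, $SS_W = \sum_g \sum_{i<j \in g}
  d_{ij}^2 / n_g$, pseudo-$F = (SS_A/(g-1)) / (SS_W/(n-g))$. The p-value
  permutes group labels; when the number of distinct relabellings is within
  the permutation budget the space is enumerated and the p-value is exact,
  otherwise Monte-Carlo sampling with the add-one convention
  $p = (1 + \#\{F^* \ge F\}) / (1 + n_{perm})$, so p is never zero.
  Pairwise tests run per group pair with Benjamini–Hochberg adjustment.
* **Dispersion.** Homogeneity of multivariate spread guards the PERMANOVA's
  location interpretation; `beta_dispersion()` delegates to the standard
  principal-coordinates / spatial-median construction with the
  negative-eigenvalue correction (`vegan::betadisper` + `permutest`),
  dropping single-sample groups, which carry no spread information.
* **Mantel–Spearman.** Rank correlation of the lower triangles under
  simultaneous row/column permutation of one matrix, exact for small n
  (all $n!$ permutations when $n! \le n_{perm}$).
* **Region groups.** k-means on raw (lat, lon) degrees, with wetland
  samples excluded before clustering. The candidate number of regions is
  judged by a stability curve: per k, many pairs of independent clusterings
  are compared by adjusted Rand index (Hubert–Arabie).
* **Geography.** Geodesic distances on the WGS84 ellipsoid in meters via
  the Karney-style algorithm in `geosphere::distGeo`; great-circle
  approximations are deliberately not used.

### A note on k-means stability

Each clustering inside the stability loop takes the best of
`n_starts_per_run = 20` random starts. With a single random start,
Hartigan–Wong recovers the globally optimal partition of even perfectly
separated blob layouts only about half the time — random row
initialisation regularly seeds one blob twice and the local search cannot
escape — so the stability curve is dominated by initialisation noise at
every k and peaks nowhere. With modest multistart, instability isolates
genuine ambiguity among near-optimal partitions: stability is perfect for
every k up to the natural group count (coarse merges are unambiguous) and
decays beyond it, where splitting a tight group is arbitrary. The
`stable_k()` rule therefore reports the **largest** k attaining the
maximal mean adjusted Rand index.

## The synthetic-data generator

`generate_dataset()` plants known structure so every downstream stage is
testable without sequencing data:

* species base sequences pairwise at least twice the OTU threshold apart
  (random draws at amplicon length 229 are ~75% divergent; a bounded retry
  loop guards short-sequence configurations);
* 1–5 haplotypes per species, each 1–3 substitutions from the base;
* a species' range is all regions, or one region with probability
  `species_structure_strength` (community-level structure); a haplotype is
  private to one region of its species' range with probability
  `structure_strength` (intraspecific structure). The two knobs separate
  the levels: `species_structure_strength > 0` with
  `structure_strength = 0` plants community structure over exchangeable
  haplotypes, the configuration under which the observed intraspecific
  pseudo-F should fall inside its scrambled null;
* detection of a resident haplotype in a sample with probability
  `detection_prob` (default 0.8), then negative-binomial reads per
  replicate (`mean_depth = 1000`, size `depth_dispersion = 2`) —
  overdispersed counts typical of amplicon data;
* spurious noise variants: with probability `noise_esv_rate` a haplotype
  spawns a single-substitution variant carrying Poisson(5) reads (capped
  below 100) in one replicate of one occupied sample, exercising both the
  total-read and replicate filters;
* sample coordinates scattered (σ = 0.05°) around region centroids spaced
  along the study bounding box (lon −118..−113, lat 49..52), spacing far
  exceeding the scatter so region recovery is well posed;
* three field replicates per sample, collection years 2019–2022, optional
  wetland-flagged samples.

What the generator does **not** emulate: phylogenetically realistic
sequence evolution, PCR chimeras, primer bias, abundance–occupancy
correlations, or uneven sampling effort. Passing tests therefore show the
pipeline's statistical machinery is correct and calibrated under the
planted model, not that real communities satisfy that model.

## Numerical and design choices

* Cluster ids are the lexicographically smallest member ESV id —
  deterministic across runs.
* `select_otu_d` breaks exact ties toward the smaller `d` (more
  conservative clustering).
* Matrix completion breaks ties on the missing-pair count by removing the
  lexicographically smallest sample id.
* Sørensen between two samples with no present features is undefined and
  recorded missing; against an occupied sample it is 1 by the formula.
* Permutation p-values are reproducible given a seed; exact modes engage
  automatically when the permutation space fits the budget.
* All-pairs distances use `utils::adist` (C implementation); the O(n²)
  pair count is acceptable at the scale this package targets (up to a few
  tens of thousands of ESVs per amplicon).

## Problem sizes used in the test suite

The statistical properties are exercised at deliberately modest sizes: the
power and type-I checks use 2 regions × 10 samples and 15 species over 100
(alternative) and 200 (null) simulated datasets at 999 permutations; the
null-model check uses 20 datasets at 200 scrambles; the stability check 200
pairs per k. These sizes give the binomial margins quoted in the tests
while keeping a full run of the suite to a few minutes.

## Worked example

```{r example, eval = FALSE}
cfg <- list(
  synth = list(n_regions = 2, samples_per_region = 8, n_species = 10,
               structure_strength = 1, detection_prob = 1, seed = 5),
  params = list(permutations = 999, scrambles = 100, kmeans_k = 2,
                seed = 5))
res <- run_pipeline(cfg, "demo_run")
res$stats$intraspecific_otu$permanova
res$nulls$otu$percentile
```

## Limitations

* Only one-factor PERMANOVA is provided; multi-factor designs and
  distance-based RDA are out of scope.
* The abundance-weighted Sørensen variant is not implemented: every
  downstream step uses presence/absence, for which the incidence form is
  equivalent.
* Whether per-cluster matrices should span all samples (scoring 1 against
  cluster-free samples) or only occupied ones is a genuine modelling
  choice; the occupied-samples restriction is the default here because it
  separates intraspecific variation from occupancy, and it is what creates
  the missing-pair completion step.
* The SBC representative when membership changes with `d` (widest
  persistence vs. lowest `d`) is configurable; results in well-separated
  data are insensitive to it.
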