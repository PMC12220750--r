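# metaphylo

Community β-diversity and intraspecific haplotype structure from denoised
COI metabarcoding data.

Bulk-sample metabarcoding yields exact sequence variants (ESVs) — unique
denoised amplicon sequences with read counts per sample and field
replicate. Because distinct COI ESVs within a species behave as
haplotypes, one dataset supports inference at two levels: which species
occur where (community β-diversity) and which haplotypes of each species
occur where (intraspecific genetic variation, the raw material of
phylogeography). `metaphylo` is for ecologists and molecular biologists
who want both levels from the same table, with permutation inference
against geographic region groups and a null model that makes the two
levels comparable.

## What it implements

* **Quality filters** in fixed order: a frameshift/length screen
  (end-gap-only alignment to the modal-length block), removal of ESVs with
  < 100 total reads, zeroing of sample-replicate cells with < 5 reads, and
  pooling of replicates to presence/absence.
* **SWARM-style clustering**: clusters are connected components of the
  graph linking ESVs at ≤ *d* Levenshtein differences (no cluster
  breaking). The OTU threshold is the integer *d* closest to 3% of the
  amplicon length (229 nt → *d* = 7; 313 nt → *d* = 9); the full hierarchy
  runs *d* = 0, 1, … until a single cluster remains.
* **Species-bound clusters (SBCs)**: for each species (ESVs assigned at
  species-level bootstrap ≥ 0.8), any cluster in the hierarchy containing
  all of that species' assigned ESVs and none of any other species.
* **Sørensen dissimilarity** β<sub>sor</sub> = (b + c)/(2a + b + c) at
  community level and per cluster (restricted to samples containing the
  cluster), mean intraspecific matrices across clusters, and greedy
  missing-pair completion.
* **Scrambled-cluster null model**: ESV membership shuffled among clusters
  preserving cluster sizes, rebuilding the mean-matrix construction per
  scramble to give the null distribution of a statistic.
* **Permutation statistics**: one-way PERMANOVA (exact enumeration for
  small designs, add-one Monte-Carlo otherwise), pairwise PERMANOVA with
  Benjamini–Hochberg FDR, multivariate dispersion homogeneity,
  Mantel tests with Spearman correlation, adjusted Rand index, k-means
  region grouping with a stability curve, and WGS84 geodesic distance
  matrices in meters.
* **A synthetic-data generator** planting species, haplotype, and region
  structure with known truth, so the whole pipeline is testable without
  sequencing data.

## Worked example

```r
library(metaphylo)

cfg <- synth_config(n_regions = 2, samples_per_region = 8, n_species = 10,
                    structure_strength = 1, detection_prob = 0.8, seed = 5)
ds  <- generate_dataset(cfg)
fc  <- apply_filter_chain(ds$esv, samples = ds$metadata$sample_id)

otus <- cluster_at_d(fc$esv, select_otu_d(229))
sbcs <- find_sbcs(build_hierarchy(fc$esv), assign_species(fc$esv))

reg  <- ds$truth$sample_regions
ids  <- select_intraspecific_clusters(otus$clusters, fc$presence, reg)
mats <- per_cluster_matrices(fc$presence, otus$clusters[ids])
mm   <- complete_matrix(mean_dissimilarity(mats))
permanova(mm, reg[rownames(mm)], n_perm = 999, seed = 5)
```

Output:

```
esv_partition: d = 7 -- 10 clusters over 33 ESVs
sbc_set: 10 species-bound clusters ( 10 species assigned, 0 not recovered )
PERMANOVA: pseudo-F = 444.5 (df 1, 14), p = 0.001 (Monte-Carlo, 999 perms)
```

The generator planted 10 species (each ≥ 14 substitutions apart) with
fully region-private haplotypes in 2 regions of 8 samples. The filters
removed the planted low-count noise variants, the 3%-rule threshold
(*d* = 7 for 229 nt) recovered the 10 species as OTUs, all 10 were
species-bound, and the intraspecific mean matrix separates the two regions
(pseudo-F is the ratio of among- to within-region variation; p = 0.001 is
the Monte-Carlo floor at 999 permutations). Comparing the observed
pseudo-F with its scrambled-cluster null:

```r
nd <- null_statistic_distribution(fc$presence, otus$clusters[ids],
                                  regions = reg,
                                  observed_samples = rownames(mm),
                                  n_reps = 100, statistic = "pseudo_F",
                                  seed = 5)
null_percentile(nd, 444.5)
#> [1] 0.97
```

A config-driven end-to-end run (filters → regions → clustering → SBCs →
matrices → null model → statistics, with a hashed manifest) is available
as `run_pipeline(config, out_dir)`; see `?run_pipeline`.

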