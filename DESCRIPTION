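Package: metaphylo
Title: Metaphylogeography from Denoised Metabarcoding Sequence Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for extracting community beta-diversity and intraspecific
    haplotype structure from denoised COI metabarcoding data. Implements
    post-denoising quality filters (frameshift/length screening, read-count
    thresholds, replicate pooling), SWARM-style single-linkage clustering of
    exact sequence variants across a full d-threshold hierarchy, detection of
    species-bound clusters, Sorensen dissimilarity matrices at community and
    within-cluster level, mean intraspecific dissimilarity matrices with
    missing-pair completion, a scrambled-cluster null model, and permutation
    statistics (PERMANOVA, multivariate dispersion, Mantel-Spearman, adjusted
    Rand, k-means region grouping, WGS84 geodesic distances). A synthetic-data
    generator with planted species, haplotype and region structure supports
    end-to-end testing without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    geosphere,
    vegan,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
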