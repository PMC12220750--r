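test_that("mutate_sequence introduces exactly the requested substitutions", {
  set.seed(1)
  s <- paste(rep("A", 50), collapse = "")
  expect_identical(mutate_sequence(s, 0), s)
  for (k in 1:5) {
    r <- random_dna(1, 40)
    mut <- mutate_sequence(r, k)
    expect_equal(nchar(mut), 40)
    expect_equal(sum(strsplit(r, "")[[1]] != strsplit(mut, "")[[1]]), k)
  }
  expect_error(mutate_sequence("ACGT", 5), "exceeds")
  set.seed(7); a <- mutate_sequence(s, 3)
  set.seed(7); b <- mutate_sequence(s, 3)
  expect_identical(a, b)
})

test_that("same config and seed give byte-identical datasets", {
  cfg <- synth_config(n_species = 5, samples_per_region = 4, seed = 3)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$esv, d2$esv)
  expect_identical(d1$metadata, d2$metadata)
})

test_that("planted structure follows structure_strength", {
  # fully structured: every haplotype's region set is a single region
  cfg1 <- synth_config(n_regions = 2, samples_per_region = 6, n_species = 6,
                       structure_strength = 1, detection_prob = 1, seed = 5)
  d1 <- generate_dataset(cfg1)
  expect_true(all(lengths(d1$truth$haplotype_regions) == 1))
  # every observed true haplotype occurs only in its own region's samples
  pres <- pool_replicates(d1$esv, samples = d1$metadata$sample_id)
  for (id in intersect(names(d1$truth$haplotype_regions), colnames(pres))) {
    occ <- rownames(pres)[pres[, id]]
    expect_true(all(d1$truth$sample_regions[occ] ==
                      d1$truth$haplotype_regions[[id]]))
  }
  # exchangeable: every haplotype spans all regions
  cfg0 <- synth_config(n_regions = 3, samples_per_region = 4, n_species = 4,
                       structure_strength = 0, seed = 5)
  d0 <- generate_dataset(cfg0)
  expect_true(all(lengths(d0$truth$haplotype_regions) == 3))
})

test_that("generated sequences respect the divergence plan", {
  cfg <- synth_config(n_species = 8, samples_per_region = 4,
                      interspecies_min_subs = 14, seed = 9)
  ds <- generate_dataset(cfg)
  sp <- ds$truth$haplotype_species
  seqs <- setNames(ds$esv$esvs$sequence, ds$esv$esvs$esv_id)
  true_ids <- intersect(names(sp), names(seqs))
  bases <- tapply(true_ids, sp[true_ids], function(ids) seqs[ids[1]])
  D <- adist(bases)
  expect_true(all(D[upper.tri(D)] >= 14 - 2 * 3))  # bases mutated by <= 3
  # noise ESVs are one substitution from a true haplotype and low-count
  for (nid in intersect(ds$truth$noise_ids, names(seqs))) {
    dmin <- min(adist(seqs[nid], seqs[true_ids]))
    expect_equal(as.integer(dmin), 1L)
    expect_lt(sum(ds$esv$counts$reads[ds$esv$counts$esv_id == nid]), 100)
  }
  # assigned haplotypes carry sBP in [0.8, 1]
  bp <- ds$esv$esvs$sbp[!is.na(ds$esv$esvs$sbp)]
  expect_true(all(bp >= 0.8 & bp <= 1))
})

test_that("infeasible divergence constraints error after bounded retries", {
  expect_error(
    generate_dataset(synth_config(n_species = 40, amplicon_length = 4,
                                  interspecies_min_subs = 4,
                                  intraspecies_subs = c(1, 1), seed = 1)),
    "could not place")
})

test_that("planted species are recovered as SBCs when divergence allows", {
  # interspecies distance far above intraspecies spread and full assignment:
  # brute-force enumeration over all partitions must find each species,
  # and find_sbcs must agree
  cfg <- synth_config(n_species = 6, samples_per_region = 5,
                      haplotypes_per_species = c(2, 4),
                      assigned_fraction = 1, noise_esv_rate = 0, seed = 21)
  ds <- generate_dataset(cfg)
  fc <- apply_filter_chain(ds$esv, samples = ds$metadata$sample_id)
  hier <- build_hierarchy(fc$esv)
  assign <- assign_species(fc$esv)
  sbcs <- find_sbcs(hier, assign)
  expect_equal(length(sbcs), length(unique(na.omit(assign))))
  oracle <- oracle_sbcs(hier, assign)
  expect_setequal(vapply(sbcs, `[[`, "", "species"), names(oracle))
})

test_that("written synthetic datasets re-read into the same analysis input", {
  ds <- generate_dataset(synth_config(n_species = 4, samples_per_region = 3,
                                      seed = 12))
  dir <- withr::local_tempdir()
  write_synth_dataset(ds, dir)
  back <- read_esv_table(file.path(dir, "esv_counts.tsv"),
                         file.path(dir, "esv_seqs.fasta"),
                         file.path(dir, "taxonomy.tsv"))
  ord <- order(back$esvs$esv_id)
  expect_equal(back$counts, ds$esv$counts)
  expect_equal(back$esvs$sequence[ord],
               ds$esv$esvs$sequence[order(ds$esv$esvs$esv_id)])
  expect_equal(read_sample_metadata(file.path(dir, "samples.csv")),
               ds$metadata)
})
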