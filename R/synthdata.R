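# Synthetic metabarcoding communities with planted species, haplotype and
# region structure. The generator emulates the features the downstream
# analysis relies on: multiple well-diverged species, 1-5 haplotypes per
# species differing by a few substitutions, region-structured haplotype
# occurrence, triplicate field replicates with overdispersed read depths,
# and rare one-off noise variants that the abundance filters should remove.

#' Configuration for the synthetic-data generator
#'
#' @param n_regions number of geographic region groups.
#' @param samples_per_region samples per region.
#' @param n_species number of planted species.
#' @param haplotypes_per_species integer range `c(min, max)`; each species
#'   draws its haplotype count uniformly from it.
#' @param amplicon_length length of every generated sequence (nt).
#' @param interspecies_min_subs minimum pairwise substitutions between
#'   species base sequences; defaults to twice the OTU threshold for the
#'   amplicon length so species never merge at the community threshold.
#' @param intraspecies_subs range of substitutions separating each extra
#'   haplotype from its species base sequence.
#' @param structure_strength probability in `[0,1]` that a haplotype is
#'   private to a single region of its species' range (1 = fully
#'   region-structured, 0 = haplotype frequencies identical across the
#'   range).
#' @param species_structure_strength probability a species' whole range is
#'   restricted to one region. Plants community-level occupancy structure
#'   independently of haplotype-level structure: with
#'   `species_structure_strength > 0` and `structure_strength = 0`,
#'   communities differ between regions while haplotypes within each
#'   multi-region species remain exchangeable.
#' @param detection_prob probability a haplotype occurring in a sample's
#'   region is actually detected in that sample.
#' @param mean_depth mean reads per detected haplotype per replicate.
#' @param depth_dispersion negative-binomial size parameter of the depth
#'   model (smaller = more overdispersed).
#' @param noise_esv_rate probability each true haplotype spawns one spurious
#'   low-count single-substitution variant.
#' @param replicate_count field replicates per sample.
#' @param assigned_fraction fraction of true haplotypes given a species-level
#'   taxonomic call (sBP drawn from `[0.8, 1]`); the rest stay unassigned.
#' @param n_wetland_per_region extra wetland-flagged samples per region
#'   (excluded from region grouping downstream).
#' @param coord_sd Gaussian scatter (degrees) of sample coordinates around
#'   their region centroid; centroid spacing is much larger.
#' @param seed integer seed; the same config generates byte-identical data.
#' @return a validated list of class `synth_config`.
#' @export
synth_config <- function(n_regions = 2,
                         samples_per_region = 10,
                         n_species = 15,
                         haplotypes_per_species = c(1L, 5L),
                         amplicon_length = 229,
                         interspecies_min_subs = 2L * select_otu_d(amplicon_length),
                         intraspecies_subs = c(1L, 3L),
                         structure_strength = 0.5,
                         species_structure_strength = 0,
                         detection_prob = 0.8,
                         mean_depth = 1000,
                         depth_dispersion = 2,
                         noise_esv_rate = 0.5,
                         replicate_count = 3,
                         assigned_fraction = 1,
                         n_wetland_per_region = 0,
                         coord_sd = 0.05,
                         seed = 1L) {
  cfg <- list(n_regions = as.integer(n_regions),
              samples_per_region = as.integer(samples_per_region),
              n_species = as.integer(n_species),
              haplotypes_per_species = as.integer(haplotypes_per_species),
              amplicon_length = as.integer(amplicon_length),
              interspecies_min_subs = as.integer(interspecies_min_subs),
              intraspecies_subs = as.integer(intraspecies_subs),
              structure_strength = structure_strength,
              species_structure_strength = species_structure_strength,
              detection_prob = detection_prob,
              mean_depth = mean_depth,
              depth_dispersion = depth_dispersion,
              noise_esv_rate = noise_esv_rate,
              replicate_count = as.integer(replicate_count),
              assigned_fraction = assigned_fraction,
              n_wetland_per_region = as.integer(n_wetland_per_region),
              coord_sd = coord_sd,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_regions >= 1, samples_per_region >= 1, n_species >= 1,
              length(haplotypes_per_species) == 2,
              haplotypes_per_species[1] >= 1,
              haplotypes_per_species[1] <= haplotypes_per_species[2],
              amplicon_length > 0, interspecies_min_subs >= 1,
              replicate_count >= 1, mean_depth > 0, depth_dispersion > 0)
    probs <- c(structure_strength, species_structure_strength,
               detection_prob, noise_esv_rate, assigned_fraction)
    if (any(probs < 0) || any(probs > 1))
      stop("probabilities must lie in [0, 1]")
    if (intraspecies_subs[2] > amplicon_length)
      stop("intraspecies_subs exceeds amplicon length")
  })
  structure(cfg, class = "synth_config")
}

#' Introduce an exact number of substitutions into a sequence
#'
#' Picks `n_subs` distinct positions and replaces each base by a different
#' one, so the result is at Hamming distance exactly `n_subs` from the input
#' and has the same length.
#'
#' @param seq DNA string over A/C/G/T.
#' @param n_subs number of substitutions; must not exceed the length.
#' @return mutated sequence.
#' @export
mutate_sequence <- function(seq, n_subs) {
  n <- nchar(seq)
  if (n_subs > n) stop("n_subs exceeds sequence length")
  if (n_subs == 0) return(seq)
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  pos <- sample.int(n, n_subs)
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1)
  }
  paste(chars, collapse = "")
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Species base sequences pairwise >= min_subs apart; random draws at typical
# amplicon lengths are ~75% divergent, so retries are a safety valve for
# short-sequence configs rather than the common path.
draw_species_bases <- function(n_species, len, min_subs, max_tries = 200) {
  bases <- character(0)
  tries <- 0
  while (length(bases) < n_species) {
    cand <- random_sequence(len)
    ok <- all(vapply(bases, function(b) hamming(cand, b) >= min_subs,
                     logical(1)))
    if (ok) {
      bases <- c(bases, cand)
    } else {
      tries <- tries + 1
      if (tries > max_tries)
        stop("could not place ", n_species, " species at >= ", min_subs,
             " substitutions in length ", len)
    }
  }
  bases
}

#' Generate a synthetic ESV dataset with known truth
#'
#' Builds species base sequences, haplotypes, region-structured occurrence,
#' sample coordinates clustered around region centroids inside the study
#' bounding box (lon -118..-113, lat 49..52), negative-binomial read depths
#' per replicate, and spurious low-count noise variants.
#'
#' @param cfg a [synth_config()].
#' @return list of class `synth_dataset` with elements `esv` (an
#'   [esv_table()] of every observed ESV), `metadata` (sample data.frame) and
#'   `truth` (planted structure: species haplotype sequences, haplotype
#'   region sets, sample regions, noise ESV ids).
#' @export
generate_dataset <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  set.seed(cfg$seed)
  L <- cfg$amplicon_length
  bases <- draw_species_bases(cfg$n_species, L, cfg$interspecies_min_subs)

  # haplotypes per species; haplotype 1 is the base sequence
  hap <- list()
  for (s in seq_len(cfg$n_species)) {
    n_h <- sample(seq(cfg$haplotypes_per_species[1],
                      cfg$haplotypes_per_species[2]), 1)
    seqs <- bases[s]
    guard <- 0
    while (length(seqs) < n_h) {
      k <- sample(seq(cfg$intraspecies_subs[1], cfg$intraspecies_subs[2]), 1)
      cand <- mutate_sequence(bases[s], k)
      if (!cand %in% unlist(hap) && !cand %in% seqs) {
        seqs <- c(seqs, cand)
      } else {
        guard <- guard + 1
        if (guard > 100) break
      }
    }
    hap[[s]] <- seqs
  }

  # region occupancy: a species' range is one region or all of them;
  # a private haplotype sits in one region of its species' range,
  # a cosmopolitan one spans the whole range
  regions <- seq_len(cfg$n_regions)
  pick1 <- function(x) x[sample.int(length(x), 1)]
  species_range <- lapply(seq_len(cfg$n_species), function(s) {
    if (runif(1) < cfg$species_structure_strength) pick1(regions)
    else regions
  })
  hap_df <- do.call(rbind, lapply(seq_along(hap), function(s) {
    data.frame(species = sprintf("species_%02d", s), species_idx = s,
               hap_idx = seq_along(hap[[s]]),
               sequence = hap[[s]], stringsAsFactors = FALSE)
  }))
  hap_df$esv_id <- sprintf("ESV%04d", seq_len(nrow(hap_df)))
  hap_regions <- lapply(seq_len(nrow(hap_df)), function(i) {
    rng <- species_range[[hap_df$species_idx[i]]]
    if (runif(1) < cfg$structure_strength) pick1(rng) else rng
  })
  names(hap_regions) <- hap_df$esv_id

  # samples: Gaussian scatter around centroids spaced along the study box
  lon_cent <- if (cfg$n_regions == 1) -115.5 else
    seq(-117.5, -113.5, length.out = cfg$n_regions)
  lat_cent <- rep(50.5, cfg$n_regions)
  md <- do.call(rbind, lapply(regions, function(r) {
    n <- cfg$samples_per_region + cfg$n_wetland_per_region
    data.frame(
      sample_id = sprintf("R%d_S%02d", r, seq_len(n)),
      lat = lat_cent[r] + stats::rnorm(n, 0, cfg$coord_sd),
      lon = lon_cent[r] + stats::rnorm(n, 0, cfg$coord_sd),
      year = sample(2019:2022, n, replace = TRUE),
      wetland = rep(c(FALSE, TRUE),
                    c(cfg$samples_per_region, cfg$n_wetland_per_region)),
      region = r, stringsAsFactors = FALSE)
  }))
  md$lat <- pmin(pmax(md$lat, 49), 52)
  md$lon <- pmin(pmax(md$lon, -118), -113)

  # detection and read depth
  counts <- list()
  present <- matrix(FALSE, nrow(md), nrow(hap_df),
                    dimnames = list(md$sample_id, hap_df$esv_id))
  for (i in seq_len(nrow(hap_df))) {
    eligible <- md$region %in% hap_regions[[i]]
    det <- eligible & runif(nrow(md)) < cfg$detection_prob
    present[, i] <- det
    for (j in which(det)) {
      reads <- stats::rnbinom(cfg$replicate_count, size = cfg$depth_dispersion,
                              mu = cfg$mean_depth)
      keep <- reads > 0
      if (any(keep))
        counts[[length(counts) + 1]] <- data.frame(
          esv_id = hap_df$esv_id[i], sample_id = md$sample_id[j],
          replicate_id = as.character(which(keep)), reads = reads[keep],
          stringsAsFactors = FALSE)
    }
  }

  # spurious one-substitution variants with low counts in one replicate
  noise <- list()
  n_noise <- 0
  for (i in seq_len(nrow(hap_df))) {
    if (runif(1) >= cfg$noise_esv_rate) next
    carriers <- which(present[, i])
    if (!length(carriers)) next
    cand <- mutate_sequence(hap_df$sequence[i], 1)
    if (cand %in% hap_df$sequence ||
        cand %in% vapply(noise, `[[`, "", "sequence")) next
    n_noise <- n_noise + 1
    id <- sprintf("NOISE%03d", n_noise)
    reads <- min(max(stats::rpois(1, 5), 1), 99)
    noise[[n_noise]] <- list(
      esv_id = id, sequence = cand, parent = hap_df$esv_id[i],
      row = data.frame(esv_id = id,
                       sample_id = md$sample_id[sample(carriers, 1)],
                       replicate_id = as.character(
                         sample.int(cfg$replicate_count, 1)),
                       reads = reads, stringsAsFactors = FALSE))
  }

  count_df <- do.call(rbind, c(counts, lapply(noise, `[[`, "row")))
  observed <- unique(count_df$esv_id)

  # taxonomy: true haplotypes assigned with sBP in [0.8, 1]; noise unassigned
  assigned <- runif(nrow(hap_df)) < cfg$assigned_fraction
  esvs <- data.frame(
    esv_id = hap_df$esv_id, amplicon = "SYNTH",
    sequence = hap_df$sequence,
    species = ifelse(assigned, hap_df$species, NA_character_),
    sbp = ifelse(assigned, round(runif(nrow(hap_df), 0.8, 1), 3), NA_real_),
    stringsAsFactors = FALSE)
  if (n_noise > 0)
    esvs <- rbind(esvs, data.frame(
      esv_id = vapply(noise, `[[`, "", "esv_id"), amplicon = "SYNTH",
      sequence = vapply(noise, `[[`, "", "sequence"),
      species = NA_character_, sbp = NA_real_, stringsAsFactors = FALSE))
  esvs <- esvs[esvs$esv_id %in% observed, , drop = FALSE]

  truth <- list(
    species_haplotypes = split(hap_df$esv_id, hap_df$species),
    haplotype_species = stats::setNames(hap_df$species, hap_df$esv_id),
    haplotype_regions = hap_regions,
    species_regions = stats::setNames(species_range,
                                      sprintf("species_%02d",
                                              seq_len(cfg$n_species))),
    sample_regions = stats::setNames(md$region, md$sample_id),
    noise_ids = if (n_noise > 0) vapply(noise, `[[`, "", "esv_id")
                else character(0),
    observed_ids = observed,
    config = cfg)

  structure(list(esv = esv_table(esvs, count_df),
                 metadata = md[c("sample_id", "lat", "lon", "year",
                                 "wetland")],
                 truth = truth),
            class = "synth_dataset")
}

#' Write a synthetic dataset to disk in the pipeline's input formats
#'
#' @param x a `synth_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed); writes `esv_counts.tsv`,
#'   `esv_seqs.fasta`, `taxonomy.tsv` and `samples.csv`.
#' @export
write_synth_dataset <- function(x, dir) {
  stopifnot(inherits(x, "synth_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_esv_table(x$esv,
                  file.path(dir, "esv_counts.tsv"),
                  file.path(dir, "esv_seqs.fasta"),
                  file.path(dir, "taxonomy.tsv"))
  write_sample_metadata(x$metadata, file.path(dir, "samples.csv"))
  invisible(x)
}
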