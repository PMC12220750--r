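# Config-driven end-to-end run: load or simulate an ESV table, filter,
# group samples into regions, cluster (OTU threshold + full hierarchy),
# find SBCs, build community and intraspecific dissimilarity matrices, run
# the scrambled-cluster null and the permutation statistics, and leave a
# machine-readable manifest. Identical config + seed gives byte-identical
# numeric outputs.

default_pipeline_params <- function() {
  list(min_total_reads = 100, min_replicate_reads = 5,
       sbp_threshold = 0.8, otu_target_fraction = 0.03,
       permutations = 9999, scrambles = 1000, alpha = 0.05,
       kmeans_k = NULL, kmeans_range = 2:20, kmeans_pairs = 1000,
       seed = 1L)
}

read_pipeline_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML path")
  if (!is.null(config$input) && !is.null(config$synth))
    stop("config blocks `input` and `synth` are mutually exclusive")
  if (is.null(config$input) && is.null(config$synth))
    stop("config needs an `input` or a `synth` block")
  params <- utils::modifyList(default_pipeline_params(),
                              config$params %||% list())
  list(input = config$input, synth = config$synth, params = params)
}

run_stage <- function(name, log_path, expr) {
  res <- tryCatch(expr, error = function(e)
    stop("stage `", name, "` failed: ", conditionMessage(e), call. = FALSE))
  cat(format(Sys.time(), "%H:%M:%S"), "stage", name, "done\n",
      file = log_path, append = TRUE)
  res
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data loading (or synthesis), the quality-filter
#' chain, k-means region grouping, OTU clustering at the 3%-of-length
#' threshold, the d-hierarchy and SBC search, community Sorensen matrices
#' (ESV / OTU / SBC), intraspecific cluster selection and mean matrices,
#' the scrambled-cluster null, and PERMANOVA / dispersion / Mantel
#' statistics. Outputs (matrices as TSV, reports as JSON) land in
#' `out_dir` together with `manifest.json` recording parameters, seed and
#' md5 hashes of every written file.
#'
#' @param config a list or YAML path with either an `input` block (paths
#'   `counts`, `fasta`, `taxonomy`, `samples`) or a `synth` block
#'   ([synth_config()] arguments), plus an optional `params` block
#'   overriding: min_total_reads (100), min_replicate_reads (5),
#'   sbp_threshold (0.8), otu_target_fraction (0.03), permutations (9999),
#'   scrambles (1000), alpha (0.05), kmeans_k (fixed k; otherwise chosen
#'   as the most stable k over kmeans_range), kmeans_pairs (1000), seed.
#' @param out_dir output directory, created if needed.
#' @return (invisibly) a list with every intermediate result; also written
#'   under `out_dir`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- read_pipeline_config(config)
  p <- cfg$params
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  cat("pipeline start, seed", p$seed, "\n", file = log_path)

  dat <- run_stage("load", log_path, {
    if (!is.null(cfg$synth)) {
      sc <- do.call(synth_config, cfg$synth)
      ds <- generate_dataset(sc)
      list(esv = ds$esv, metadata = ds$metadata, truth = ds$truth)
    } else {
      list(esv = read_esv_table(cfg$input$counts, cfg$input$fasta,
                                cfg$input$taxonomy),
           metadata = read_sample_metadata(cfg$input$samples),
           truth = NULL)
    }
  })

  filt <- run_stage("filter", log_path, {
    res <- apply_filter_chain(dat$esv, min_total = p$min_total_reads,
                              min_replicate = p$min_replicate_reads,
                              samples = dat$metadata$sample_id)
    for (i in seq_len(nrow(res$log)))
      cat("removed", res$log$esv_id[i], res$log$reason[i], "\n",
          file = log_path, append = TRUE)
    res
  })

  regions <- run_stage("regions", log_path, {
    non_wet <- dat$metadata[!dat$metadata$wetland, , drop = FALSE]
    k <- p$kmeans_k
    stab <- NULL
    if (is.null(k)) {
      krange <- p$kmeans_range[p$kmeans_range < nrow(non_wet)]
      stab <- kmeans_stability(dat$metadata, k_range = krange,
                               n_pairs = p$kmeans_pairs, seed = p$seed)
      k <- stable_k(stab)
    }
    ra <- kmeans_regions(dat$metadata, k = k, seed = p$seed)
    list(assignment = ra, stability = stab)
  })
  region_of <- regions$assignment$regions

  # wetland samples are omitted from every region-based analysis
  pres <- filt$presence[rownames(filt$presence) %in% names(region_of), ,
                        drop = FALSE]
  pres <- presence_matrix(pres[, colSums(pres) > 0, drop = FALSE])
  filt_esv <- subset_esv_table(filt$esv, colnames(pres))

  amp_len <- max(nchar(filt_esv$esvs$sequence))
  otu_d <- select_otu_d(amp_len, p$otu_target_fraction)

  otus <- run_stage("cluster_otu", log_path,
                    cluster_at_d(filt_esv, otu_d))
  hier <- run_stage("hierarchy", log_path, build_hierarchy(filt_esv))
  sbcs <- run_stage("sbc", log_path,
                    find_sbcs(hier, assign_species(filt_esv,
                                                   p$sbp_threshold)))

  community <- run_stage("community", log_path, {
    reps <- list(esv = pres,
                 otu = merge_presence_by_cluster(pres, otus),
                 sbc = merge_presence_by_sbc(pres, sbcs))
    lapply(reps, sorensen_matrix)
  })

  intra <- run_stage("intraspecific", log_path, {
    out <- list()
    for (repn in c("otu", "sbc")) {
      clusters <- if (repn == "otu") otus$clusters else sbc_clusters(sbcs)
      ids <- select_intraspecific_clusters(clusters, pres, region_of)
      if (!length(ids)) {
        out[[repn]] <- NULL
        next
      }
      mats <- per_cluster_matrices(pres, clusters[ids])
      mm <- complete_matrix(mean_dissimilarity(mats))
      out[[repn]] <- list(cluster_ids = ids, matrices = mats, mean = mm)
    }
    out
  })

  stats_out <- run_stage("stats", log_path, {
    res <- list()
    for (nm in names(community)) {
      cm <- complete_matrix(community[[nm]])
      res[[paste0("community_", nm)]] <- summarise_region_tests(
        cm, region_of, p)
    }
    for (nm in names(intra)) {
      res[[paste0("intraspecific_", nm)]] <- summarise_region_tests(
        intra[[nm]]$mean, region_of, p)
    }
    res
  })

  nulls <- run_stage("null", log_path, {
    out <- list()
    for (nm in names(intra)) {
      clusters <- if (nm == "otu") otus$clusters else sbc_clusters(sbcs)
      clusters <- clusters[intra[[nm]]$cluster_ids]
      nd <- null_statistic_distribution(
        pres, clusters, regions = region_of,
        observed_samples = rownames(intra[[nm]]$mean),
        n_reps = p$scrambles, statistic = "pseudo_F", seed = p$seed)
      obs <- stats_out[[paste0("intraspecific_", nm)]]$permanova$pseudo_F
      out[[nm]] <- list(distribution = nd,
                        observed = obs,
                        percentile = null_percentile(nd, obs))
    }
    out
  })

  results <- list(esv = filt_esv, presence = pres,
                  regions = regions, otu_d = otu_d, otus = otus,
                  hierarchy = hier, sbcs = sbcs, community = community,
                  intraspecific = intra, stats = stats_out, nulls = nulls,
                  filter_log = filt$log, truth = dat$truth,
                  params = p)
  write_pipeline_outputs(results, out_dir)
  invisible(results)
}

summarise_region_tests <- function(m, region_of, p) {
  g <- region_of[rownames(m)]
  pa <- permanova(m, g, n_perm = p$permutations, seed = p$seed)
  pw <- tryCatch(pairwise_permanova(m, g, n_perm = p$permutations,
                                    seed = p$seed),
                 error = function(e) NULL)
  disp <- tryCatch(beta_dispersion(m, g, n_perm = p$permutations,
                                   seed = p$seed),
                   error = function(e) NULL)
  list(permanova = pa, pairwise = pw, dispersion = disp,
       n_samples = nrow(m))
}

write_pipeline_outputs <- function(results, out_dir) {
  for (nm in names(results$community))
    write_dist_matrix(results$community[[nm]],
                      file.path(out_dir, paste0("community_", nm, ".tsv")))
  for (nm in names(results$intraspecific))
    write_dist_matrix(results$intraspecific[[nm]]$mean,
                      file.path(out_dir,
                                paste0("intraspecific_", nm, "_mean.tsv")))
  otu_map <- data.frame(esv_id = names(results$otus$assignment),
                        cluster = unname(results$otus$assignment))
  utils::write.table(otu_map, file.path(out_dir, "otu_clusters.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  sbc_df <- summary(results$sbcs)
  utils::write.table(sbc_df, file.path(out_dir, "sbc_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(results$filter_log,
                     file.path(out_dir, "filter_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  report <- list(
    params = results$params,
    otu_d = results$otu_d,
    k_regions = results$regions$assignment$k,
    n_esvs = nrow(results$esv$esvs),
    n_otus = length(results$otus$clusters),
    n_sbcs = length(results$sbcs),
    stats = lapply(results$stats, function(s) list(
      pseudo_F = s$permanova$pseudo_F, p = s$permanova$p,
      n_samples = s$n_samples)),
    nulls = lapply(results$nulls, function(x) list(
      observed = x$observed, percentile = x$percentile,
      n_excluded = x$distribution$n_excluded)))
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  files <- setdiff(list.files(out_dir, full.names = TRUE),
                   file.path(out_dir, c("manifest.json", "run.log")))
  manifest <- list(files = as.list(tools::md5sum(files)),
                   seed = results$params$seed,
                   params = results$params)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, force = TRUE)
  invisible(NULL)
}
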