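# Scrambled-cluster null model. ESV membership is shuffled among the
# selected clusters while preserving the number of clusters and every
# cluster's size, destroying within-cluster species identity but keeping
# the dimensional structure of the intraspecific analysis. Repeating the
# mean-matrix construction on many scrambles yields the null distribution
# of a test statistic against which the observed value is placed.

#' Shuffle ESVs among clusters, preserving cluster sizes
#'
#' Uniformly permutes the pooled member ESVs into slots of the original
#' sizes; the cluster-size multiset and the ESV universe are unchanged.
#'
#' @param clusters named list of member esv_id vectors.
#' @return named list of the same shape with shuffled membership.
#' @export
scramble_clusters <- function(clusters) {
  stopifnot(is.list(clusters))
  pool <- unlist(clusters, use.names = FALSE)
  if (anyDuplicated(pool)) stop("clusters must be disjoint")
  shuffled <- sample(pool)
  sizes <- lengths(clusters)
  stats::setNames(split(shuffled, rep(seq_along(sizes), sizes)),
                  names(clusters))
}

#' Null distribution of a statistic over scrambled clusters
#'
#' Per replicate: scramble the cluster membership, rebuild the per-cluster
#' Sorensen matrices, average them, complete the mean matrix, restrict it to
#' the observed intraspecific sample set, and compute the statistic --
#' either the PERMANOVA pseudo-F against region groups or the Spearman
#' correlation with a geodesic distance matrix. Replicates whose completed
#' matrix can no longer support the statistic (fewer than two groups with
#' two samples, or fewer than three samples for the correlation) are
#' excluded and counted.
#'
#' @param esv_presence a [presence_matrix()] (samples x ESVs).
#' @param clusters named list of the observed (qualifying) clusters.
#' @param regions named vector sample_id -> region group (for
#'   `statistic = "pseudo_F"`).
#' @param geo a geodesic [dist_matrix()] (for `statistic = "mantel_rho"`).
#' @param observed_samples sample ids of the observed intraspecific matrix;
#'   each scramble's matrix is restricted to this set. Defaults to all
#'   samples of `esv_presence`.
#' @param n_reps number of scrambles (the study default is 1000).
#' @param statistic `"pseudo_F"` or `"mantel_rho"`.
#' @param seed master seed; spawns one substream per replicate so individual
#'   replicates are reproducible.
#' @return list of class `null_distribution`: `statistic`, `values`
#'   (defined replicates), `n_reps`, `n_excluded`, `seed`.
#' @export
null_statistic_distribution <- function(esv_presence, clusters,
                                        regions = NULL, geo = NULL,
                                        observed_samples = NULL,
                                        n_reps = 1000,
                                        statistic = c("pseudo_F",
                                                      "mantel_rho"),
                                        seed = 1L) {
  statistic <- match.arg(statistic)
  if (statistic == "pseudo_F" && is.null(regions))
    stop("pseudo_F requires region groups")
  if (statistic == "mantel_rho" && is.null(geo))
    stop("mantel_rho requires a geodesic matrix")
  if (is.null(observed_samples)) observed_samples <- rownames(esv_presence)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_reps)
  values <- rep(NA_real_, n_reps)
  for (r in seq_len(n_reps)) {
    set.seed(rep_seeds[r])
    scr <- scramble_clusters(clusters)
    stopifnot(identical(sort(lengths(scr)), sort(lengths(clusters))),
              setequal(unlist(scr), unlist(clusters)))
    mats <- per_cluster_matrices(esv_presence, scr)
    mm <- complete_matrix(mean_dissimilarity(mats))
    mm <- restrict_matrix(mm, observed_samples)
    values[r] <- null_statistic_value(mm, statistic, regions, geo)
  }
  structure(list(statistic = statistic, values = values[!is.na(values)],
                 n_reps = n_reps, n_excluded = sum(is.na(values)),
                 seed = seed),
            class = "null_distribution")
}

null_statistic_value <- function(mm, statistic, regions, geo) {
  if (statistic == "pseudo_F") {
    g <- regions[rownames(mm)]
    sizes <- table(g)
    if (length(sizes) < 2 || sum(sizes >= 2) < 2) return(NA_real_)
    return(permanova_F(unclass(mm)^2, as.integer(factor(g))))
  }
  if (nrow(mm) < 3) return(NA_real_)
  gsub_ids <- intersect(rownames(mm), rownames(geo))
  if (length(gsub_ids) < 3) return(NA_real_)
  m1 <- unclass(restrict_matrix(mm, gsub_ids))
  m2 <- unclass(restrict_matrix(geo, gsub_ids))[rownames(m1), rownames(m1)]
  lt <- lower.tri(m1)
  suppressWarnings(stats::cor(m1[lt], m2[lt], method = "spearman"))
}

#' Where an observed statistic falls within its null distribution
#'
#' @param nd a `null_distribution`.
#' @param observed observed statistic value.
#' @return percentile of the observed value among the null values (fraction
#'   of null values at or below it).
#' @export
null_percentile <- function(nd, observed) {
  stopifnot(inherits(nd, "null_distribution"))
  mean(nd$values <= observed)
}

#' @export
print.null_distribution <- function(x, ...) {
  cat("null_distribution (", x$statistic, "): ", length(x$values),
      " values (", x$n_excluded, " excluded), seed ", x$seed, "\n", sep = "")
  invisible(x)
}
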