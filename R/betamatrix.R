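# Sorensen dissimilarity machinery. Community matrices compare whole
# presence/absence profiles; intraspecific matrices are computed per cluster
# over only the samples that contain the cluster, then averaged pair-wise
# across clusters and completed by greedy removal of the samples with the
# most missing pairs.

#' Sorensen dissimilarity matrix from presence/absence
#'
#' For samples i, j with a shared present features and b, c features unique
#' to each: beta_sor = (b + c) / (2a + b + c). Pairs in which both samples
#' have no present feature are undefined and set missing.
#'
#' @param presence a [presence_matrix()] or logical matrix.
#' @return a [dist_matrix()] with metric `"sorensen"`.
#' @export
sorensen_matrix <- function(presence) {
  p <- unclass(presence) * 1
  a <- tcrossprod(p)                       # shared presences
  n_i <- rowSums(p)
  tot <- outer(n_i, n_i, "+")              # 2a + b + c
  out <- (tot - 2 * a) / tot
  out[tot == 0] <- NA_real_
  diag(out) <- ifelse(n_i > 0, 0, NA_real_)
  dimnames(out) <- list(rownames(presence), rownames(presence))
  dist_matrix(out, metric = "sorensen")
}

#' Per-cluster Sorensen matrices over member ESVs
#'
#' Each cluster's matrix is computed on the presence submatrix of its member
#' ESVs, restricted to the samples in which at least one member occurs;
#' samples free of the cluster are excluded rather than scored as maximally
#' dissimilar. Clusters occupying fewer than two samples yield a matrix with
#' no pairs.
#'
#' @param esv_presence a [presence_matrix()] (samples x ESVs).
#' @param clusters named list of member esv_id vectors (or `esv_partition`).
#' @return named list of [dist_matrix()], one per cluster.
#' @export
per_cluster_matrices <- function(esv_presence, clusters) {
  if (inherits(clusters, "esv_partition")) clusters <- clusters$clusters
  lapply(clusters, function(members) {
    members <- intersect(members, colnames(esv_presence))
    sub <- esv_presence[, members, drop = FALSE]
    keep <- rowSums(sub) > 0
    sorensen_matrix(sub[keep, , drop = FALSE])
  })
}

#' Select clusters eligible for intraspecific analysis
#'
#' A cluster qualifies iff it has at least `min_haplotypes` member ESVs in
#' the presence table and is present (any member ESV) in at least
#' `min_regions` region groups with at least `min_samples_per_region`
#' samples each -- with the defaults, a minimum of 6 samples overall.
#'
#' @param clusters named list of member esv_id vectors (or `esv_partition`).
#' @param esv_presence a [presence_matrix()] (samples x ESVs).
#' @param regions named vector sample_id -> region group covering every
#'   sample of the presence table.
#' @param min_haplotypes minimum member ESVs (default 2).
#' @param min_regions minimum region groups (default 2).
#' @param min_samples_per_region minimum occupied samples per qualifying
#'   region group (default 3).
#' @return character vector of qualifying cluster ids.
#' @export
select_intraspecific_clusters <- function(clusters, esv_presence, regions,
                                          min_haplotypes = 2,
                                          min_regions = 2,
                                          min_samples_per_region = 3) {
  if (inherits(clusters, "esv_partition")) clusters <- clusters$clusters
  samp <- rownames(esv_presence)
  if (!all(samp %in% names(regions)))
    stop("regions must label every sample of the presence table")
  reg <- regions[samp]
  ok <- vapply(clusters, function(members) {
    members <- intersect(members, colnames(esv_presence))
    if (length(members) < min_haplotypes) return(FALSE)
    occupied <- rowSums(esv_presence[, members, drop = FALSE]) > 0
    per_region <- table(reg[occupied])
    sum(per_region >= min_samples_per_region) >= min_regions
  }, logical(1))
  names(clusters)[ok]
}

#' Mean dissimilarity across cluster matrices
#'
#' Entry (i, j) is the arithmetic mean over the matrices in which the pair
#' is defined; pairs defined in no matrix stay missing. The output covers
#' the union of the input sample sets.
#'
#' @param matrices non-empty list of [dist_matrix()].
#' @param metric metric label of the result.
#' @return a [dist_matrix()].
#' @export
mean_dissimilarity <- function(matrices, metric = "mean_sorensen") {
  if (!length(matrices)) stop("no matrices to average")
  samples <- sort(unique(unlist(lapply(matrices, rownames))))
  n <- length(samples)
  acc <- matrix(0, n, n, dimnames = list(samples, samples))
  cnt <- matrix(0L, n, n, dimnames = list(samples, samples))
  for (m in matrices) {
    ids <- rownames(m)
    v <- unclass(m)
    def <- !is.na(v)
    acc[ids, ids] <- acc[ids, ids] + ifelse(def, v, 0)
    cnt[ids, ids] <- cnt[ids, ids] + def
  }
  out <- acc / cnt
  out[cnt == 0] <- NA_real_
  dist_matrix(out, metric = metric)
}

#' Complete a matrix by removing the samples with most missing pairs
#'
#' Iteratively drops the sample carrying the greatest number of missing
#' pairwise values (ties: lexicographically smallest sample id) until no
#' missing dissimilarities remain.
#'
#' @param m a [dist_matrix()].
#' @return a [dist_matrix()] with no missing entries; removed samples in
#'   `attr(, "removed")`.
#' @export
complete_matrix <- function(m) {
  stopifnot(inherits(m, "dist_matrix"))
  v <- unclass(m)
  removed <- character(0)
  repeat {
    miss <- is.na(v)
    diag(miss) <- FALSE
    if (!any(miss)) break
    n_miss <- rowSums(miss)
    worst <- which(n_miss == max(n_miss))
    drop_id <- sort(rownames(v)[worst])[1]
    keep <- rownames(v) != drop_id
    v <- v[keep, keep, drop = FALSE]
    removed <- c(removed, drop_id)
  }
  out <- dist_matrix(v, metric = attr(m, "metric"))
  attr(out, "removed") <- removed
  out
}

#' Restrict a matrix to a subset of samples
#'
#' @param m a [dist_matrix()].
#' @param samples sample ids to keep (order follows `m`).
#' @return a [dist_matrix()] over the intersection.
#' @export
restrict_matrix <- function(m, samples) {
  keep <- rownames(m)[rownames(m) %in% samples]
  dist_matrix(unclass(m)[keep, keep, drop = FALSE],
              metric = attr(m, "metric"))
}
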