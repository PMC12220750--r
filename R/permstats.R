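# Permutation statistics for region-group inference: one-way PERMANOVA with
# exact enumeration when the permutation space is small, pairwise PERMANOVA
# with FDR adjustment, multivariate dispersion homogeneity, the Mantel test
# with Spearman correlation, adjusted Rand index, k-means region grouping
# with a stability curve, and WGS84 geodesic distance matrices.
#
# Monte-Carlo p-values use the add-one convention p = (1 + #{T* >= T_obs}) /
# (1 + n_perm), so p is never zero; exact mode enumerates every distinct
# relabelling and engages automatically when that space is no larger than
# n_perm.

# pseudo-F for a squared-dissimilarity matrix and integer group labels:
# SS_T = sum_{i<j} d2_ij / n, SS_W = sum_g sum_{i<j in g} d2_ij / n_g,
# F = (SS_A / (g-1)) / (SS_W / (n-g))
permanova_F <- function(D2, g) {
  n <- nrow(D2)
  sst <- sum(D2) / (2 * n)
  ssw <- 0
  for (lab in unique(g)) {
    idx <- g == lab
    ng <- sum(idx)
    if (ng > 1) ssw <- ssw + sum(D2[idx, idx]) / (2 * ng)
  }
  ng_groups <- length(unique(g))
  ((sst - ssw) / (ng_groups - 1)) / (ssw / (n - ng_groups))
}

# all distinct arrangements of a label multiset (exact permutation space)
multiset_permutations <- function(g) {
  labs <- sort(unique(g))
  counts <- as.integer(table(factor(g, levels = labs)))
  rec <- function(counts, n_left) {
    if (n_left == 0L) return(list(integer(0)))
    out <- list()
    for (i in seq_along(counts)) {
      if (counts[i] == 0L) next
      cc <- counts
      cc[i] <- cc[i] - 1L
      for (tail in rec(cc, n_left - 1L))
        out[[length(out) + 1L]] <- c(i, tail)
    }
    out
  }
  arr <- rec(counts, length(g))
  do.call(rbind, arr)
}

n_distinct_arrangements <- function(g) {
  counts <- as.integer(table(g))
  round(exp(lgamma(length(g) + 1) - sum(lgamma(counts + 1))))
}

check_complete <- function(m) {
  v <- unclass(m)
  off <- v[upper.tri(v)]
  if (any(is.na(off)))
    stop("matrix has missing pairs; run complete_matrix() first")
  invisible(v)
}

align_groups <- function(m, groups) {
  ids <- rownames(m)
  if (!is.null(names(groups))) {
    if (!all(ids %in% names(groups)))
      stop("groups must label every sample of the matrix")
    groups <- groups[ids]
  } else if (length(groups) != length(ids)) {
    stop("groups length does not match the matrix")
  }
  factor(groups)
}

#' One-way PERMANOVA on a dissimilarity matrix
#'
#' Partitions the total sum of squared dissimilarities into among- and
#' within-group components and tests the pseudo-F ratio by permuting group
#' labels. When the number of distinct relabellings does not exceed
#' `n_perm` (and `exact = "auto"`), every relabelling is enumerated and the
#' p-value is the exact fraction with pseudo-F at least the observed one;
#' otherwise `n_perm` uniform random permutations are drawn and the add-one
#' rule applies.
#'
#' @param m a complete [dist_matrix()].
#' @param groups grouping factor, named by sample id or aligned with the
#'   matrix rows; at least two groups.
#' @param n_perm permutations (default 9999).
#' @param seed RNG seed for the Monte-Carlo mode.
#' @param exact `"auto"`, `"never"` or `"always"`.
#' @return a `permanova_result`: list with `pseudo_F`, `p`, `df_among`,
#'   `df_within`, `n_perm` (permutations actually used), `seed`, `exact`.
#' @export
permanova <- function(m, groups, n_perm = 9999, seed = NULL,
                      exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  check_complete(m)
  g <- as.integer(align_groups(m, groups))
  n <- nrow(m)
  n_groups <- length(unique(g))
  if (n_groups < 2) stop("need at least two groups")
  if (n - n_groups < 1) stop("no within-group degrees of freedom")
  D2 <- unclass(m)^2
  f_obs <- permanova_F(D2, g)
  n_space <- n_distinct_arrangements(g)
  use_exact <- exact == "always" || (exact == "auto" && n_space <= n_perm)
  if (use_exact) {
    arr <- multiset_permutations(g)
    f_all <- apply(arr, 1, function(gp) permanova_F(D2, gp))
    p <- mean(f_all >= f_obs - 1e-12)
    n_used <- nrow(arr)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm)) {
      if (permanova_F(D2, sample(g)) >= f_obs - 1e-12) hits <- hits + 1L
    }
    p <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(pseudo_F = f_obs, p = p, df_among = n_groups - 1L,
                 df_within = n - n_groups, n_perm = n_used,
                 seed = seed, exact = use_exact),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g (df %d, %d), p = %.4g (%s, %d perms)\n",
    x$pseudo_F, x$df_among, x$df_within, x$p,
    if (x$exact) "exact" else "Monte-Carlo", x$n_perm))
  invisible(x)
}

#' Pairwise PERMANOVA between groups with FDR adjustment
#'
#' One test per unordered group pair on the submatrix of those groups'
#' samples; p-values are Benjamini-Hochberg adjusted across pairs.
#'
#' @inheritParams permanova
#' @return data.frame with columns group1, group2, n, pseudo_F, p, p_adj.
#' @export
pairwise_permanova <- function(m, groups, n_perm = 9999, seed = NULL) {
  g <- align_groups(m, groups)
  levs <- levels(droplevels(g))
  if (length(levs) < 2) stop("need at least two groups")
  pairs <- utils::combn(levs, 2)
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, ncol(pairs))
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    keep <- g %in% pairs[, i]
    sm <- restrict_matrix(m, rownames(m)[keep])
    res <- permanova(sm, stats::setNames(as.character(g[keep]),
                                         rownames(m)[keep]),
                     n_perm = n_perm, seed = sub_seeds[i])
    data.frame(group1 = pairs[1, i], group2 = pairs[2, i],
               n = nrow(sm), pseudo_F = res$pseudo_F, p = res$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Homogeneity of multivariate dispersion between groups
#'
#' Embeds the dissimilarity matrix by principal coordinates (with the
#' standard imaginary-axis correction for negative eigenvalues), measures
#' each sample's distance to its group's spatial median, and permutation-
#' tests the one-way F on those distances (via [vegan::betadisper()] and
#' [vegan::permutest.betadisper()]). Groups with a single sample carry no
#' spread information and are dropped before the test.
#'
#' @inheritParams permanova
#' @param type `"median"` (default) or `"centroid"`.
#' @return list of class `dispersion_result`: `F`, `p`, `group_dispersion`
#'   (mean distance-to-median per group), `dropped_groups`, `n_perm`,
#'   `seed`.
#' @export
beta_dispersion <- function(m, groups, n_perm = 9999, seed = NULL,
                            type = c("median", "centroid")) {
  type <- match.arg(type)
  check_complete(m)
  g <- align_groups(m, groups)
  sizes <- table(g)
  dropped <- names(sizes)[sizes < 2]
  if (length(dropped)) {
    keep <- !(as.character(g) %in% dropped)
    m <- restrict_matrix(m, rownames(m)[keep])
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2) stop("need at least two groups of size >= 2")
  if (all(unclass(m) == 0)) stop("degenerate all-zero matrix")
  bd <- vegan::betadisper(stats::as.dist(unclass(m)), g, type = type)
  if (!is.null(seed)) set.seed(seed)
  pt <- vegan::permutest(bd, permutations = n_perm)
  structure(list(F = unname(pt$tab$F[1]),
                 p = unname(pt$tab[["Pr(>F)"]][1]),
                 group_dispersion = tapply(bd$distances, g, mean),
                 dropped_groups = dropped,
                 n_perm = n_perm, seed = seed),
            class = "dispersion_result")
}

#' @export
print.dispersion_result <- function(x, ...) {
  cat(sprintf("Dispersion homogeneity: F = %.4g, p = %.4g (%d perms)\n",
              x$F, x$p, x$n_perm))
  invisible(x)
}

# all permutations of 1..n as rows (n small)
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

#' Mantel test with Spearman rank correlation
#'
#' Correlates the lower triangles of two complete dissimilarity matrices
#' over the same samples; rho is 1 for any strictly increasing monotonic
#' relationship and -1 for a strictly decreasing one. Significance comes
#' from simultaneous row/column permutations of the second matrix (exact
#' enumeration of all n! permutations when that is no larger than
#' `n_perm`; one-sided, large rho).
#'
#' @param m1,m2 complete [dist_matrix()] over the same sample set (order
#'   may differ).
#' @inheritParams permanova
#' @return a `mantel_result`: list with `rho`, `p`, `n_perm`, `seed`,
#'   `exact`.
#' @export
mantel_spearman <- function(m1, m2, n_perm = 9999, seed = NULL,
                            exact = c("auto", "never", "always")) {
  exact <- match.arg(exact)
  if (!setequal(rownames(m1), rownames(m2)))
    stop("matrices cover different sample sets")
  v1 <- check_complete(m1)
  m2 <- restrict_matrix(m2, rownames(m1))
  v2 <- check_complete(m2)[rownames(m1), rownames(m1)]
  n <- nrow(v1)
  if (n < 3) stop("need at least three samples")
  lt <- lower.tri(v1)
  rho_of <- function(perm) {
    vp <- v2[perm, perm]
    suppressWarnings(stats::cor(v1[lt], vp[lt], method = "spearman"))
  }
  rho_obs <- rho_of(seq_len(n))
  n_space <- round(exp(lgamma(n + 1)))
  use_exact <- exact == "always" || (exact == "auto" && n_space <= n_perm)
  if (use_exact) {
    perms <- all_permutations(n)
    rho_all <- apply(perms, 1, rho_of)
    p <- mean(rho_all >= rho_obs - 1e-12)
    n_used <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    hits <- 0L
    for (i in seq_len(n_perm))
      if (rho_of(sample.int(n)) >= rho_obs - 1e-12) hits <- hits + 1L
    p <- (1 + hits) / (1 + n_perm)
    n_used <- n_perm
  }
  structure(list(rho = rho_obs, p = p, n_perm = n_used, seed = seed,
                 exact = use_exact),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel (Spearman): rho = %.4g, p = %.4g (%s, %d perms)\n",
              x$rho, x$p, if (x$exact) "exact" else "Monte-Carlo",
              x$n_perm))
  invisible(x)
}

#' Adjusted Rand index between two labelings
#'
#' Hubert-Arabie chance-corrected Rand index from the contingency table;
#' 1 for identical partitions (up to label names), about 0 for independent
#' ones.
#'
#' @param labels1,labels2 vectors of cluster labels over the same items.
#' @return numeric adjusted Rand index.
#' @export
adjusted_rand <- function(labels1, labels2) {
  if (length(labels1) != length(labels2))
    stop("labelings cover different item sets")
  tab <- table(labels1, labels2)
  n <- length(labels1)
  sum_ij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  max_idx <- (a + b) / 2
  if (abs(max_idx - expected) < 1e-12) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

#' Group samples into geographic regions by k-means
#'
#' Standard k-means on raw (lat, lon) decimal degrees. Wetland-flagged
#' samples are excluded before clustering (they are omitted from the
#' analysis).
#'
#' @param metadata sample metadata data.frame (sample_id, lat, lon, year,
#'   wetland).
#' @param k number of region groups.
#' @param n_starts random restarts (default 10).
#' @param seed RNG seed.
#' @return a `region_assignment`: list with `regions` (named vector
#'   sample_id -> region label), `k`, `wss` (total within-cluster sum of
#'   squares), `centers`.
#' @export
kmeans_regions <- function(metadata, k, n_starts = 10, seed = NULL) {
  md <- validate_sample_metadata(metadata)
  md <- md[!md$wetland, , drop = FALSE]
  if (k > nrow(md)) stop("k exceeds the number of non-wetland samples")
  if (!is.null(seed)) set.seed(seed)
  if (k == nrow(md)) {
    # trivial partition: every sample its own region, zero within-cluster SS
    centers <- cbind(md$lat, md$lon)
    rownames(centers) <- NULL
    return(structure(list(regions = stats::setNames(seq_len(k),
                                                    md$sample_id),
                          k = as.integer(k), wss = 0, centers = centers),
                     class = "region_assignment"))
  }
  km <- stats::kmeans(cbind(md$lat, md$lon), centers = k,
                      nstart = n_starts)
  structure(list(regions = stats::setNames(km$cluster, md$sample_id),
                 k = as.integer(k), wss = km$tot.withinss,
                 centers = km$centers),
            class = "region_assignment")
}

#' k-means stability and within-cluster sum-of-squares curves
#'
#' For each candidate number of region groups, repeatedly runs two
#' independent k-means clusterings and records the adjusted Rand index
#' between them; k values whose optimal partition is unambiguous give
#' indices at 1, while k values beyond the natural group count split
#' groups arbitrarily and destabilise. Each clustering takes the best of
#' `n_starts_per_run` random starts, so residual disagreement between a
#' pair reflects genuine ambiguity among near-optimal partitions rather
#' than failure of the local search: with a single random start the curve
#' is dominated by initialisation noise at every k (random initial centers
#' regularly seed one group twice and the search cannot escape) and
#' identifies nothing. Also reports the total within-cluster sum of
#' squares per k for elbow inspection.
#'
#' @param metadata sample metadata data.frame.
#' @param k_range candidate k values (study default 2..20).
#' @param n_pairs clustering pairs per k (study default 1000).
#' @param n_starts_per_run random starts within each clustering of a pair.
#' @param seed RNG seed.
#' @return a `kmeans_stability` list: `stability` (data.frame k, mean_ari,
#'   min_ari), `ari` (n_pairs x k matrix), `wss` (data.frame k, wss),
#'   `seed`.
#' @seealso [stable_k()] for the k-selection rule.
#' @export
kmeans_stability <- function(metadata, k_range = 2:20, n_pairs = 1000,
                             n_starts_per_run = 20, seed = 1L) {
  md <- validate_sample_metadata(metadata)
  md <- md[!md$wetland, , drop = FALSE]
  coords <- cbind(md$lat, md$lon)
  if (max(k_range) > nrow(md)) stop("k exceeds the number of samples")
  set.seed(seed)
  ari <- matrix(NA_real_, n_pairs, length(k_range),
                dimnames = list(NULL, paste0("k", k_range)))
  wss <- numeric(length(k_range))
  for (j in seq_along(k_range)) {
    k <- k_range[j]
    wss[j] <- stats::kmeans(coords, k, nstart = 10)$tot.withinss
    for (i in seq_len(n_pairs)) {
      c1 <- stats::kmeans(coords, k, nstart = n_starts_per_run)$cluster
      c2 <- stats::kmeans(coords, k, nstart = n_starts_per_run)$cluster
      ari[i, j] <- adjusted_rand(c1, c2)
    }
  }
  structure(list(stability = data.frame(k = k_range,
                                        mean_ari = colMeans(ari),
                                        min_ari = apply(ari, 2, min)),
                 ari = ari,
                 wss = data.frame(k = k_range, wss = wss),
                 seed = seed),
            class = "kmeans_stability")
}

#' Most stable number of region groups
#'
#' The largest k attaining the maximum mean adjusted Rand index: stability
#' is trivially high for k below the natural group count (coarse merges are
#' unambiguous), so among equally stable candidates the finest partition is
#' the informative one, and k values beyond the natural count destabilise.
#'
#' @param ks a `kmeans_stability` result.
#' @param tol tolerance on "attaining the maximum".
#' @return integer k.
#' @export
stable_k <- function(ks, tol = 1e-9) {
  stopifnot(inherits(ks, "kmeans_stability"))
  s <- ks$stability
  max(s$k[s$mean_ari >= max(s$mean_ari) - tol])
}

#' WGS84 geodesic distance matrix between sampling locations
#'
#' Pairwise geodesic distances on the WGS84 ellipsoid, in meters,
#' accounting for the shape of the Earth (via [geosphere::distGeo()]'s
#' ellipsoidal algorithm; great-circle approximations are not used).
#'
#' @param metadata sample metadata data.frame.
#' @return a [dist_matrix()] in meters with metric `"geodesic_m"`.
#' @export
geodesic_matrix <- function(metadata) {
  md <- validate_sample_metadata(metadata)
  D <- geosphere::distm(cbind(md$lon, md$lat), fun = geosphere::distGeo)
  D <- (D + t(D)) / 2
  diag(D) <- 0
  dimnames(D) <- list(md$sample_id, md$sample_id)
  dist_matrix(D, metric = "geodesic_m")
}

#' PERMANOVA on every individual cluster matrix
#'
#' Completes each cluster's dissimilarity matrix separately, tests region
#' separation per cluster, and Benjamini-Hochberg-adjusts the p-values
#' across the testable clusters. Clusters left with fewer than two region
#' groups of two samples after completion are recorded as untestable and
#' excluded from the FDR family.
#'
#' @param matrices named list of per-cluster [dist_matrix()] (from
#'   [per_cluster_matrices()]).
#' @param regions named vector sample_id -> region group.
#' @inheritParams permanova
#' @param alpha significance threshold for the summary (default 0.05).
#' @return data.frame (cluster, n, pseudo_F, p, p_adj, testable) with
#'   attributes `n_testable`, `n_significant`, `frac_significant`.
#' @export
per_cluster_permanova <- function(matrices, regions, n_perm = 9999,
                                  seed = NULL, alpha = 0.05) {
  if (!is.null(seed)) set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max, max(length(matrices), 1))
  rows <- lapply(seq_along(matrices), function(i) {
    cm <- complete_matrix(matrices[[i]])
    g <- regions[rownames(cm)]
    sizes <- table(g)
    testable <- nrow(cm) >= 4 && sum(sizes >= 2) >= 2 &&
      length(sizes[sizes > 0]) >= 2
    if (!testable)
      return(data.frame(cluster = names(matrices)[i], n = nrow(cm),
                        pseudo_F = NA_real_, p = NA_real_,
                        testable = FALSE, stringsAsFactors = FALSE))
    res <- permanova(cm, g, n_perm = n_perm, seed = sub_seeds[i])
    data.frame(cluster = names(matrices)[i], n = nrow(cm),
               pseudo_F = res$pseudo_F, p = res$p, testable = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- NA_real_
  out$p_adj[out$testable] <- stats::p.adjust(out$p[out$testable],
                                             method = "BH")
  attr(out, "n_testable") <- sum(out$testable)
  attr(out, "n_significant") <- sum(out$p_adj < alpha, na.rm = TRUE)
  attr(out, "frac_significant") <-
    if (any(out$testable)) mean(out$p_adj[out$testable] < alpha) else NA_real_
  out
}
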