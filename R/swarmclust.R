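# SWARM-style clustering with no OTU breaking: clusters are the connected
# components of the graph joining two ESVs whenever their Levenshtein
# distance (substitutions + indels) is at most d. With breaking disabled the
# cited tool computes exactly this transitive closure, so the components are
# built directly from the all-pairs distance matrix. The d-hierarchy grows d
# from 0 until all ESVs fall into a single cluster; nesting is guaranteed
# because the edge set only grows with d.

#' Number of differences between two sequences
#'
#' Levenshtein edit distance: substitutions and single-base indels each
#' count one difference. For equal-length sequences with no indels this
#' coincides with the Hamming distance.
#'
#' @param a,b DNA strings.
#' @return integer edit distance.
#' @export
sequence_differences <- function(a, b) {
  as.integer(utils::adist(a, b))
}

# all-pairs Levenshtein distances, named square matrix
esv_distances <- function(seqs) {
  D <- utils::adist(seqs)
  dimnames(D) <- list(names(seqs), names(seqs))
  D
}

# extract named sequence vector from the accepted inputs
esv_sequences <- function(x) {
  if (inherits(x, "esv_table"))
    return(stats::setNames(x$esvs$sequence, x$esvs$esv_id))
  if (is.character(x)) {
    if (is.null(names(x))) stop("sequences must be named by esv_id")
    return(x)
  }
  stop("expected an esv_table or a named character vector of sequences")
}

#' Select the OTU clustering threshold for an amplicon length
#'
#' Returns the integer number of differences d (at least 1) whose ratio to
#' the amplicon length is closest to the target fraction (3% by default);
#' ties break toward the smaller d.
#'
#' @param amplicon_length amplicon length in nt.
#' @param target_fraction target divergence (default 0.03).
#' @return integer d.
#' @export
select_otu_d <- function(amplicon_length, target_fraction = 0.03) {
  stopifnot(amplicon_length > 0)
  lo <- max(1L, as.integer(floor(target_fraction * amplicon_length)))
  cand <- unique(c(lo, lo + 1L))
  err <- abs(cand / amplicon_length - target_fraction)
  cand[which.min(err)]  # which.min takes the first, i.e. the smaller d
}

#' Cluster ESVs at a fixed number of differences
#'
#' Single-linkage transitive closure: two ESVs share a cluster iff they are
#' joined by a chain of pairwise distances each at most `d`. Cluster ids are
#' the lexicographically smallest member esv_id.
#'
#' @param x an [esv_table()] or named character vector of sequences.
#' @param d maximum number of differences joining two ESVs.
#' @return an `esv_partition`: list with `d`, `assignment` (named vector
#'   esv_id -> cluster id) and `clusters` (named list of member ids).
#' @export
cluster_at_d <- function(x, d) {
  seqs <- esv_sequences(x)
  if (!length(seqs)) stop("no sequences to cluster")
  D <- esv_distances(seqs)
  comp <- components_at_d(D, d)
  make_partition(names(seqs), comp, d)
}

# union-find with path compression
uf_new <- function(n) seq_len(n)
uf_find <- function(parent, i) {
  while (parent[i] != i) i <- parent[i]
  i
}
uf_union <- function(parent, i, j) {
  ri <- uf_find(parent, i); rj <- uf_find(parent, j)
  if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
  parent
}

components_at_d <- function(D, d) {
  n <- nrow(D)
  parent <- uf_new(n)
  if (n > 1) {
    idx <- which(upper.tri(D) & D <= d, arr.ind = TRUE)
    if (nrow(idx))
      for (k in seq_len(nrow(idx)))
        parent <- uf_union(parent, idx[k, 1], idx[k, 2])
  }
  vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
}

make_partition <- function(ids, comp, d) {
  groups <- split(ids, comp)
  cl_ids <- vapply(groups, function(g) min(g), character(1))
  names(groups) <- cl_ids
  groups <- groups[order(cl_ids)]
  assignment <- stats::setNames(rep(names(groups), lengths(groups)),
                                unlist(groups, use.names = FALSE))
  assignment <- assignment[ids]
  structure(list(d = as.integer(d), assignment = assignment,
                 clusters = groups),
            class = "esv_partition")
}

#' @export
print.esv_partition <- function(x, ...) {
  cat("esv_partition: d =", x$d, "--", length(x$clusters), "clusters over",
      length(x$assignment), "ESVs\n")
  invisible(x)
}

#' Build the full d-hierarchy of partitions
#'
#' Starts at d = 0 and increases d by one until all ESVs fall into a single
#' cluster; each partition at d + 1 is a coarsening of the one at d.
#'
#' @param x an [esv_table()] or named character vector of sequences.
#' @return an `esv_hierarchy`: list of `esv_partition` for d = 0..d_single.
#' @export
build_hierarchy <- function(x) {
  seqs <- esv_sequences(x)
  if (!length(seqs)) stop("no sequences to cluster")
  D <- esv_distances(seqs)
  n <- length(seqs)
  ids <- names(seqs)
  parent <- uf_new(n)
  # pairs grouped by distance so each d-step only adds the new edges
  ut <- which(upper.tri(D), arr.ind = TRUE)
  dist_of <- if (nrow(ut)) D[ut] else integer(0)
  partitions <- list()
  d <- 0L
  repeat {
    if (length(dist_of)) {
      new_edges <- which(dist_of == d)
      for (k in new_edges)
        parent <- uf_union(parent, ut[k, 1], ut[k, 2])
    }
    comp <- vapply(seq_len(n), function(i) uf_find(parent, i), integer(1))
    partitions[[d + 1L]] <- make_partition(ids, comp, d)
    if (length(unique(comp)) == 1L) break
    d <- d + 1L
  }
  structure(partitions, class = "esv_hierarchy")
}

#' @export
print.esv_hierarchy <- function(x, ...) {
  cat("esv_hierarchy: d = 0..", x[[length(x)]]$d, " over ",
      length(x[[1]]$assignment), " ESVs\n", sep = "")
  invisible(x)
}

#' Merge presence columns by cluster membership
#'
#' One column per cluster, the logical OR over its member ESV columns.
#' Features belonging to no cluster are dropped from the merged matrix.
#'
#' @param presence a [presence_matrix()] (samples x ESVs).
#' @param clusters named list of member esv_id vectors, or an
#'   `esv_partition`.
#' @return a [presence_matrix()] (samples x clusters).
#' @export
merge_presence_by_cluster <- function(presence, clusters) {
  if (inherits(clusters, "esv_partition")) clusters <- clusters$clusters
  stopifnot(is.list(clusters))
  cols <- lapply(clusters, function(members) {
    members <- intersect(members, colnames(presence))
    if (!length(members)) return(rep(FALSE, nrow(presence)))
    rowSums(presence[, members, drop = FALSE]) > 0
  })
  m <- do.call(cbind, cols)
  dimnames(m) <- list(rownames(presence), names(clusters))
  presence_matrix(m)
}
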