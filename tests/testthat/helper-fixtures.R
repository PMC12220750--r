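# Shared fixture builders and independent oracles.

# tiny esv_table built in code
toy_table <- function(seqs, counts = NULL, species = NULL, sbp = NULL) {
  ids <- names(seqs)
  esvs <- data.frame(esv_id = ids, amplicon = "AMP", sequence = unname(seqs),
                     stringsAsFactors = FALSE)
  if (!is.null(species)) {
    esvs$species <- species[ids]
    esvs$sbp <- sbp[ids]
  }
  if (is.null(counts))
    counts <- data.frame(esv_id = ids, sample_id = "s1", replicate_id = "1",
                         reads = 1000, stringsAsFactors = FALSE)
  esv_table(esvs, counts)
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

# random valid symmetric dissimilarity matrix with distinct entries
random_dist <- function(n, seed = NULL, missing_pairs = 0) {
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  v <- matrix(0, n, n, dimnames = list(ids, ids))
  vals <- sample(seq_len(n * (n - 1) / 2)) / (n * (n - 1) / 2 + 1)
  v[lower.tri(v)] <- vals
  v <- v + t(v)
  if (missing_pairs > 0) {
    idx <- which(lower.tri(v), arr.ind = TRUE)
    pick <- idx[sample.int(nrow(idx), missing_pairs), , drop = FALSE]
    for (r in seq_len(nrow(pick))) {
      v[pick[r, 1], pick[r, 2]] <- NA
      v[pick[r, 2], pick[r, 1]] <- NA
    }
  }
  dist_matrix(v)
}

random_presence <- function(n_samples, n_features, p = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- matrix(runif(n_samples * n_features) < p, n_samples, n_features,
              dimnames = list(sprintf("s%02d", seq_len(n_samples)),
                              sprintf("f%02d", seq_len(n_features))))
  presence_matrix(m)
}

# --- independent oracles ---------------------------------------------------

# Sorensen by naive per-pair set arithmetic
oracle_sorensen <- function(presence) {
  n <- nrow(presence)
  out <- matrix(NA_real_, n, n,
                dimnames = list(rownames(presence), rownames(presence)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    fi <- colnames(presence)[presence[i, ]]
    fj <- colnames(presence)[presence[j, ]]
    a <- length(intersect(fi, fj))
    b <- length(setdiff(fi, fj))
    cc <- length(setdiff(fj, fi))
    if (2 * a + b + cc > 0) out[i, j] <- (b + cc) / (2 * a + b + cc)
  }
  out
}

# connected components of the <= d graph via single-linkage dendrogram
oracle_components <- function(seqs, d) {
  if (length(seqs) == 1) return(stats::setNames(1L, names(seqs)))
  D <- utils::adist(seqs)
  dimnames(D) <- list(names(seqs), names(seqs))
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  stats::cutree(hc, h = d + 0.5)
}

# pseudo-F recomputed from first principles for one labelling
oracle_pseudo_F <- function(m, groups) {
  d2 <- unclass(m)^2
  n <- nrow(d2)
  sst <- sum(d2[upper.tri(d2)]) / n
  ssw <- 0
  for (g in unique(groups)) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      ssw <- ssw + sum(d2[idx, idx][upper.tri(diag(length(idx)))]) /
        length(idx)
  }
  g <- length(unique(groups))
  ((sst - ssw) / (g - 1)) / (ssw / (n - g))
}

# exhaustive SBC search: enumerate every cluster of every partition
oracle_sbcs <- function(hierarchy, assignment) {
  species <- sort(unique(assignment[!is.na(assignment)]))
  found <- list()
  for (s in species) {
    own <- names(assignment)[!is.na(assignment) & assignment == s]
    foreign <- names(assignment)[!is.na(assignment) & assignment != s]
    sets <- character(0)
    for (p in hierarchy) for (cl in p$clusters) {
      if (all(own %in% cl) && !any(foreign %in% cl))
        sets <- union(sets, paste(sort(cl), collapse = "|"))
    }
    if (length(sets)) found[[s]] <- sets
  }
  found
}
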