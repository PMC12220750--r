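# Post-denoising quality control. The chain, in fixed order:
#   1. frameshift/length screen via end-gap-only alignment to the modal-
#      length block (a COI amplicon is protein coding, so genuine sequences
#      align without internal gaps),
#   2. removal of ESVs with fewer than 100 reads in total,
#   3. zeroing of sample-replicate cells with fewer than 5 reads
#      (guards against tag-switching),
#   4. pooling of replicates to presence/absence per sample.

#' Remove putative frameshifted ESVs
#'
#' Aligns every sequence against the modal-length sequence block with gap
#' placement allowed only at the ends (internal gap opening prohibitively
#' penalised). Any sequence that would need a leading gap or leave unaligned
#' trailing sequence -- i.e. any sequence whose length differs from the modal
#' length -- is removed as a putative artifact. With internal gaps forbidden,
#' equal-length sequences always align cleanly, so the screen retains exactly
#' the modal-length sequences. The modal length is computed on the raw input;
#' ties go to the length carrying more total reads, then to the shorter.
#'
#' @param x an [esv_table()] whose ESVs share one amplicon label.
#' @return the filtered `esv_table`; removed ids in `attr(, "removed")`.
#' @export
msa_frameshift_filter <- function(x) {
  stopifnot(inherits(x, "esv_table"))
  if (nrow(x$esvs) == 0) return(x)
  if (length(unique(x$esvs$amplicon)) > 1)
    stop("frameshift filter expects a single amplicon; split the table first")
  len <- nchar(x$esvs$sequence)
  tab <- table(len)
  modal_counts <- as.integer(tab)
  cand <- as.integer(names(tab))[modal_counts == max(modal_counts)]
  if (length(cand) > 1) {
    reads_by_len <- vapply(cand, function(L) {
      ids <- x$esvs$esv_id[len == L]
      sum(x$counts$reads[x$counts$esv_id %in% ids])
    }, numeric(1))
    cand <- cand[reads_by_len == max(reads_by_len)]
    cand <- min(cand)
  }
  keep <- len == cand
  removed <- x$esvs$esv_id[!keep]
  out <- subset_esv_table(x, x$esvs$esv_id[keep])
  attr(out, "removed") <- removed
  out
}

#' Remove low-abundance ESVs
#'
#' An ESV is retained iff its reads summed over every sample and replicate
#' reach `min_total` (strict "fewer than" removal).
#'
#' @param x an [esv_table()].
#' @param min_total minimum total read count (default 100).
#' @return filtered `esv_table`; removed ids in `attr(, "removed")`.
#' @export
filter_min_total_reads <- function(x, min_total = 100) {
  stopifnot(inherits(x, "esv_table"))
  totals <- tapply(x$counts$reads, x$counts$esv_id, sum)
  totals <- totals[x$esvs$esv_id]
  totals[is.na(totals)] <- 0
  keep <- totals >= min_total
  removed <- x$esvs$esv_id[!keep]
  out <- subset_esv_table(x, x$esvs$esv_id[keep])
  attr(out, "removed") <- removed
  out
}

#' Zero out low-read sample-replicate cells
#'
#' Any (ESV, sample, replicate) cell with fewer than `min_reads` reads is set
#' to zero; cells at or above the threshold are untouched. ESV records whose
#' every cell is zeroed are kept in the table (they drop out at pooling).
#'
#' @param x an [esv_table()].
#' @param min_reads per-cell minimum (default 5).
#' @return `esv_table` with cells below threshold removed.
#' @export
filter_replicate_min <- function(x, min_reads = 5) {
  stopifnot(inherits(x, "esv_table"))
  out <- x
  out$counts <- x$counts[x$counts$reads >= min_reads, , drop = FALSE]
  rownames(out$counts) <- NULL
  attr(out, "removed") <- NULL
  out
}

#' Pool replicates into a presence/absence matrix
#'
#' An ESV is present in a sample iff the sum of reads over that sample's
#' replicates is positive. Feature columns that end up absent from every
#' sample are dropped; samples with no presences are retained so the sample
#' axis stays aligned with the metadata.
#'
#' @param x an [esv_table()] (replicate filter already applied).
#' @param samples sample universe for the rows; defaults to the samples seen
#'   in the count table.
#' @return a [presence_matrix()] (samples x ESVs).
#' @export
pool_replicates <- function(x, samples = NULL) {
  stopifnot(inherits(x, "esv_table"))
  if (is.null(samples)) samples <- sort(unique(x$counts$sample_id))
  pooled <- tapply(x$counts$reads,
                   list(x$counts$sample_id, x$counts$esv_id), sum)
  m <- matrix(FALSE, length(samples), nrow(x$esvs),
              dimnames = list(samples, x$esvs$esv_id))
  if (!is.null(pooled)) {
    rows <- intersect(rownames(pooled), samples)
    cols <- intersect(colnames(pooled), x$esvs$esv_id)
    sub <- pooled[rows, cols, drop = FALSE]
    sub[is.na(sub)] <- 0
    m[rows, cols] <- sub > 0
  }
  m <- m[, colSums(m) > 0, drop = FALSE]
  presence_matrix(m)
}

#' Run the full quality-filter chain
#'
#' Fixed order: frameshift screen, total-read filter, replicate-cell filter,
#' replicate pooling. The chain is idempotent.
#'
#' @param x an [esv_table()].
#' @param min_total total-read threshold (default 100).
#' @param min_replicate per-cell threshold (default 5).
#' @param samples sample universe passed to [pool_replicates()].
#' @return list with `presence` (the pooled [presence_matrix()]), `esv` (the
#'   filtered table) and `log` (data.frame of removed ESVs with a reason:
#'   `frameshift`, `low_total` or `empty_after_replicate_filter`).
#' @export
apply_filter_chain <- function(x, min_total = 100, min_replicate = 5,
                               samples = NULL) {
  removal_log <- function(f, reason) {
    ids <- attr(f, "removed") %||% character(0)
    data.frame(esv_id = ids, reason = rep(reason, length(ids)),
               stringsAsFactors = FALSE)
  }
  f1 <- msa_frameshift_filter(x)
  log1 <- removal_log(f1, "frameshift")
  f2 <- filter_min_total_reads(f1, min_total)
  log2 <- removal_log(f2, "low_total")
  f3 <- filter_replicate_min(f2, min_replicate)
  emptied <- setdiff(f3$esvs$esv_id, unique(f3$counts$esv_id))
  log3 <- data.frame(esv_id = emptied,
                     reason = rep("empty_after_replicate_filter",
                                  length(emptied)),
                     stringsAsFactors = FALSE)
  pres <- pool_replicates(f3, samples = samples)
  list(presence = pres, esv = f3, log = rbind(log1, log2, log3))
}

subset_esv_table <- function(x, keep_ids) {
  out <- x
  out$esvs <- x$esvs[x$esvs$esv_id %in% keep_ids, , drop = FALSE]
  out$counts <- x$counts[x$counts$esv_id %in% keep_ids, , drop = FALSE]
  rownames(out$esvs) <- NULL
  rownames(out$counts) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
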