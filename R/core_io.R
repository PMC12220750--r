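# Domain data model: ESV tables, sample metadata, presence and dissimilarity
# matrices, plus readers/writers for the plain-text formats the pipeline uses.
#
# ESV count tables are long-format TSV (one row per ESV x sample x replicate
# with reads > 0; absent rows mean zero), sequences travel as FASTA, taxonomy
# as TSV (esv_id, species, sbp), sample metadata as CSV, and matrices as TSV
# with a leading header row/column of sample ids.

#' Construct an ESV table
#'
#' Bundles per-ESV annotation (amplicon, sequence, optional species call with
#' its species-level bootstrap proportion, sBP) with long-format read counts
#' per sample and field replicate.
#'
#' @param esvs data.frame with columns `esv_id`, `amplicon`, `sequence`, and
#'   optionally `species` (NA = unassigned) and `sbp` (in `[0,1]`; must be
#'   present exactly when `species` is).
#' @param counts data.frame with columns `esv_id`, `sample_id`,
#'   `replicate_id`, `reads` (non-negative integers). Rows with zero reads are
#'   dropped; absent rows mean zero.
#' @return An object of class `esv_table`: a list with elements `esvs` and
#'   `counts`.
#' @export
esv_table <- function(esvs, counts) {
  esvs <- as.data.frame(esvs, stringsAsFactors = FALSE)
  counts <- as.data.frame(counts, stringsAsFactors = FALSE)
  need <- c("esv_id", "amplicon", "sequence")
  if (!all(need %in% names(esvs)))
    stop("`esvs` must have columns: ", paste(need, collapse = ", "))
  if (is.null(esvs$species)) esvs$species <- NA_character_
  if (is.null(esvs$sbp)) esvs$sbp <- NA_real_
  esvs$esv_id <- as.character(esvs$esv_id)
  esvs$sequence <- toupper(as.character(esvs$sequence))
  if (anyDuplicated(esvs$esv_id))
    stop("duplicated esv_id in ESV table")
  if (any(!nzchar(esvs$sequence)))
    stop("empty sequence")
  if (any(grepl("[^ACGT]", esvs$sequence)))
    stop("sequences must be DNA over {A,C,G,T}")
  has_sp <- !is.na(esvs$species)
  has_bp <- !is.na(esvs$sbp)
  if (any(has_sp != has_bp))
    stop("sbp must be present exactly when species is present")
  if (any(has_bp & (esvs$sbp < 0 | esvs$sbp > 1)))
    stop("sbp must lie in [0, 1]")
  need_c <- c("esv_id", "sample_id", "replicate_id", "reads")
  if (!all(need_c %in% names(counts)))
    stop("`counts` must have columns: ", paste(need_c, collapse = ", "))
  counts$esv_id <- as.character(counts$esv_id)
  counts$sample_id <- as.character(counts$sample_id)
  counts$replicate_id <- as.character(counts$replicate_id)
  if (any(is.na(counts$reads)) || any(counts$reads < 0))
    stop("read counts must be non-negative")
  if (any(counts$reads != round(counts$reads)))
    stop("read counts must be integers")
  unknown <- setdiff(counts$esv_id, esvs$esv_id)
  if (length(unknown))
    stop("count rows reference unknown ESVs: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  counts <- counts[counts$reads > 0, need_c, drop = FALSE]
  key <- paste(counts$esv_id, counts$sample_id, counts$replicate_id)
  if (anyDuplicated(key))
    stop("duplicated (esv, sample, replicate) count rows")
  counts <- counts[order(counts$esv_id, counts$sample_id,
                         counts$replicate_id), , drop = FALSE]
  rownames(esvs) <- NULL
  rownames(counts) <- NULL
  structure(list(esvs = esvs[c("esv_id", "amplicon", "sequence",
                               "species", "sbp")],
                 counts = counts),
            class = "esv_table")
}

#' @export
print.esv_table <- function(x, ...) {
  cat("ESV table:", nrow(x$esvs), "ESVs,",
      length(unique(x$counts$sample_id)), "samples,",
      sum(x$counts$reads), "reads\n")
  invisible(x)
}

#' Read an ESV table from TSV + FASTA (+ optional taxonomy TSV)
#'
#' @param table_path TSV with columns esv_id, sample_id, replicate_id, reads.
#' @param fasta_path FASTA whose ids match the table's esv_ids; lowercase
#'   bases are normalised to uppercase.
#' @param taxonomy_path optional TSV with columns esv_id, species, sbp; ESVs
#'   without a row are left unassigned.
#' @return An [esv_table()].
#' @export
read_esv_table <- function(table_path, fasta_path, taxonomy_path = NULL) {
  counts <- utils::read.delim(table_path, stringsAsFactors = FALSE)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicated esv_id in FASTA: ", fasta_path)
  amplicon <- "unknown"
  if (!is.null(counts$amplicon) && nrow(counts))
    amplicon <- counts$amplicon[1]
  esvs <- data.frame(esv_id = ids, amplicon = amplicon,
                     sequence = toupper(as.character(seqs)),
                     stringsAsFactors = FALSE)
  missing <- setdiff(unique(as.character(counts$esv_id)), ids)
  if (length(missing))
    stop("count rows reference ESVs absent from FASTA: ",
         paste(utils::head(missing, 5), collapse = ", "))
  if (!is.null(taxonomy_path)) {
    tax <- utils::read.delim(taxonomy_path, stringsAsFactors = FALSE)
    idx <- match(esvs$esv_id, as.character(tax$esv_id))
    esvs$species <- ifelse(is.na(idx), NA_character_,
                           as.character(tax$species)[idx])
    esvs$sbp <- ifelse(is.na(idx), NA_real_, as.numeric(tax$sbp)[idx])
  }
  esv_table(esvs, counts[c("esv_id", "sample_id", "replicate_id", "reads")])
}

#' Write an ESV table as TSV + FASTA (+ taxonomy TSV)
#'
#' Inverse of [read_esv_table()]; only ESVs with a species call get a
#' taxonomy row.
#'
#' @param x an [esv_table()].
#' @param table_path,fasta_path,taxonomy_path output paths; `taxonomy_path`
#'   may be NULL to skip taxonomy.
#' @export
write_esv_table <- function(x, table_path, fasta_path, taxonomy_path = NULL) {
  stopifnot(inherits(x, "esv_table"))
  utils::write.table(x$counts, table_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  seqs <- Biostrings::DNAStringSet(x$esvs$sequence)
  names(seqs) <- x$esvs$esv_id
  Biostrings::writeXStringSet(seqs, fasta_path)
  if (!is.null(taxonomy_path)) {
    tax <- x$esvs[!is.na(x$esvs$species), c("esv_id", "species", "sbp")]
    utils::write.table(tax, taxonomy_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(x)
}

#' Read or write sample metadata
#'
#' CSV with columns sample_id, lat, lon (WGS84 decimal degrees), year,
#' wetland (logical). Coordinates outside valid ranges are rejected.
#'
#' @param path CSV path.
#' @return data.frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  md <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_sample_metadata(md)
}

#' @rdname read_sample_metadata
#' @param metadata data.frame as above.
#' @export
write_sample_metadata <- function(metadata, path) {
  metadata <- validate_sample_metadata(metadata)
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(metadata)
}

validate_sample_metadata <- function(md) {
  need <- c("sample_id", "lat", "lon", "year", "wetland")
  if (!all(need %in% names(md)))
    stop("sample metadata must have columns: ", paste(need, collapse = ", "))
  md$sample_id <- as.character(md$sample_id)
  md$wetland <- as.logical(md$wetland)
  if (anyDuplicated(md$sample_id)) stop("duplicated sample_id")
  if (any(md$lat < -90 | md$lat > 90)) stop("latitude outside [-90, 90]")
  if (any(md$lon < -180 | md$lon > 180)) stop("longitude outside [-180, 180]")
  md[need]
}

#' Construct a sample-by-sample dissimilarity matrix
#'
#' A symmetric numeric matrix with zero diagonal; `NA` marks pairs for which
#' no dissimilarity is defined (missingness must be symmetric).
#'
#' @param values square numeric matrix with identical row/column names.
#' @param metric label recording what the entries measure.
#' @return the matrix with class `dist_matrix` and a `metric` attribute.
#' @export
dist_matrix <- function(values, metric = "sorensen") {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("matrix must be square")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("matrix must carry sample ids as dimnames")
  if (!identical(rownames(values), colnames(values)))
    stop("row and column ids differ")
  if (anyDuplicated(rownames(values))) stop("duplicated sample ids")
  nas <- is.na(values)
  if (!identical(nas, t(nas))) stop("missingness must be symmetric")
  if (any(abs(values - t(values)) > 1e-9, na.rm = TRUE))
    stop("matrix must be symmetric")
  d <- diag(values)
  if (any(!is.na(d) & abs(d) > 1e-12)) stop("diagonal must be zero")
  dv <- diag(values)
  dv[is.na(dv)] <- 0
  diag(values) <- dv
  structure(values, class = c("dist_matrix", "matrix"),
            metric = metric)
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("dist_matrix (", attr(x, "metric"), "): ", nrow(x), " samples, ",
      sum(is.na(x[upper.tri(x)])), " missing pairs\n", sep = "")
  print(unclass(x), ...)
  invisible(x)
}

#' Write / read a dissimilarity matrix as TSV
#'
#' TSV with a header row and a leading column of sample ids; missing pairs
#' are serialized as `NA`. Round-trips to 12 significant digits.
#'
#' @param m a [dist_matrix()].
#' @param path TSV path.
#' @export
write_dist_matrix <- function(m, path) {
  stopifnot(inherits(m, "dist_matrix"))
  out <- format(unclass(m), digits = 15, trim = TRUE, scientific = FALSE)
  out[is.na(unclass(m))] <- "NA"
  df <- data.frame(sample_id = rownames(m), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(m)
}

#' @rdname write_dist_matrix
#' @param metric metric label to attach on read.
#' @export
read_dist_matrix <- function(path, metric = "sorensen") {
  df <- utils::read.delim(path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  ids <- as.character(df[[1]])
  vals <- as.matrix(df[-1])
  mode(vals) <- "numeric"
  rownames(vals) <- ids
  colnames(vals) <- names(df)[-1]
  dist_matrix(vals, metric = metric)
}

#' Build a presence/absence matrix
#'
#' @param values logical matrix, samples in rows, features (ESV/OTU/SBC) in
#'   columns, with unique ids on both axes.
#' @return validated logical matrix of class `presence_matrix`.
#' @export
presence_matrix <- function(values) {
  values <- as.matrix(values)
  mode(values) <- "logical"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("presence matrix needs sample and feature ids")
  if (anyDuplicated(rownames(values))) stop("duplicated sample ids")
  if (anyDuplicated(colnames(values))) stop("duplicated feature ids")
  if (any(is.na(values))) stop("presence values must be TRUE/FALSE")
  structure(values, class = c("presence_matrix", "matrix"))
}
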