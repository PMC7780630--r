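#' Read a beta-value matrix from TSV
#'
#' Expects the layout written by [write_beta_matrix()]: first column
#' `probe_id`, remaining columns one per sample, values in `[0, 1]` or
#' missing.
#'
#' @param path TSV file path.
#' @return Numeric matrix, probes in rows (named), samples in columns.
#' @export
read_beta_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "probe_id") stop("first column must be 'probe_id'")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$probe_id
  storage.mode(m) <- "double"
  .check_beta_matrix(m)
}

#' Write a beta-value matrix to TSV
#' @param beta Probes x samples matrix.
#' @param path Output path.
#' @export
write_beta_matrix <- function(beta, path) {
  df <- data.frame(probe_id = rownames(beta), beta, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe annotation table (BED-like TSV, 1-based positions)
#' @param path TSV path with columns probe_id, chrom, pos, gene,
#'   promoter_class, cgi_relation, enhancer_flag, dnase_flag.
#' @return data.frame validated against the annotation contract.
#' @export
read_probe_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$enhancer_flag <- as.logical(df$enhancer_flag)
  df$dnase_flag <- as.logical(df$dnase_flag)
  .check_annotation(df)
}

#' Write a probe annotation table
#' @param annotation data.frame of probe annotations.
#' @param path Output path.
#' @export
write_probe_annotation <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a clinical table
#' @param path TSV with sample_id, mi_status, os_time, os_event, pfs_time,
#'   pfs_event and optional covariates.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  for (col in c("os_event", "pfs_event")) {
    if (col %in% names(df)) df[[col]] <- as.logical(df[[col]])
  }
  df
}

#' Read a 96-channel signature basis
#'
#' TSV with first column `channel` (the 96 pyrimidine-centric contexts in
#' the order of [sbs96_channels()]) and one column per signature. Columns
#' are checked to sum to 1 within 1e-6.
#'
#' @param path TSV path.
#' @return 96 x S numeric matrix with channel row names.
#' @export
read_signature_basis <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  .check_basis(m)
  m
}

#' Write a consensus clustering result to disk
#'
#' Emits three files under `prefix`: the consensus matrix (`*_consensus.tsv`),
#' the final labels (`*_labels.tsv`) and a JSON metadata record with the
#' parameters, seed and skipped-run count.
#'
#' @param result A `consensus_result` from [consensus_cluster()].
#' @param prefix File path prefix.
#' @return Invisibly, the paths written.
#' @export
write_consensus_result <- function(result, prefix) {
  stopifnot(inherits(result, "consensus_result"))
  p1 <- paste0(prefix, "_consensus.tsv")
  p2 <- paste0(prefix, "_labels.tsv")
  p3 <- paste0(prefix, "_meta.json")
  utils::write.table(
    data.frame(sample_id = rownames(result$consensus), result$consensus,
               check.names = FALSE),
    p1, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = names(result$labels), cluster = result$labels),
    p2, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(result$params, list(skipped_runs = result$skipped_runs))
  jsonlite::write_json(meta, p3, auto_unbox = TRUE, digits = NA)
  invisible(c(p1, p2, p3))
}
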