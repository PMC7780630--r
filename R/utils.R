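#' Derive a reproducible substream seed for a named pipeline stage
#'
#' One global seed drives every stochastic stage; each stage draws from its
#' own substream so that adding or reordering a stage never perturbs the
#' draws of another. The substream seed is a stable arithmetic hash of the
#' stage name combined with the global seed, kept below 2^31 - 1 so it is a
#' valid R integer seed on every platform.
#'
#' @param seed Global integer seed.
#' @param stream Character stage name, e.g. `"beta"`, `"mutations"`.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((abs(seed) * 1000003 + h * 69069) %% 2147483647)
}

# shared validators -----------------------------------------------------------

.check_prob <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}

.check_beta_matrix <- function(beta) {
  if (!is.matrix(beta) || !is.numeric(beta)) {
    stop("beta must be a numeric matrix (probes x samples)", call. = FALSE)
  }
  if (is.null(rownames(beta)) || is.null(colnames(beta))) {
    stop("beta must carry probe row names and sample column names", call. = FALSE)
  }
  rng <- range(beta, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 1) stop("beta values must lie in [0, 1]", call. = FALSE)
  if (anyDuplicated(colnames(beta))) stop("sample ids must be unique", call. = FALSE)
  invisible(beta)
}

.check_annotation <- function(annotation) {
  need <- c("probe_id", "chrom", "pos", "gene", "promoter_class",
            "cgi_relation", "enhancer_flag", "dnase_flag")
  miss <- setdiff(need, names(annotation))
  if (length(miss)) {
    stop("annotation is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(annotation$probe_id)) stop("probe_id must be unique", call. = FALSE)
  if (any(annotation$pos < 1)) stop("positions must be 1-based (>= 1)", call. = FALSE)
  invisible(annotation)
}

#' Chromosome vocabulary accepted by probe filters
#'
#' Both `chrN` (UCSC) and bare `N` (Ensembl) styles are recognised for
#' autosomes 1-22 and the sex chromosomes X and Y.
#' @return Character vector of valid chromosome names.
#' @keywords internal
.valid_chroms <- function() {
  base <- c(as.character(1:22), "X", "Y")
  c(base, paste0("chr", base))
}

.is_sex_chrom <- function(chrom) {
  sub("^chr", "", chrom) %in% c("X", "Y")
}
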