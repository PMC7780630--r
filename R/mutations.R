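#' Variant-class synonym table for MAF dialects
#'
#' Maps common MAF `Variant_Classification` strings onto the closed class
#' vocabulary used throughout the package: missense, silent, nonsense,
#' splice, frameshift_ins, frameshift_del, inframe_indel, other.
#'
#' @return Named character vector (synonym -> canonical class).
#' @export
maf_class_synonyms <- function() {
  c(Missense_Mutation = "missense", Silent = "silent",
    Nonsense_Mutation = "nonsense", Nonstop_Mutation = "nonsense",
    Splice_Site = "splice", Splice_Region = "splice",
    Frame_Shift_Ins = "frameshift_ins", Frame_Shift_Del = "frameshift_del",
    In_Frame_Ins = "inframe_indel", In_Frame_Del = "inframe_indel",
    Translation_Start_Site = "other", "3'UTR" = "other", "5'UTR" = "other",
    "3'Flank" = "other", "5'Flank" = "other", Intron = "other",
    IGR = "other", RNA = "other")
}

.canonical_classes <- function() {
  c("missense", "silent", "nonsense", "splice", "frameshift_ins",
    "frameshift_del", "inframe_indel", "other")
}

.indel_classes <- function() c("frameshift_ins", "frameshift_del", "inframe_indel")

# resolve MAF column-name dialects onto the internal schema
.maf_columns <- function(df) {
  alias <- list(sample_id = c("sample_id", "Tumor_Sample_Barcode"),
                gene = c("gene", "Hugo_Symbol"),
                variant_class = c("variant_class", "Variant_Classification"),
                chrom = c("chrom", "Chromosome"),
                pos = c("pos", "Start_Position"),
                ref = c("ref", "Reference_Allele"),
                alt = c("alt", "Tumor_Seq_Allele2"),
                context = c("context", "Trinucleotide_Context"))
  out <- list()
  for (nm in names(alias)) {
    hit <- intersect(alias[[nm]], names(df))
    if (length(hit)) {
      out[[nm]] <- df[[hit[1]]]
    } else if (nm != "context") {
      stop("required MAF column missing: one of ",
           paste(alias[[nm]], collapse = "/"))
    } else {
      out[[nm]] <- rep("", nrow(df))
    }
  }
  data.frame(out, stringsAsFactors = FALSE)
}

#' Parse a MAF-like somatic mutation table
#'
#' Accepts either a file path or a data.frame in the documented dialect
#' (`sample_id`/`Tumor_Sample_Barcode`, `gene`/`Hugo_Symbol`, ...). Variant
#' classes are mapped onto the closed vocabulary via
#' [maf_class_synonyms()]; an unmappable class string is an error naming
#' the offender. Records with `ref == alt` are rejected.
#'
#' @param x Path to a TSV, or a data.frame.
#' @param sample_universe Optional character vector of all cohort samples
#'   (so mutation-free samples are representable downstream); defaults to
#'   the samples observed in the table.
#' @return List with `records` (validated data.frame), `class_distribution`
#'   (counts and fractions per class plus the indel union), and
#'   `sample_universe`.
#' @export
parse_mutations <- function(x, sample_universe = NULL) {
  df <- if (is.character(x)) {
    utils::read.delim(x, stringsAsFactors = FALSE, check.names = FALSE)
  } else as.data.frame(x, stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    records <- data.frame(sample_id = character(), gene = character(),
                          chrom = character(), pos = integer(),
                          ref = character(), alt = character(),
                          variant_class = character(), context = character(),
                          stringsAsFactors = FALSE)
  } else {
    records <- .maf_columns(df)
    syn <- maf_class_synonyms()
    cls <- records$variant_class
    mapped <- ifelse(cls %in% .canonical_classes(), cls,
                     unname(syn[cls]))
    if (anyNA(mapped)) {
      stop("unmappable variant class: ",
           paste(unique(cls[is.na(mapped)]), collapse = ", "))
    }
    records$variant_class <- mapped
    if (any(records$ref == records$alt)) {
      stop("records with ref == alt are invalid")
    }
  }
  if (is.null(sample_universe)) sample_universe <- sort(unique(records$sample_id))
  n <- nrow(records)
  counts <- table(factor(records$variant_class, levels = .canonical_classes()))
  dist <- data.frame(class = names(counts), n = as.integer(counts),
                     fraction = if (n > 0) as.numeric(counts) / n else 0,
                     stringsAsFactors = FALSE)
  attr(dist, "total") <- n
  attr(dist, "indel") <- sum(counts[.indel_classes()])
  list(records = records, class_distribution = dist,
       sample_universe = sample_universe)
}

#' Binary gene x sample mutation indicator matrix
#'
#' @param records Mutation records (from [parse_mutations()]).
#' @param sample_universe All cohort samples, including mutation-free ones.
#' @param genes Optional gene set to restrict/extend rows to.
#' @return Integer 0/1 matrix, genes x samples; entry 1 iff at least one
#'   record exists for the pair.
#' @export
mutation_matrix <- function(records, sample_universe, genes = NULL) {
  if (is.null(genes)) genes <- sort(unique(records$gene))
  m <- matrix(0L, length(genes), length(sample_universe),
              dimnames = list(genes, sample_universe))
  keep <- records$gene %in% genes & records$sample_id %in% sample_universe
  r <- records[keep, , drop = FALSE]
  if (nrow(r)) m[cbind(r$gene, r$sample_id)] <- 1L
  m
}

#' Per-sample mutational load
#'
#' Load is the total mutation count of a sample (all classes) divided by
#' the captured exome size in Mb (default 50, the whole-exome capture
#' convention). Samples without records get load 0.
#'
#' @param records Mutation records.
#' @param sample_universe All cohort samples.
#' @param target_mb Capture size in Mb (> 0).
#' @return List with `load` (named per-sample vector, mutations per Mb)
#'   and `summary` (mean, sd, median, min, max).
#' @export
mutational_load <- function(records, sample_universe, target_mb = 50) {
  if (target_mb <= 0) stop("target_mb must be > 0")
  counts <- table(factor(records$sample_id, levels = sample_universe))
  load <- as.numeric(counts) / target_mb
  names(load) <- sample_universe
  list(load = load,
       summary = c(mean = mean(load), sd = stats::sd(load),
                   median = stats::median(load),
                   min = min(load), max = max(load)))
}

#' Per-gene (and gene-family) mutation frequency
#'
#' @param matrix Binary mutation matrix from [mutation_matrix()].
#' @param families Optional named list of gene-symbol vectors; a sample
#'   counts as family-mutated when any member gene is mutated.
#' @return data.frame with gene, n_mutated, frequency; family rows (if
#'   any) appended with the family name.
#' @export
gene_frequency <- function(matrix, families = NULL) {
  n <- ncol(matrix)
  out <- data.frame(gene = rownames(matrix),
                    n_mutated = as.integer(rowSums(matrix)),
                    frequency = rowSums(matrix) / n,
                    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(families)) {
    fam <- do.call(rbind, lapply(names(families), function(nm) {
      members <- intersect(families[[nm]], rownames(matrix))
      hit <- if (length(members)) {
        colSums(matrix[members, , drop = FALSE]) > 0
      } else rep(FALSE, n)
      data.frame(gene = nm, n_mutated = sum(hit), frequency = mean(hit),
                 stringsAsFactors = FALSE)
    }))
    out <- rbind(out, fam)
  }
  out[order(-out$frequency, out$gene), , drop = FALSE]
}

# sample odds ratio with Haldane 0.5 correction on zero cells
.sample_or <- function(tab) {
  if (any(tab == 0)) tab <- tab + 0.5
  (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
}

#' Pairwise mutual exclusivity and co-occurrence of mutated genes
#'
#' For every pair of genes mutated in at least `min_freq` of samples,
#' builds the 2x2 of joint mutation status and reports both one-sided
#' Fisher exact p-values: `p_exclusive` (alternative "less", fewer joint
#' mutations than expected) and `p_cooccur` (alternative "greater"). The
#' log2 odds ratio uses the sample OR with Haldane 0.5 correction on zero
#' cells; BH adjustment is applied within each direction across the tested
#' pairs.
#'
#' @param matrix Binary mutation matrix.
#' @param min_freq Minimum per-gene mutation frequency (default 0.10).
#' @return data.frame with gene_a, gene_b, the four cells (n_both,
#'   n_a_only, n_b_only, n_neither), log2_odds_ratio, p_exclusive,
#'   p_cooccur, fdr_exclusive, fdr_cooccur.
#' @export
pairwise_exclusivity <- function(matrix, min_freq = 0.10) {
  freq <- rowMeans(matrix)
  genes <- rownames(matrix)[freq >= min_freq]
  if (length(genes) < 2) stop("fewer than 2 genes pass min_freq")
  pairs <- utils::combn(sort(genes), 2)
  rows <- apply(pairs, 2, function(gp) {
    a <- matrix[gp[1], ] == 1
    b <- matrix[gp[2], ] == 1
    tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)),
                  2, 2, byrow = TRUE)
    data.frame(gene_a = gp[1], gene_b = gp[2],
               n_both = tab[1, 1], n_a_only = tab[1, 2],
               n_b_only = tab[2, 1], n_neither = tab[2, 2],
               log2_odds_ratio = log2(.sample_or(tab)),
               p_exclusive = fisher_exact(tab, "less")$p_value,
               p_cooccur = fisher_exact(tab, "greater")$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr_exclusive <- stats::p.adjust(out$p_exclusive, method = "BH")
  out$fdr_cooccur <- stats::p.adjust(out$p_cooccur, method = "BH")
  rownames(out) <- NULL
  out
}

#' Association between mutation status and a phenotype
#'
#' For each gene in the panel: a categorical phenotype is tested with a
#' two-sided Fisher exact test on the 2x2 of mutation status by phenotype
#' level; a continuous phenotype with a two-sided Mann-Whitney test split
#' by mutation status. P-values are BH-adjusted across the panel.
#'
#' @param matrix Binary mutation matrix (samples must cover the phenotype).
#' @param phenotype Named vector (names = sample ids), categorical (2
#'   levels) or numeric.
#' @param genes Gene panel to test; default all matrix rows.
#' @return data.frame with gene, statistic (odds ratio or U), p_value, fdr.
#' @export
mutation_phenotype_association <- function(matrix, phenotype,
                                           genes = rownames(matrix)) {
  samples <- colnames(matrix)
  if (!all(samples %in% names(phenotype))) {
    stop("phenotype missing for some samples in the universe")
  }
  ph <- phenotype[samples]
  categorical <- is.character(ph) || is.factor(ph) || is.logical(ph)
  if (categorical) {
    ph <- factor(ph)
    if (nlevels(ph) < 2) stop("phenotype has a single category")
    if (nlevels(ph) > 2) stop("categorical phenotype must have 2 levels")
  }
  rows <- lapply(genes, function(g) {
    mut <- matrix[g, ] == 1
    if (categorical) {
      tab <- table(factor(mut, levels = c(TRUE, FALSE)), ph)
      fe <- fisher_exact(matrix(tab, 2, 2), "two_sided")
      data.frame(gene = g, statistic = fe$odds_ratio, p_value = fe$p_value,
                 stringsAsFactors = FALSE)
    } else {
      if (all(mut) || !any(mut)) {
        return(data.frame(gene = g, statistic = NA_real_, p_value = NA_real_,
                          stringsAsFactors = FALSE))
      }
      mw <- mann_whitney(ph[mut], ph[!mut], "two_sided")
      data.frame(gene = g, statistic = mw$U, p_value = mw$p_value,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$p_value, method = "BH")
  out
}
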