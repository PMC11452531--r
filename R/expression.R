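#' Median-of-ratios count normalization
#'
#' Computes per-sample size factors as the median, over genes with nonzero
#' counts in every sample, of the ratio of each gene's count to its
#' geometric mean across samples, then divides counts by the factors. This
#' is the standard library-size normalization for RNA-seq count tables;
#' within a sample it is a single scalar division, so gene rank order per
#' sample is unchanged.
#'
#' @param counts numeric matrix, genes x samples, non-negative integers,
#'   with gene row names.
#' @return list with `size_factors` (named by sample) and `normalized`
#'   (matrix of counts / factor).
#' @export
normalize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (ncol(counts) == 1) {
    sf <- stats::setNames(1, colnames(counts))
    return(list(size_factors = sf, normalized = counts))
  }
  all_pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(all_pos))
    stop("no gene has nonzero counts in every sample; cannot normalize")
  log_geo <- rowMeans(log(counts[all_pos, , drop = FALSE]))
  sf <- apply(counts[all_pos, , drop = FALSE], 2, function(col)
    exp(stats::median(log(col) - log_geo)))
  list(size_factors = sf,
       normalized = sweep(counts, 2, sf, "/"))
}

#' Flag genes expressed in both genotypes
#'
#' A gene is considered expressed when its mean normalized count reaches
#' `min_mean` in BOTH genotypes — detection in one genotype only does not
#' qualify.
#'
#' @param normalized normalized count matrix, genes x samples.
#' @param genotype character/factor of length `ncol(normalized)` with
#'   exactly two levels.
#' @param min_mean minimum mean normalized count per genotype (default 10).
#' @return named logical vector per gene.
#' @export
detect_expressed <- function(normalized, genotype, min_mean = 10) {
  normalized <- as.matrix(normalized)
  genotype <- as.character(genotype)
  if (length(genotype) != ncol(normalized))
    stop("genotype must have one entry per sample")
  levels <- unique(genotype)
  if (length(levels) != 2) stop("need exactly two genotypes")
  m1 <- rowMeans(normalized[, genotype == levels[1], drop = FALSE])
  m2 <- rowMeans(normalized[, genotype == levels[2], drop = FALSE])
  stats::setNames(m1 >= min_mean & m2 >= min_mean, rownames(normalized))
}

#' Classify differential expression by fold-change and significance
#'
#' A gene is `up` when `log2_fold_change > lfc_threshold` and
#' `adjusted_p < alpha`, `down` when `log2_fold_change < -lfc_threshold`
#' and `adjusted_p < alpha`, otherwise `ns`. Defaults follow the common
#' |log2FC| > 1, padj < 0.05 convention.
#'
#' @param records data frame with columns `log2_fold_change` and
#'   `adjusted_p` (NA adjusted_p classifies as `ns`).
#' @param lfc_threshold log2 fold-change magnitude threshold (default 1).
#' @param alpha adjusted-P significance level (default 0.05).
#' @return `records` with an added `de_class` factor (up/down/ns).
#' @export
classify_de <- function(records, lfc_threshold = 1, alpha = 0.05) {
  records <- as.data.frame(records)
  if (!all(c("log2_fold_change", "adjusted_p") %in% names(records)))
    stop("records need log2_fold_change and adjusted_p columns ",
         "(supply statistics or run welch_de() first)")
  lfc <- records$log2_fold_change
  p <- records$adjusted_p
  sig <- !is.na(p) & p < alpha & !is.na(lfc)
  cls <- rep("ns", nrow(records))
  cls[sig & lfc > lfc_threshold] <- "up"
  cls[sig & lfc < -lfc_threshold] <- "down"
  records$de_class <- factor(cls, levels = c("up", "down", "ns"))
  records
}

#' Fallback differential-expression test
#'
#' When no externally computed statistics table is available, performs a
#' two-sample Welch t-test per gene on `log2(normalized + 1)` with
#' Benjamini-Hochberg adjustment across the tested genes. `log2_fold_change`
#' is oriented as `numerator_genotype` minus the other genotype (mean of
#' log2-transformed normalized counts). This is a deliberately simple
#' stand-in for a full count-model DE engine and is not meant to reproduce
#' one.
#'
#' @param normalized normalized count matrix, genes x samples.
#' @param genotype two-level genotype vector per sample.
#' @param numerator_genotype level used as the fold-change numerator.
#' @return data frame: `gene`, `base_mean`, `log2_fold_change`, `p_value`,
#'   `adjusted_p`.
#' @export
welch_de <- function(normalized, genotype, numerator_genotype = NULL) {
  normalized <- as.matrix(normalized)
  genotype <- as.character(genotype)
  levels <- unique(genotype)
  if (length(levels) != 2) stop("need exactly two genotypes")
  if (is.null(numerator_genotype)) numerator_genotype <- levels[1]
  if (!numerator_genotype %in% levels)
    stop("numerator_genotype not among genotype levels")
  other <- setdiff(levels, numerator_genotype)
  lg <- log2(normalized + 1)
  a <- lg[, genotype == numerator_genotype, drop = FALSE]
  b <- lg[, genotype == other, drop = FALSE]
  if (ncol(a) < 2 || ncol(b) < 2)
    stop("need at least two samples per genotype for the fallback test")
  pvals <- vapply(seq_len(nrow(lg)), function(i) {
    if (stats::sd(a[i, ]) == 0 && stats::sd(b[i, ]) == 0)
      return(if (mean(a[i, ]) == mean(b[i, ])) 1 else NA_real_)
    stats::t.test(a[i, ], b[i, ])$p.value
  }, numeric(1))
  data.frame(
    gene = rownames(normalized),
    base_mean = rowMeans(normalized),
    log2_fold_change = rowMeans(a) - rowMeans(b),
    p_value = pvals,
    adjusted_p = stats::p.adjust(pvals, method = "BH"))
}

#' Expression report for BBR-bound genes
#'
#' Restricts an expression-record table to the genes bound by BBRs, keeping
#' bound genes absent from the table as rows flagged `missing_data`, and
#' summarises: genes bound, genes expressed in both genotypes, genes with
#' |log2FC| above the threshold, and genes significant at `alpha` — the
#' latter counted both among all bound genes and among the expressed subset,
#' since "significant" may or may not carry an expression floor.
#'
#' @param bbr_gene_list character vector of bound gene names
#'   (see [bbr_gene_list()]).
#' @param records expression records with `gene`, `log2_fold_change`,
#'   `adjusted_p` and optionally `expressed` (logical) and `de_class`.
#' @param lfc_threshold,alpha thresholds as in [classify_de()].
#' @return list with `table` (per-gene rows) and `summary` (one-row data
#'   frame of counts).
#' @export
bbr_expression_report <- function(bbr_gene_list, records,
                                  lfc_threshold = 1, alpha = 0.05) {
  records <- as.data.frame(records)
  if (!"gene" %in% names(records)) stop("records need a gene column")
  bbr_gene_list <- unique(as.character(bbr_gene_list))
  if (length(bbr_gene_list) == 0) {
    tab <- records[0, , drop = FALSE]
    tab$missing_data <- logical(0)
    return(list(table = tab,
                summary = data.frame(n_bound = 0L, n_expressed = 0L,
                                     n_large_lfc = 0L, n_significant = 0L,
                                     n_expressed_significant = 0L)))
  }
  idx <- match(bbr_gene_list, records$gene)
  tab <- records[ifelse(is.na(idx), 1L, idx), , drop = FALSE]
  tab[is.na(idx), setdiff(names(tab), "gene")] <- NA
  tab$gene <- bbr_gene_list
  tab$missing_data <- is.na(idx)
  rownames(tab) <- NULL
  expressed <- if ("expressed" %in% names(tab)) tab$expressed %in% TRUE
               else rep(TRUE, nrow(tab)) & !tab$missing_data
  large_lfc <- !is.na(tab$log2_fold_change) &
    abs(tab$log2_fold_change) > lfc_threshold
  sig <- !is.na(tab$adjusted_p) & tab$adjusted_p < alpha
  summary <- data.frame(
    n_bound = length(bbr_gene_list),
    n_expressed = sum(expressed),
    n_large_lfc = sum(large_lfc & expressed),
    n_significant = sum(sig),
    n_expressed_significant = sum(sig & expressed))
  list(table = tab, summary = summary)
}
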