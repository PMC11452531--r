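#' Call broad binding regions from peak calls
#'
#' Merges ChIP-seq peaks separated by at most `max_gap` bp (default 50 kb,
#' the distance used to define broad binding regions, BBRs) into clusters,
#' scores each cluster by its PSCORE — the -log10 of the product of the
#' member peaks' P values, i.e. the sum of their per-peak -log10 P — and
#' returns the clusters ranked by descending PSCORE. Ranking ties are broken
#' by (chrom, start), so the ordering is deterministic.
#'
#' @param peaks data frame of peak calls with `chrom`, `start`, `end`,
#'   `neg_log10_p` (and optionally `name`), e.g. from [read_narrowpeak()].
#' @param max_gap maximum distance between peaks to merge, bp.
#' @param min_peaks clusters with fewer constituent peaks are dropped.
#'   The default 1 keeps every merged region; a single-peak "broad" region
#'   is degenerate, so recovery analyses typically use 2.
#' @return a `bbr_set` data frame: `chrom`, `start`, `end`, `pscore`,
#'   `n_peaks`, and list-column `peak_ids` (names or indices of member
#'   peaks), sorted by descending `pscore`.
#' @export
call_bbrs <- function(peaks, max_gap = 50000, min_peaks = 1) {
  stopifnot(min_peaks >= 1)
  peaks <- as.data.frame(peaks)
  if (nrow(peaks) == 0) {
    out <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      pscore = numeric(), n_peaks = integer())
    out$peak_ids <- list()
    class(out) <- c("bbr_set", "data.frame")
    return(out)
  }
  if (!"neg_log10_p" %in% names(peaks))
    stop("peaks need a neg_log10_p column")
  if (any(peaks$neg_log10_p < 0)) stop("neg_log10_p must be >= 0")
  sorted <- sort_and_validate(peaks)
  merged <- merge_with_gap(sorted[, c("chrom", "start", "end")], max_gap)
  members <- attr(merged, "members")
  ids <- if ("name" %in% names(sorted)) as.character(sorted$name)
         else as.character(seq_len(nrow(sorted)))
  out <- data.frame(
    chrom = merged$chrom,
    start = merged$start,
    end = merged$end,
    pscore = vapply(members, function(i) sum(sorted$neg_log10_p[i]), numeric(1)),
    n_peaks = lengths(members))
  out$peak_ids <- lapply(members, function(i) ids[i])
  out <- out[out$n_peaks >= min_peaks, , drop = FALSE]
  ck <- chrom_order_key(out$chrom)
  ord <- order(-out$pscore, ck$prefix, ck$num, ck$full, out$start)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("bbr_set", "data.frame")
  out
}

#' Assign broad binding regions to gene models
#'
#' Annotates each BBR by its >= 1 bp overlap with gene bodies: exactly one
#' overlapping gene gives `single_gene`, two or more give `multi_gene`, none
#' gives `intergenic`. Multiple transcript records sharing a gene name count
#' as one gene; the recorded `gene_length` of a single-gene BBR is the
#' longest genomic span (end - start) among that gene's records.
#'
#' @param bbrs a `bbr_set` from [call_bbrs()].
#' @param genes data frame of gene models with `chrom`, `start`, `end`,
#'   `gene` (name), `strand`.
#' @return `bbrs` with added columns `assignment` (single_gene/multi_gene/
#'   intergenic), `genes` (comma-joined overlapping gene names) and
#'   `gene_length` (bp, NA unless single_gene).
#' @export
assign_genes <- function(bbrs, genes) {
  genes <- as.data.frame(genes)
  if (!all(c("chrom", "start", "end", "gene") %in% names(genes)))
    stop("genes need columns chrom, start, end, gene")
  gene_len <- tapply(genes$end - genes$start, genes$gene, max)
  assignment <- character(nrow(bbrs))
  gene_names <- character(nrow(bbrs))
  gene_length <- rep(NA_real_, nrow(bbrs))
  for (r in seq_len(nrow(bbrs))) {
    hit <- genes$chrom == bbrs$chrom[r] &
      genes$start < bbrs$end[r] & genes$end > bbrs$start[r]
    nms <- unique(genes$gene[hit])
    if (length(nms) == 0) {
      assignment[r] <- "intergenic"
    } else if (length(nms) == 1) {
      assignment[r] <- "single_gene"
      gene_names[r] <- nms
      gene_length[r] <- gene_len[[nms]]
    } else {
      assignment[r] <- "multi_gene"
      gene_names[r] <- paste(nms, collapse = ",")
    }
  }
  bbrs$assignment <- assignment
  bbrs$genes <- gene_names
  bbrs$gene_length <- gene_length
  bbrs
}

#' Summarise BBR counts by assigned-gene size class
#'
#' Size classes are cumulative: a gene longer than 1.0 Mb is also counted in
#' the > 0.5 Mb class.
#'
#' @param bbrs an annotated `bbr_set` from [assign_genes()].
#' @param thresholds gene-length thresholds in bp (default 0.5 and 1.0 Mb).
#' @return one-row data frame: `n_bbrs`, `n_single_gene`, one
#'   `n_gene_gt_<threshold>` column per threshold, and `frac_genic` (BBRs
#'   overlapping at least one gene).
#' @export
size_class_summary <- function(bbrs, thresholds = c(5e5, 1e6)) {
  if (!"assignment" %in% names(bbrs))
    stop("bbrs must be annotated with assign_genes() first")
  single <- bbrs$assignment == "single_gene"
  out <- data.frame(n_bbrs = nrow(bbrs), n_single_gene = sum(single))
  for (thr in thresholds) {
    lab <- if (thr >= 1e6) sprintf("%g_Mb", thr / 1e6)
           else sprintf("%g_Mb", thr / 1e6)
    out[[paste0("n_gene_gt_", lab)]] <-
      sum(single & !is.na(bbrs$gene_length) & bbrs$gene_length > thr)
  }
  out$frac_genic <- if (nrow(bbrs) == 0) 0 else
    mean(bbrs$assignment != "intergenic")
  out
}

#' Gene-size distribution skew of BBR-bound genes
#'
#' Compares the empirical CDFs of gene lengths between the BBR-bound genes
#' and a background gene set with the two-sample Kolmogorov-Smirnov
#' statistic `D = sup |ECDF_bound - ECDF_background|`, evaluated by a direct
#' scan over the pooled lengths, together with the direction of the shift at
#' the supremum (`"larger"` means bound genes skew toward larger sizes).
#'
#' @param bbr_genes,all_genes data frames of gene models (need `start`,
#'   `end`) or numeric vectors of gene lengths; both non-empty.
#' @return list with `D`, `direction` ("larger"/"smaller"), `n_bbr`, `n_all`
#'   and the two ECDF functions.
#' @export
gene_size_skew <- function(bbr_genes, all_genes) {
  len <- function(x) {
    if (is.numeric(x)) return(x)
    x <- as.data.frame(x)
    x$end - x$start
  }
  a <- len(bbr_genes); b <- len(all_genes)
  if (length(a) == 0 || length(b) == 0)
    stop("both gene lists must be non-empty")
  grid <- sort(unique(c(a, b)))
  fa <- stats::ecdf(a); fb <- stats::ecdf(b)
  diffs <- fa(grid) - fb(grid)
  i <- which.max(abs(diffs))
  list(D = abs(diffs[i]),
       # at the supremum, a lower bound-gene ECDF means mass shifted right
       direction = if (diffs[i] < 0) "larger" else "smaller",
       n_bbr = length(a), n_all = length(b),
       ecdf_bbr = fa, ecdf_all = fb)
}
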