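#' Labelled comparison region set
#'
#' Wraps an interval set with a label (e.g. "HS68_MiDAS", "090_CNV_gain")
#' and an optional polarity tag (gain/loss for CNV calls).
#'
#' @param label unique label for the set within a run.
#' @param intervals interval set or coercible data frame.
#' @param polarity optional `"gain"` or `"loss"`.
#' @return a `comparison_set`.
#' @export
comparison_set <- function(label, intervals, polarity = NULL) {
  stopifnot(is.character(label), length(label) == 1, nzchar(label))
  if (!is.null(polarity)) stopifnot(polarity %in% c("gain", "loss"))
  structure(list(label = label, intervals = as_interval_set(intervals),
                 polarity = polarity),
            class = "comparison_set")
}

#' Overlap of BBRs with a comparison region set
#'
#' Computes a [coverage_report()] with the BBR spans as query and the
#' comparison set as subject: what fraction of BBRs (regions and base
#' pairs) is covered by, e.g., MiDAS regions or CNV hotspots. A warning is
#' emitted when the two sets share no chromosome names (typically a
#' "chr1" vs "1" naming mismatch; see [rename_chroms()]).
#'
#' @param bbrs a `bbr_set` (or any interval data frame) used as query.
#' @param comparison a [comparison_set] (or interval data frame) as subject.
#' @return an `overlap_report` with an added `label` field.
#' @export
compare_to_set <- function(bbrs, comparison) {
  label <- NA_character_
  if (inherits(comparison, "comparison_set")) {
    label <- comparison$label
    comparison <- comparison$intervals
  }
  query <- as_interval_set(as.data.frame(bbrs)[, c("chrom", "start", "end")])
  subject <- as_interval_set(comparison)
  if (nrow(query) > 0 && nrow(subject) > 0 &&
      length(intersect(unique(query$chrom), unique(subject$chrom))) == 0)
    warning("query and subject share no chromosome names; ",
            "overlap is zero (use rename_chroms() if naming differs)")
  rep <- coverage_report(query, subject)
  rep$label <- label
  rep
}

#' Venn partition of gene lists
#'
#' Partitions 2-5 sets of gene names into the exclusive regions of the Venn
#' diagram. Gene matching is case-sensitive and exact. For every non-empty
#' combination of datasets the report gives both the exclusive count (genes
#' in exactly those datasets) and the total intersection count (genes in at
#' least those datasets), so either reading of a "shared genes" figure can
#' be checked.
#'
#' @param gene_lists named list (2-5 elements) of character vectors.
#' @return a `venn_partition`: list with `labels`, `exclusive` (named counts
#'   per membership pattern, names like "A&B"), `intersections` (total
#'   intersection counts per pattern), `full_intersection` (sorted genes in
#'   every dataset) and `union_size`.
#' @export
multi_dataset_venn <- function(gene_lists) {
  if (!is.list(gene_lists) || is.null(names(gene_lists)) ||
      any(!nzchar(names(gene_lists))))
    stop("gene_lists must be a named list")
  k <- length(gene_lists)
  if (k < 2 || k > 5) stop("need between 2 and 5 datasets")
  if (anyDuplicated(names(gene_lists))) stop("dataset labels must be unique")
  labels <- names(gene_lists)
  gene_lists <- lapply(gene_lists, function(g) unique(as.character(g)))
  universe <- sort(unique(unlist(gene_lists)))
  membership <- vapply(gene_lists, function(g) universe %in% g,
                       logical(length(universe)))
  if (length(universe) == 1) membership <- matrix(membership, nrow = 1)
  patterns <- unlist(lapply(seq_len(k), function(m)
    utils::combn(labels, m, paste, collapse = "&")))
  pattern_sets <- unlist(lapply(seq_len(k), function(m)
    utils::combn(labels, m, identity, simplify = FALSE)), recursive = FALSE)
  exclusive <- integer(length(patterns))
  intersections <- integer(length(patterns))
  names(exclusive) <- names(intersections) <- patterns
  for (i in seq_along(pattern_sets)) {
    inset <- labels %in% pattern_sets[[i]]
    if (length(universe) > 0) {
      exclusive[i] <- sum(apply(membership, 1, function(row) all(row == inset)))
      intersections[i] <- sum(apply(membership[, inset, drop = FALSE], 1, all))
    }
  }
  full <- if (length(universe) > 0)
    universe[apply(membership, 1, all)] else character(0)
  structure(list(labels = labels, exclusive = exclusive,
                 intersections = intersections,
                 full_intersection = full,
                 union_size = length(universe)),
            class = "venn_partition")
}

#' @export
print.venn_partition <- function(x, ...) {
  cat(sprintf("venn_partition of %d datasets (union %d genes)\n",
              length(x$labels), x$union_size))
  df <- data.frame(pattern = names(x$exclusive), exclusive = x$exclusive,
                   intersection = x$intersections, row.names = NULL)
  print(df)
  cat("full intersection:",
      if (length(x$full_intersection)) paste(x$full_intersection, collapse = ", ")
      else "(none)", "\n")
  invisible(x)
}

#' Gene names bound by an annotated BBR set
#'
#' Union of gene names over single- and multi-gene assignments, for use in
#' gene-level Venn comparisons.
#'
#' @param bbrs an annotated `bbr_set` from [assign_genes()].
#' @return character vector of unique gene names.
#' @export
bbr_gene_list <- function(bbrs) {
  if (!"genes" %in% names(bbrs))
    stop("bbrs must be annotated with assign_genes() first")
  nms <- unlist(strsplit(bbrs$genes[nzchar(bbrs$genes)], ",", fixed = TRUE))
  sort(unique(nms))
}

#' Overlap of BBRs with late-replicating regions
#'
#' Thresholds a replication-timing track into late-replicating intervals
#' (bins at or above `late_threshold`; by default the genome-wide median of
#' the track, since published analyses display timing as browser tracks
#' without a printed cutoff) and reports BBR coverage by those intervals.
#'
#' @param bbrs a `bbr_set`.
#' @param timing_track a [signal_track] where higher values mean later
#'   replication.
#' @param late_threshold numeric cutoff; default the track median.
#' @return an `overlap_report` labelled "late_replicating".
#' @export
late_region_overlap <- function(bbrs, timing_track, late_threshold = NULL) {
  stopifnot(inherits(timing_track, "signal_track"))
  if (is.null(late_threshold))
    late_threshold <- stats::median(unlist(timing_track$values))
  late <- threshold_track_to_intervals(timing_track, late_threshold, "ge")
  compare_to_set(bbrs, comparison_set("late_replicating", late))
}

#' Tidy table of overlap reports
#'
#' @param reports list of `overlap_report`s (e.g. from [compare_to_set()]).
#' @param query_label label describing the shared query set.
#' @return data frame with one row per report.
#' @export
overlap_report_table <- function(reports, query_label = "query") {
  rows <- lapply(reports, function(r) {
    df <- as.data.frame(r)
    df$query <- query_label
    df$subject <- if (is.null(r$label) || is.na(r$label)) "subject" else r$label
    df[, c("query", "subject", setdiff(names(df), c("query", "subject")))]
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
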