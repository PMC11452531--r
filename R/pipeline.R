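#' Pipeline run configuration
#'
#' Collects the tunable parameters of the full analysis with the standard
#' defaults: 50-kb peak-merge distance, 200-bp tag extension, 32-bp density
#' bins, +/- 5-kb TSS flank with 50-bp matrix columns, pseudocount 1,
#' gene-size thresholds at 0.5 and 1.0 Mb, and DE thresholds padj < 0.05
#' with |log2FC| > 1.
#'
#' @param merge_gap peak-merge distance, bp.
#' @param min_peaks minimum peaks per reported BBR.
#' @param fragment_length tag extension length, bp.
#' @param density_bin signal-track bin, bp.
#' @param flank TSS matrix half-window, bp.
#' @param matrix_bin TSS matrix column width, bp.
#' @param pseudocount log2-ratio pseudocount.
#' @param size_thresholds gene-length class thresholds, bp.
#' @param alpha adjusted-P threshold.
#' @param lfc_threshold log2 fold-change threshold.
#' @param min_mean expression floor (mean normalized counts per genotype).
#' @param seed seed for any stochastic step.
#' @return a validated `run_config` list.
#' @export
run_config <- function(merge_gap = 50000, min_peaks = 1,
                       fragment_length = 200, density_bin = 32,
                       flank = 5000, matrix_bin = 50, pseudocount = 1,
                       size_thresholds = c(5e5, 1e6),
                       alpha = 0.05, lfc_threshold = 1, min_mean = 10,
                       seed = 1) {
  cfg <- as.list(environment())
  numeric_pos <- c("merge_gap", "min_peaks", "fragment_length", "density_bin",
                   "flank", "matrix_bin", "pseudocount", "alpha",
                   "lfc_threshold", "min_mean")
  for (key in numeric_pos)
    if (!is.numeric(cfg[[key]]) || any(cfg[[key]] < 0))
      stop("run_config: ", key, " must be non-negative numeric")
  if (cfg$flank %% cfg$matrix_bin != 0)
    stop("run_config: flank must be divisible by matrix_bin")
  class(cfg) <- "run_config"
  cfg
}

#' Run the full analysis on a directory of input files
#'
#' Expects the file layout written by [simulate_all()] (gene models, chrom
#' sizes, narrowPeak peaks, comparison-set BEDs, timing bedGraph, tags and
#' counts TSVs) and writes the analysis tables: ranked annotated BBRs, size
#' classes, overlap reports, TSS mean profile and the BBR expression
#' report. All outputs are tab-separated with a single `#`-prefixed header.
#'
#' @param in_dir directory of inputs.
#' @param out_dir directory for outputs (created if needed).
#' @param config a [run_config()].
#' @param comparison_files named character vector of BED paths for
#'   comparison sets; defaults to every `*.bed` in `in_dir` other than
#'   `genes.bed`.
#' @return invisibly, a list of the in-memory results.
#' @export
run_pipeline <- function(in_dir, out_dir, config = run_config(),
                         comparison_files = NULL) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  need <- function(f) {
    p <- file.path(in_dir, f)
    if (!file.exists(p)) stop("missing input file: ", p)
    p
  }
  genes <- read_gene_models(need("genes.bed"))
  cs <- utils::read.table(need("chrom.sizes"), sep = "\t",
                          col.names = c("chrom", "length"))
  chrom_sizes <- stats::setNames(cs$length, cs$chrom)
  peaks <- read_narrowpeak(need("peaks.narrowPeak"))

  bbrs <- call_bbrs(peaks, max_gap = config$merge_gap,
                    min_peaks = config$min_peaks)
  bbrs <- assign_genes(bbrs, genes)
  write_tsv_report(bbr_table(bbrs), file.path(out_dir, "bbrs.tsv"))
  sizes <- size_class_summary(bbrs, config$size_thresholds)
  write_tsv_report(sizes, file.path(out_dir, "size_classes.tsv"))
  skew <- gene_size_skew(genes[genes$gene %in% bbr_gene_list(bbrs), ], genes)
  write_tsv_report(data.frame(D = skew$D, direction = skew$direction,
                              n_bbr_genes = skew$n_bbr, n_all_genes = skew$n_all),
                   file.path(out_dir, "gene_size_skew.tsv"))

  if (is.null(comparison_files)) {
    beds <- list.files(in_dir, pattern = "\\.bed$", full.names = TRUE)
    beds <- beds[basename(beds) != "genes.bed"]
    comparison_files <- stats::setNames(beds, sub("\\.bed$", "", basename(beds)))
  }
  reports <- lapply(names(comparison_files), function(label)
    compare_to_set(bbrs, comparison_set(label,
                                        read_bed(comparison_files[[label]]))))
  timing_path <- file.path(in_dir, "timing.bedGraph")
  if (file.exists(timing_path)) {
    timing <- read_bedgraph(timing_path, bin_size = 10000, chrom_sizes)
    reports <- c(reports, list(late_region_overlap(bbrs, timing)))
  }
  if (length(reports) > 0)
    write_tsv_report(overlap_report_table(reports, "BBRs"),
                     file.path(out_dir, "overlaps.tsv"))

  tags_path <- file.path(in_dir, "tags.tsv")
  profile <- NULL
  if (file.exists(tags_path)) {
    tags <- read_tsv_report(tags_path)
    frags <- extend_tags(tags, config$fragment_length, chrom_sizes)
    track <- bin_density(frags, config$density_bin, chrom_sizes)
    mat <- tss_matrix(track, genes, flank = config$flank,
                      matrix_bin = config$matrix_bin)
    profile <- mean_profile(mat)
    write_tsv_report(
      data.frame(offset_bp = seq(-config$flank, config$flank - 1,
                                 by = config$matrix_bin),
                 mean_signal = profile),
      file.path(out_dir, "tss_profile.tsv"))
  }

  expr_report <- NULL
  counts_path <- file.path(in_dir, "counts.tsv")
  if (file.exists(counts_path)) {
    counts <- read_counts(counts_path)
    geno <- read_tsv_report(need("genotypes.tsv"))
    norm <- normalize_counts(counts)
    expressed <- detect_expressed(norm$normalized, geno$genotype,
                                  config$min_mean)
    de <- welch_de(norm$normalized, geno$genotype,
                   numerator_genotype = "complemented")
    de$expressed <- expressed[de$gene]
    de <- classify_de(de, config$lfc_threshold, config$alpha)
    expr_report <- bbr_expression_report(bbr_gene_list(bbrs), de,
                                         config$lfc_threshold, config$alpha)
    write_tsv_report(expr_report$table, file.path(out_dir, "bbr_expression.tsv"))
    write_tsv_report(expr_report$summary,
                     file.path(out_dir, "bbr_expression_summary.tsv"))
  }
  invisible(list(bbrs = bbrs, size_classes = sizes, skew = skew,
                 overlaps = reports, profile = profile,
                 expression = expr_report))
}

#' Flatten a BBR set for tabular output
#'
#' @param bbrs a (possibly annotated) `bbr_set`.
#' @return plain data frame with `peak_ids` comma-joined.
#' @export
bbr_table <- function(bbrs) {
  df <- as.data.frame(bbrs)
  if ("peak_ids" %in% names(df))
    df$peak_ids <- vapply(df$peak_ids, paste, "", collapse = ",")
  df
}

# minimal --key value argument parser for the CLI front-end
parse_cli_args <- function(args) {
  out <- list()
  pos <- character(0)
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- sub("^--", "", a)
      if (i + 1 > length(args)) stop("missing value for --", key)
      out[[gsub("-", "_", key)]] <- args[i + 1]
      i <- i + 2
    } else {
      pos <- c(pos, a)
      i <- i + 1
    }
  }
  list(options = out, positional = pos)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `callbbr`, `tssmatrix`, `overlap`,
#' `venn`, `expr` and `run-all`. Intended to be driven by the thin
#' `inst/cli/broadbind` Rscript; exposed as a function so the dispatch
#' logic is testable in-process. Numeric options override [run_config()]
#' defaults.
#'
#' @param argv character vector of command-line arguments
#'   (subcommand first).
#' @return exit status, invisibly (0 on success).
#' @export
bbr_cli <- function(argv) {
  if (length(argv) == 0) {
    message("usage: broadbind <simulate|callbbr|tssmatrix|overlap|venn|expr|run-all> [--options]")
    return(invisible(1L))
  }
  sub <- argv[1]
  parsed <- parse_cli_args(argv[-1])
  opt <- parsed$options
  num <- function(key, default) if (!is.null(opt[[key]])) as.numeric(opt[[key]]) else default
  chr <- function(key, default = NULL) if (!is.null(opt[[key]])) opt[[key]] else default
  cfg <- run_config(merge_gap = num("merge_gap", 50000),
                    min_peaks = num("min_peaks", 1),
                    fragment_length = num("fragment_length", 200),
                    density_bin = num("density_bin", 32),
                    flank = num("flank", 5000),
                    matrix_bin = num("matrix_bin", 50),
                    alpha = num("alpha", 0.05),
                    lfc_threshold = num("lfc_threshold", 1),
                    min_mean = num("min_mean", 10),
                    seed = num("seed", 1))
  status <- 0L
  switch(
    sub,
    "simulate" = {
      out <- chr("out", "sim_out")
      simulate_all(sim_config(seed = cfg$seed), out)
      message("wrote synthetic inputs to ", out)
    },
    "callbbr" = {
      peaks <- read_narrowpeak(chr("peaks", stop("need --peaks")))
      bbrs <- call_bbrs(peaks, cfg$merge_gap, cfg$min_peaks)
      if (!is.null(chr("genes")))
        bbrs <- assign_genes(bbrs, read_gene_models(chr("genes")))
      write_tsv_report(bbr_table(bbrs), chr("out", "bbrs.tsv"))
      message(nrow(bbrs), " BBRs written")
    },
    "tssmatrix" = {
      cs <- utils::read.table(chr("chrom_sizes", stop("need --chrom-sizes")),
                              sep = "\t", col.names = c("chrom", "length"))
      chrom_sizes <- stats::setNames(cs$length, cs$chrom)
      tags <- read_tsv_report(chr("tags", stop("need --tags")))
      genes <- read_gene_models(chr("genes", stop("need --genes")))
      frags <- extend_tags(tags, cfg$fragment_length, chrom_sizes)
      track <- bin_density(frags, cfg$density_bin, chrom_sizes)
      mat <- tss_matrix(track, genes, cfg$flank, cfg$matrix_bin)
      prof <- mean_profile(mat)
      write_tsv_report(data.frame(gene = rownames(mat),
                                  as.data.frame(unclass(mat))),
                       chr("out_matrix", "tss_matrix.tsv"))
      write_tsv_report(data.frame(offset_bp = seq(-cfg$flank, cfg$flank - 1,
                                                  by = cfg$matrix_bin),
                                  mean_signal = prof),
                       chr("out_profile", "tss_profile.tsv"))
    },
    "overlap" = {
      bbrs <- read_tsv_report(chr("bbrs", stop("need --bbrs")))
      subject <- read_bed(chr("subject", stop("need --subject")))
      rep <- compare_to_set(bbrs, comparison_set(
        chr("label", "subject"), subject))
      write_tsv_report(overlap_report_table(list(rep), "BBRs"),
                       chr("out", "overlap.tsv"))
    },
    "venn" = {
      paths <- parsed$positional
      if (length(paths) < 2) stop("venn needs >= 2 gene-list files")
      lists <- lapply(paths, function(p) readLines(p))
      names(lists) <- sub("\\.[^.]*$", "", basename(paths))
      v <- multi_dataset_venn(lists)
      write_tsv_report(data.frame(pattern = names(v$exclusive),
                                  exclusive = v$exclusive,
                                  intersection = v$intersections),
                       chr("out", "venn.tsv"))
      message("full intersection: ",
              paste(v$full_intersection, collapse = ", "))
    },
    "expr" = {
      counts <- read_counts(chr("counts", stop("need --counts")))
      geno <- read_tsv_report(chr("genotypes", stop("need --genotypes")))
      norm <- normalize_counts(counts)
      de <- welch_de(norm$normalized, geno$genotype)
      de$expressed <- detect_expressed(norm$normalized, geno$genotype,
                                       cfg$min_mean)[de$gene]
      de <- classify_de(de, cfg$lfc_threshold, cfg$alpha)
      write_tsv_report(de, chr("out", "expression.tsv"))
    },
    "run-all" = {
      in_dir <- chr("in", stop("need --in"))
      run_pipeline(in_dir, chr("out", "results"), cfg)
      message("pipeline complete")
    },
    {
      message("unknown subcommand: ", sub)
      status <- 1L
    })
  invisible(status)
}
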