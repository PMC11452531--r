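#' Simulation configuration
#'
#' Bundles and validates all parameters of the synthetic-data generators.
#' The defaults describe a toy genome that mirrors the structure of a
#' replication-stress occupancy study at a scale that runs in seconds:
#' one 20-Mb chromosome carrying 40 genes with a heavy-tailed size mixture
#' (a large class of 0.5-1.5 Mb genes among mostly 5-100 kb genes), 8
#' planted peak clusters confined to large genes with intra-cluster gaps
#' well under the 50-kb merge distance, 30 isolated background peaks, and a
#' two-genotype negative-binomial expression table with planted |log2FC| = 2
#' effects.
#'
#' Structural guarantees are enforced by construction: genes are separated
#' by more than `merge_gap` so clusters in neighbouring genes can never
#' merge, intra-cluster peak gaps stay below `merge_gap`, and background
#' peaks keep more than `merge_gap` from each other and from every cluster.
#'
#' @param seed master seed; each generator stage derives its own RNG stream
#'   from it, so changing one stage's parameters does not perturb the
#'   others' draws.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param n_genes number of genes to place.
#' @param frac_large fraction of genes drawn from the large-size class; the
#'   large-gene count is the rounded product, fixed rather than Bernoulli,
#'   so planted clusters always have enough hosts.
#' @param large_size_range,small_size_range uniform gene-size ranges, bp.
#' @param merge_gap the downstream peak-merge distance the layout must
#'   respect (bp).
#' @param n_clusters number of planted peak clusters.
#' @param cluster_genes `"large"` plants clusters only in distinct large
#'   genes (the biased-binding arm); `"uniform"` draws a host gene uniformly
#'   with replacement for each cluster (the unbiased control arm).
#' @param peaks_per_cluster integer range (min, max) of peaks per cluster.
#' @param peak_width_range peak width range, bp.
#' @param n_background isolated background peaks.
#' @param peak_score_base,peak_score_rate per-peak -log10 P is
#'   `base + Exp(rate)`.
#' @param cooccurrence named numeric vector: per comparison-set label, the
#'   probability that a planted cluster is overlapped by a subject interval.
#' @param n_decoys decoy subject intervals placed away from all clusters.
#' @param tss_fold TSS enrichment fold (local fragment rate over background).
#' @param tss_window half-width of TSS fragment placement, bp.
#' @param n_background_frags uniform background fragments for the TSS stage.
#' @param n_samples samples per genotype.
#' @param depth mean sequencing depth per gene (counts).
#' @param dispersion negative-binomial dispersion (1/size).
#' @param de_fraction fraction of genes with a planted expression effect.
#' @param de_lfc planted |log2 fold change|.
#' @return a validated `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       chrom_lengths = c(chrS = 20e6),
                       n_genes = 40,
                       frac_large = 0.25,
                       large_size_range = c(5e5, 1.5e6),
                       small_size_range = c(5e3, 1e5),
                       merge_gap = 50000,
                       n_clusters = 8,
                       cluster_genes = c("large", "uniform"),
                       peaks_per_cluster = c(3, 8),
                       peak_width_range = c(500, 2000),
                       n_background = 30,
                       peak_score_base = 4,
                       peak_score_rate = 1,
                       cooccurrence = c(midas_like = 0.7, cnv_like = 0.7),
                       n_decoys = 10,
                       tss_fold = 8,
                       tss_window = 1000,
                       n_background_frags = 20000,
                       n_samples = 5,
                       depth = 500,
                       dispersion = 0.05,
                       de_fraction = 0.2,
                       de_lfc = 2) {
  cluster_genes <- match.arg(cluster_genes)
  cfg <- list(seed = seed, chrom_lengths = chrom_lengths, n_genes = n_genes,
              frac_large = frac_large, large_size_range = large_size_range,
              small_size_range = small_size_range, merge_gap = merge_gap,
              n_clusters = n_clusters, cluster_genes = cluster_genes,
              peaks_per_cluster = peaks_per_cluster,
              peak_width_range = peak_width_range,
              n_background = n_background,
              peak_score_base = peak_score_base,
              peak_score_rate = peak_score_rate,
              cooccurrence = cooccurrence, n_decoys = n_decoys,
              tss_fold = tss_fold, tss_window = tss_window,
              n_background_frags = n_background_frags,
              n_samples = n_samples, depth = depth, dispersion = dispersion,
              de_fraction = de_fraction, de_lfc = de_lfc)
  stopifnot(length(chrom_lengths) >= 1, all(chrom_lengths > 0),
            !is.null(names(chrom_lengths)),
            n_genes >= 1, frac_large >= 0, frac_large <= 1,
            merge_gap >= 0, n_clusters >= 0,
            all(cooccurrence >= 0), all(cooccurrence <= 1),
            de_fraction >= 0, de_fraction <= 1,
            n_samples >= 1, dispersion > 0, tss_fold >= 1)
  n_large <- round(frac_large * n_genes)
  if (cluster_genes == "large" && n_clusters > n_large)
    stop(sprintf("%d clusters need %d large genes but frac_large*n_genes = %d",
                 n_clusters, n_clusters, n_large))
  class(cfg) <- "sim_config"
  cfg
}

# Each generator stage seeds its own stream deterministically from the
# master seed; offsets keep stages independent of one another.
stage_seed <- function(config, offset) {
  (as.integer(config$seed) %% 100000L) * 17L + offset
}

#' Generate a toy genome with a heavy-tailed gene-size mixture
#'
#' Places non-overlapping genes with random strands on the configured
#' chromosomes. Gene sizes come from a two-component uniform mixture with a
#' fixed large-class count of `round(frac_large * n_genes)`. Inter-gene
#' gaps always exceed `merge_gap` (plus a 1-kb margin) so peak clusters in
#' different genes can never merge downstream. Deterministic given the seed.
#'
#' @param config a [sim_config()].
#' @return list with `genes` (gene-model data frame) and `chrom_sizes`.
#' @export
generate_genome <- function(config) {
  set.seed(stage_seed(config, 1L))
  n <- config$n_genes
  n_large <- round(config$frac_large * n)
  sizes <- c(stats::runif(n_large, config$large_size_range[1],
                          config$large_size_range[2]),
             stats::runif(n - n_large, config$small_size_range[1],
                          config$small_size_range[2]))
  is_large <- c(rep(TRUE, n_large), rep(FALSE, n - n_large))
  shuffle <- sample.int(n)
  sizes <- round(sizes[shuffle]); is_large <- is_large[shuffle]
  # apportion genes to chromosomes proportionally to length
  chrom_lengths <- config$chrom_lengths
  n_per <- round(n * chrom_lengths / sum(chrom_lengths))
  n_per[length(n_per)] <- n - sum(n_per[-length(n_per)])
  if (any(n_per < 0)) stop("cannot apportion genes to chromosomes")
  min_gap <- config$merge_gap + 1000
  genes <- list()
  offset <- 0
  for (ci in seq_along(chrom_lengths)) {
    k <- n_per[ci]
    if (k == 0) next
    idx <- offset + seq_len(k)
    offset <- offset + k
    sz <- sizes[idx]
    clen <- chrom_lengths[ci]
    slack <- clen - sum(sz) - (k + 1) * min_gap
    if (slack < 0)
      stop(sprintf("genes do not fit on %s: need %s bp of %s",
                   names(chrom_lengths)[ci],
                   format_bp(sum(sz) + (k + 1) * min_gap), format_bp(clen)))
    # random extra gaps: split the slack with a uniform stick-breaking draw
    cuts <- sort(stats::runif(k, 0, 1))
    extra <- diff(c(0, cuts, 1)) * slack
    starts <- numeric(k)
    pos <- 0
    for (j in seq_len(k)) {
      pos <- pos + min_gap + extra[j]
      starts[j] <- round(pos)
      pos <- pos + sz[j]
    }
    genes[[ci]] <- data.frame(
      chrom = names(chrom_lengths)[ci],
      start = starts, end = starts + sz,
      gene = sprintf("G%03d", idx),
      strand = sample(c("+", "-"), k, replace = TRUE),
      is_large = is_large[idx])
  }
  genes <- do.call(rbind, genes)
  genes$length <- genes$end - genes$start
  genes <- as.data.frame(sort_and_validate(genes))
  list(genes = genes, chrom_sizes = chrom_lengths)
}

#' Generate planted peak clusters and isolated background peaks
#'
#' Each planted cluster is placed inside its host gene with successive
#' intra-cluster gaps below the merge distance, so the downstream caller
#' recovers it as one region; background peaks are isolated by more than
#' the merge distance from each other and from every cluster. Per-peak
#' -log10 P values are drawn as `base + Exp(rate)`.
#'
#' @param config a [sim_config()].
#' @param genome output of [generate_genome()].
#' @return list with `peaks` (narrowPeak-style data frame) and `truth`
#'   (per-cluster host gene, span, member peak names and summed score).
#' @export
generate_peaks <- function(config, genome) {
  set.seed(stage_seed(config, 2L))
  genes <- genome$genes
  large_idx <- which(genes$is_large)
  hosts <- if (config$n_clusters == 0) integer(0)
  else if (config$cluster_genes == "large") {
    if (length(large_idx) < config$n_clusters)
      stop("not enough large genes to host the planted clusters")
    sample(large_idx, config$n_clusters)
  } else {
    sample(seq_len(nrow(genes)), config$n_clusters, replace = TRUE)
  }
  peak_rows <- list()
  truth_rows <- list()
  peak_id <- 0
  for (cl in seq_along(hosts)) {
    g <- genes[hosts[cl], ]
    k_rng <- config$peaks_per_cluster
    placed <- NULL
    for (try in 1:50) {
      k <- if (k_rng[1] == k_rng[2]) k_rng[1]
           else sample(seq(k_rng[1], k_rng[2]), 1)
      # cap peak widths so k peaks plus gaps always fit the host gene
      w_max <- max(50, min(config$peak_width_range[2],
                           floor(g$length / (2 * k))))
      w_min <- min(config$peak_width_range[1], w_max)
      w <- round(stats::runif(k, w_min, w_max))
      gap_cap <- max(2, min(config$merge_gap * 0.8, 40000))
      gaps <- round(stats::runif(max(k - 1, 0), 1, gap_cap))
      avail <- g$length - sum(w)
      if (avail < k) next
      if (sum(gaps) > avail * 0.9 && k > 1)  # shrink only, so gaps stay < merge_gap
        gaps <- pmax(1, floor(gaps / sum(gaps) * avail * 0.9))
      span <- sum(w) + sum(gaps)
      if (span > g$length) next
      start0 <- g$start + floor(stats::runif(1, 0, g$length - span + 1))
      starts <- start0 + cumsum(c(0, w[-k] + gaps))
      placed <- data.frame(start = starts, end = starts + w)
      break
    }
    if (is.null(placed))
      stop("could not fit a planted cluster inside gene ", g$gene)
    scores <- config$peak_score_base +
      stats::rexp(k, config$peak_score_rate)
    names_k <- sprintf("peak_%04d", peak_id + seq_len(k))
    peak_id <- peak_id + k
    peak_rows[[length(peak_rows) + 1]] <- data.frame(
      chrom = g$chrom, start = placed$start, end = placed$end,
      name = names_k, score = round(scores * 10), strand = ".",
      signal = scores, neg_log10_p = scores, neg_log10_q = scores - 1,
      summit = floor((placed$end - placed$start) / 2),
      cluster = cl)
    truth_rows[[cl]] <- data.frame(
      cluster = cl, gene = g$gene, chrom = g$chrom,
      span_start = min(placed$start), span_end = max(placed$end),
      n_peaks = k, pscore = sum(scores),
      peak_ids = paste(names_k, collapse = ","))
  }
  cluster_spans <- if (length(truth_rows) > 0) do.call(rbind, truth_rows) else NULL
  # background peaks: isolated from clusters and from each other
  bg_rows <- list()
  if (config$n_background > 0) {
    sep <- config$merge_gap + 1000
    taken <- if (!is.null(cluster_spans))
      data.frame(chrom = cluster_spans$chrom,
                 start = cluster_spans$span_start,
                 end = cluster_spans$span_end)
    else data.frame(chrom = character(), start = numeric(), end = numeric())
    chrom_lengths <- genome$chrom_sizes
    placed_n <- 0
    tries <- 0
    while (placed_n < config$n_background && tries < config$n_background * 200) {
      tries <- tries + 1
      ci <- sample(seq_along(chrom_lengths), 1,
                   prob = chrom_lengths / sum(chrom_lengths))
      w <- round(stats::runif(1, config$peak_width_range[1],
                              config$peak_width_range[2]))
      s <- floor(stats::runif(1, 0, chrom_lengths[ci] - w))
      cn <- names(chrom_lengths)[ci]
      clash <- taken$chrom == cn & taken$start - sep < s + w & taken$end + sep > s
      if (any(clash)) next
      placed_n <- placed_n + 1
      peak_id <- peak_id + 1
      nm <- sprintf("peak_%04d", peak_id)
      sc <- config$peak_score_base + stats::rexp(1, config$peak_score_rate)
      bg_rows[[placed_n]] <- data.frame(
        chrom = cn, start = s, end = s + w, name = nm,
        score = round(sc * 10), strand = ".", signal = sc,
        neg_log10_p = sc, neg_log10_q = sc - 1, summit = floor(w / 2),
        cluster = NA_integer_)
      taken <- rbind(taken, data.frame(chrom = cn, start = s, end = s + w))
    }
    if (placed_n < config$n_background)
      stop("could not place the requested background peaks with the required separation")
  }
  peaks <- do.call(rbind, c(peak_rows, bg_rows))
  if (is.null(peaks)) {
    peaks <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                        name = character(), score = numeric(),
                        strand = character(), signal = numeric(),
                        neg_log10_p = numeric(), neg_log10_q = numeric(),
                        summit = numeric(), cluster = integer())
  }
  # post-generation structural assertions
  if (!is.null(cluster_spans) && nrow(cluster_spans) > 1) {
    spans <- sort_and_validate(data.frame(chrom = cluster_spans$chrom,
                                          start = cluster_spans$span_start,
                                          end = cluster_spans$span_end))
    gaps_ok <- TRUE
    for (cn in unique(spans$chrom)) {
      s <- spans[spans$chrom == cn, ]
      if (nrow(s) > 1 && config$cluster_genes == "large" &&
          any(s$start[-1] - s$end[-nrow(s)] <= config$merge_gap))
        gaps_ok <- FALSE
    }
    if (!gaps_ok) stop("internal error: planted clusters violate the separation guarantee")
  }
  rownames(peaks) <- NULL
  list(peaks = peaks,
       truth = if (is.null(cluster_spans))
         data.frame(cluster = integer(), gene = character(),
                    chrom = character(), span_start = numeric(),
                    span_end = numeric(), n_peaks = integer(),
                    pscore = numeric(), peak_ids = character())
       else cluster_spans)
}

#' Generate comparison sets co-occurring with planted clusters
#'
#' For each comparison label and each planted cluster, a subject interval
#' overlapping the cluster span is emitted with the configured probability;
#' decoy intervals are placed more than the merge distance away from every
#' cluster. The per-cluster flags are recorded as ground truth.
#'
#' @param config a [sim_config()].
#' @param peaks output of [generate_peaks()].
#' @param genome output of [generate_genome()].
#' @return list of [comparison_set]s (one per label) with a `truth` data
#'   frame attribute column `hit` per cluster, returned as
#'   `list(sets = ..., truth = ...)`.
#' @export
generate_cooccurring_sets <- function(config, peaks, genome) {
  set.seed(stage_seed(config, 3L))
  truth <- peaks$truth
  sets <- list()
  truth_flags <- list()
  for (li in seq_along(config$cooccurrence)) {
    label <- names(config$cooccurrence)[li]
    p <- config$cooccurrence[[li]]
    hit <- if (nrow(truth) > 0) stats::runif(nrow(truth)) < p else logical(0)
    rows <- list()
    for (cl in which(hit)) {
      span <- c(truth$span_start[cl], truth$span_end[cl])
      center <- floor(stats::runif(1, span[1], span[2]))
      half <- round(stats::runif(1, 5000, 50000))
      rows[[length(rows) + 1]] <- data.frame(
        chrom = truth$chrom[cl],
        start = max(0, center - half),
        end = min(genome$chrom_sizes[[truth$chrom[cl]]], center + half))
    }
    # decoys: away from every cluster span
    sep <- config$merge_gap + 1000
    n_dec <- 0; tries <- 0
    while (n_dec < config$n_decoys && tries < config$n_decoys * 200) {
      tries <- tries + 1
      ci <- sample(seq_along(genome$chrom_sizes), 1,
                   prob = genome$chrom_sizes / sum(genome$chrom_sizes))
      w <- round(stats::runif(1, 10000, 60000))
      s <- floor(stats::runif(1, 0, genome$chrom_sizes[ci] - w))
      cn <- names(genome$chrom_sizes)[ci]
      if (nrow(truth) > 0 &&
          any(truth$chrom == cn & truth$span_start - sep < s + w &
                truth$span_end + sep > s)) next
      n_dec <- n_dec + 1
      rows[[length(rows) + 1]] <- data.frame(chrom = cn, start = s, end = s + w)
    }
    df <- if (length(rows) > 0) do.call(rbind, rows)
    else data.frame(chrom = character(), start = numeric(), end = numeric())
    sets[[label]] <- comparison_set(label, df)
    truth_flags[[label]] <- data.frame(
      label = label,
      cluster = if (nrow(truth) > 0) truth$cluster else integer(0),
      hit = hit)
  }
  list(sets = sets, truth = do.call(rbind, truth_flags))
}

#' Generate TSS-enriched sequencing tags
#'
#' Background tags are placed uniformly over the genome. Additional tags
#' are planted around each gene's TSS with fragment centres drawn from a
#' normal distribution centred exactly on the TSS (sd = `tss_window / 3`,
#' truncated at `tss_window`), so the expected fragment coverage after
#' 200-bp extension is a symmetric peak whose mode sits on the TSS;
#' `tss_fold = 1` plants nothing and the expected profile is flat. The
#' number of planted tags per TSS is chosen so the local fragment rate near
#' the TSS is about `tss_fold` times background. Tag strand is drawn at
#' random and tag starts are back-computed so that extending a tag to
#' `fragment_length` reproduces the drawn fragment.
#'
#' @param config a [sim_config()].
#' @param genome output of [generate_genome()].
#' @param read_length emitted tag length, bp.
#' @param fragment_length fragment length the downstream extension will
#'   use, bp.
#' @return list with `tags` (data frame) and `fragments`
#'   (tags extended to `fragment_length` via [extend_tags()]).
#' @export
generate_tss_fragments <- function(config, genome, read_length = 75,
                                   fragment_length = 200) {
  set.seed(stage_seed(config, 4L))
  chrom_lengths <- genome$chrom_sizes
  genome_bp <- sum(chrom_lengths)
  n_bg <- config$n_background_frags
  ci <- sample(seq_along(chrom_lengths), n_bg, replace = TRUE,
               prob = chrom_lengths / sum(chrom_lengths))
  start <- floor(stats::runif(n_bg, 0, chrom_lengths[ci] - read_length))
  bg <- data.frame(chrom = names(chrom_lengths)[ci], start = start,
                   end = start + read_length,
                   strand = sample(c("+", "-"), n_bg, replace = TRUE))
  tss_rows <- NULL
  if (config$tss_fold > 1 && nrow(genome$genes) > 0) {
    lambda_bg <- n_bg / genome_bp  # tags per bp
    per_tss <- round((config$tss_fold - 1) * lambda_bg * 2 * config$tss_window)
    if (per_tss > 0) {
      g <- genome$genes
      tss <- ifelse(g$strand == "+", g$start, g$end)
      idx <- rep(seq_len(nrow(g)), each = per_tss)
      offs <- round(stats::rnorm(length(idx), 0, config$tss_window / 3))
      offs <- pmin(pmax(offs, -config$tss_window), config$tss_window)
      center <- tss[idx] + offs
      strand <- sample(c("+", "-"), length(idx), replace = TRUE)
      half <- fragment_length / 2
      # tag start such that strand-aware extension recovers the fragment
      s <- ifelse(strand == "+", center - half,
                  center + half - read_length)
      s <- pmax(0, pmin(s, chrom_lengths[g$chrom[idx]] - read_length))
      tss_rows <- data.frame(chrom = g$chrom[idx], start = s,
                             end = s + read_length, strand = strand)
    }
  }
  tags <- rbind(bg, tss_rows)
  rownames(tags) <- NULL
  frags <- extend_tags(tags, fragment_length, chrom_lengths)
  list(tags = tags, fragments = frags)
}

#' Generate a two-phase replication-timing track
#'
#' A simple late/early track for overlap exercises: bins covering planted
#' cluster spans (padded by `pad` bp) get the late value, all other bins
#' the early value.
#'
#' @param config a [sim_config()].
#' @param genome output of [generate_genome()].
#' @param peaks output of [generate_peaks()].
#' @param bin_size track bin width, bp.
#' @param late_value,early_value bin values for late/early regions.
#' @param pad padding around cluster spans, bp.
#' @return a [signal_track].
#' @export
generate_timing_track <- function(config, genome, peaks, bin_size = 10000,
                                  late_value = 1, early_value = 0,
                                  pad = 25000) {
  chrom_lengths <- genome$chrom_sizes
  values <- lapply(chrom_lengths, function(len)
    rep(early_value, ceiling(len / bin_size)))
  truth <- peaks$truth
  for (cl in seq_len(nrow(truth))) {
    cn <- truth$chrom[cl]
    b1 <- max(1, floor((truth$span_start[cl] - pad) / bin_size) + 1)
    b2 <- min(length(values[[cn]]),
              floor((truth$span_end[cl] + pad - 1) / bin_size) + 1)
    values[[cn]][b1:b2] <- late_value
  }
  signal_track(values, bin_size, chrom_lengths)
}

#' Generate a two-genotype expression count table with planted effects
#'
#' Draws negative-binomial counts per gene and sample around log-normal
#' baseline means scaled to the configured depth. A planted fraction of
#' genes receives a `de_lfc` log2 fold change (random sign) in the
#' complemented genotype relative to the mutant; ground-truth classes are
#' returned alongside the counts.
#'
#' @param config a [sim_config()].
#' @param genome output of [generate_genome()].
#' @return list with `counts` (matrix genes x samples), `genotype` (per
#'   sample, levels `"mutant"` and `"complemented"`) and `truth` (per-gene
#'   `log2_fold_change` and `class`).
#' @export
generate_expression <- function(config, genome) {
  set.seed(stage_seed(config, 5L))
  genes <- genome$genes$gene
  n <- length(genes)
  n_de <- round(config$de_fraction * n)
  de_idx <- if (n_de > 0) sample.int(n, n_de) else integer(0)
  lfc <- numeric(n)
  lfc[de_idx] <- config$de_lfc * sample(c(-1, 1), n_de, replace = TRUE)
  base_mean <- stats::rlnorm(n, meanlog = log(config$depth), sdlog = 0.6)
  genotype <- rep(c("mutant", "complemented"), each = config$n_samples)
  mu <- cbind(matrix(base_mean, n, config$n_samples),
              matrix(base_mean * 2^lfc, n, config$n_samples))
  counts <- matrix(stats::rnbinom(n * length(genotype), mu = as.vector(mu),
                                  size = 1 / config$dispersion),
                   nrow = n)
  dimnames(counts) <- list(genes,
                           paste0(rep(c("mut_", "comp_"), each = config$n_samples),
                                  seq_len(config$n_samples)))
  truth <- data.frame(gene = genes, log2_fold_change = lfc,
                      class = ifelse(lfc > 0, "up",
                                     ifelse(lfc < 0, "down", "ns")))
  list(counts = counts, genotype = genotype, truth = truth)
}

#' Run every generator stage and write the standard file set
#'
#' Convenience wrapper producing all pipeline inputs (gene models BED,
#' narrowPeak, comparison-set BEDs, timing bedGraph, tag TSV, counts TSV)
#' plus truth tables into a directory.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list of generated in-memory objects.
#' @export
simulate_all <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- generate_genome(config)
  peaks <- generate_peaks(config, genome)
  sets <- generate_cooccurring_sets(config, peaks, genome)
  frags <- generate_tss_fragments(config, genome)
  timing <- generate_timing_track(config, genome, peaks)
  expr <- generate_expression(config, genome)
  write_gene_models(genome$genes, file.path(out_dir, "genes.bed"))
  writeLines(sprintf("%s\t%s", names(genome$chrom_sizes),
                     format_bp(genome$chrom_sizes)),
             file.path(out_dir, "chrom.sizes"))
  write_narrowpeak(peaks$peaks, file.path(out_dir, "peaks.narrowPeak"))
  write_tsv_report(peaks$truth, file.path(out_dir, "truth_clusters.tsv"))
  for (label in names(sets$sets))
    write_bed(sets$sets[[label]]$intervals,
              file.path(out_dir, paste0(label, ".bed")))
  write_tsv_report(sets$truth, file.path(out_dir, "truth_cooccurrence.tsv"))
  write_tsv_report(frags$tags, file.path(out_dir, "tags.tsv"))
  write_bedgraph(timing, file.path(out_dir, "timing.bedGraph"))
  counts_df <- data.frame(gene = rownames(expr$counts), expr$counts,
                          check.names = FALSE)
  write_tsv_report(counts_df, file.path(out_dir, "counts.tsv"))
  write_tsv_report(data.frame(sample = colnames(expr$counts),
                              genotype = expr$genotype),
                   file.path(out_dir, "genotypes.tsv"))
  write_tsv_report(expr$truth, file.path(out_dir, "truth_expression.tsv"))
  invisible(list(genome = genome, peaks = peaks, sets = sets,
                 fragments = frags, timing = timing, expression = expr))
}
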