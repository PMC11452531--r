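#' Binned signal tracks
#'
#' A `signal_track` stores one numeric value per fixed-width genomic bin.
#' Bin `i` on a chromosome covers base pairs `[(i-1)*bin_size, i*bin_size)`;
#' the last bin may extend past the chromosome end, so each chromosome has
#' `ceiling(chrom_length / bin_size)` bins.
#'
#' @param values named list, one numeric vector of bin values per chromosome.
#' @param bin_size bin width in bp.
#' @param chrom_sizes named numeric vector of chromosome lengths in bp.
#' @return an object of class `signal_track`.
#' @export
signal_track <- function(values, bin_size, chrom_sizes) {
  stopifnot(is.list(values), !is.null(names(values)),
            is.numeric(bin_size), bin_size >= 1)
  chrom_sizes <- unlist(chrom_sizes)
  for (chrom in names(values)) {
    if (!chrom %in% names(chrom_sizes))
      stop("no chromosome size for ", chrom)
    expected <- ceiling(chrom_sizes[[chrom]] / bin_size)
    if (length(values[[chrom]]) != expected)
      stop(sprintf("%s: expected %d bins, got %d", chrom, expected,
                   length(values[[chrom]])))
    if (any(!is.finite(values[[chrom]])))
      stop("non-finite bin values on ", chrom)
  }
  structure(list(values = values, bin_size = bin_size,
                 chrom_sizes = chrom_sizes),
            class = "signal_track")
}

#' @export
print.signal_track <- function(x, ...) {
  cat(sprintf("signal_track: %d-bp bins over %d chromosome(s), %s bins total\n",
              x$bin_size, length(x$values),
              format(sum(lengths(x$values)), big.mark = ",")))
  invisible(x)
}

track_total <- function(track) sum(vapply(track$values, sum, numeric(1)))

#' Extend sequencing tags to fragment length
#'
#' Each aligned read (tag) is extended in its 3' direction to the average
#' fragment length of the library: a plus-strand tag `[s, e)` becomes
#' `[s, s + L)` and a minus-strand tag becomes `[e - L, e)`, clamped to
#' `[0, chrom_length)`.
#'
#' @param tags data frame with `chrom`, `start`, `end`, `strand` (+/-).
#' @param fragment_length target fragment length L in bp.
#' @param chrom_sizes named vector of chromosome lengths; tags on unknown
#'   chromosomes are an error.
#' @return an [interval_set] of fragments.
#' @export
extend_tags <- function(tags, fragment_length = 200, chrom_sizes) {
  stopifnot(is.numeric(fragment_length), fragment_length >= 1)
  tags <- as.data.frame(tags)
  if (!all(c("chrom", "start", "end", "strand") %in% names(tags)))
    stop("tags need columns chrom, start, end, strand")
  chrom_sizes <- unlist(chrom_sizes)
  unknown <- setdiff(unique(tags$chrom), names(chrom_sizes))
  if (length(unknown) > 0)
    stop("tags on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  if (!all(tags$strand %in% c("+", "-")))
    stop("tag strand must be '+' or '-'")
  len <- chrom_sizes[tags$chrom]
  plus <- tags$strand == "+"
  start <- ifelse(plus, tags$start, tags$end - fragment_length)
  end <- ifelse(plus, tags$start + fragment_length, tags$end)
  start <- pmax(0, start)
  end <- pmin(len, end)
  sort_and_validate(data.frame(chrom = tags$chrom, start = start, end = end,
                               strand = tags$strand))
}

#' Fragment density in fixed-width bins
#'
#' Divides each chromosome into `bin_size`-bp bins and counts, per bin, the
#' number of fragments overlapping it by at least 1 bp (a fragment spanning
#' a bin boundary is counted in every bin it touches).
#'
#' @param fragments interval set (or data frame) of fragments.
#' @param bin_size bin width in bp (default 32).
#' @param chrom_sizes named vector of chromosome lengths.
#' @return a [signal_track] of counts.
#' @export
bin_density <- function(fragments, bin_size = 32, chrom_sizes) {
  fragments <- as_interval_set(fragments)
  chrom_sizes <- unlist(chrom_sizes)
  unknown <- setdiff(unique(fragments$chrom), names(chrom_sizes))
  if (length(unknown) > 0)
    stop("fragments on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  values <- lapply(names(chrom_sizes), function(chrom) {
    n_bins <- ceiling(chrom_sizes[[chrom]] / bin_size)
    v <- numeric(n_bins)
    sel <- fragments$chrom == chrom
    if (!any(sel)) return(v)
    first <- floor(fragments$start[sel] / bin_size) + 1
    last <- pmin(floor((fragments$end[sel] - 1) / bin_size) + 1, n_bins)
    # difference-array accumulation of [first, last] bin ranges
    d <- tabulate(first, n_bins + 1) - tabulate(last + 1, n_bins + 1)
    cumsum(d)[seq_len(n_bins)]
  })
  names(values) <- names(chrom_sizes)
  signal_track(values, bin_size, chrom_sizes)
}

#' log2 ratio of two signal tracks
#'
#' Computes `log2((sample + pseudocount) / (input + pseudocount))` per bin.
#' With `scale = "cpm"` (the default) both tracks are first scaled to
#' counts-per-million of their own totals so library size does not bias the
#' ratio; `scale = "none"` uses the raw bin values.
#'
#' @param sample,input [signal_track]s with identical bin size and
#'   chromosome sizes.
#' @param pseudocount value added to both numerator and denominator; must be
#'   positive if any input bin is zero.
#' @param scale `"cpm"` or `"none"`.
#' @return a [signal_track] of log2 ratios.
#' @export
log2_ratio <- function(sample, input, pseudocount = 1, scale = c("cpm", "none")) {
  scale <- match.arg(scale)
  stopifnot(inherits(sample, "signal_track"), inherits(input, "signal_track"))
  if (sample$bin_size != input$bin_size ||
      !identical(names(sample$values), names(input$values)) ||
      !identical(lengths(sample$values), lengths(input$values)))
    stop("sample and input tracks have mismatched shape")
  s_vals <- sample$values
  i_vals <- input$values
  if (scale == "cpm") {
    st <- track_total(sample); it <- track_total(input)
    if (st <= 0 || it <= 0) stop("cannot CPM-scale a track with zero total")
    s_vals <- lapply(s_vals, function(v) v / st * 1e6)
    i_vals <- lapply(i_vals, function(v) v / it * 1e6)
  }
  if (pseudocount <= 0 &&
      any(vapply(i_vals, function(v) any(v <= 0), logical(1))))
    stop("pseudocount must be positive when input bins contain zeros")
  out <- Map(function(s, i) log2((s + pseudocount) / (i + pseudocount)),
             s_vals, i_vals)
  signal_track(out, sample$bin_size, sample$chrom_sizes)
}

#' TSS-anchored signal matrix
#'
#' Builds a matrix with one row per gene and fixed-width columns spanning
#' `[TSS - flank, TSS + flank)`. The TSS is the gene start on the plus
#' strand and the gene end on the minus strand; minus-strand rows are
#' orientation-flipped so column 1 is always the 5'/upstream side. Each
#' matrix column averages the underlying track values (bp-weighted) it
#' spans. Columns falling outside the chromosome are filled with 0 and
#' flagged; genes on chromosomes absent from the track are skipped with a
#' warning.
#'
#' @param track a [signal_track].
#' @param genes data frame of gene models with `chrom`, `start`, `end`,
#'   `strand` and `gene` (row id).
#' @param flank half-window around the TSS in bp (default 5000).
#' @param matrix_bin matrix column width in bp; must divide `flank`.
#' @return a `signal_matrix`: numeric matrix with attributes `flank`,
#'   `bin_size` and `flagged` (logical matrix of out-of-chromosome cells).
#' @export
tss_matrix <- function(track, genes, flank = 5000, matrix_bin = 50) {
  stopifnot(inherits(track, "signal_track"))
  genes <- as.data.frame(genes)
  if (!all(c("chrom", "start", "end", "strand", "gene") %in% names(genes)))
    stop("genes need columns chrom, start, end, strand, gene")
  if (flank %% matrix_bin != 0)
    stop("flank must be divisible by matrix_bin")
  n_col <- 2 * flank / matrix_bin
  keep <- genes$chrom %in% names(track$values)
  if (any(!keep))
    warning(sum(!keep), " gene(s) on chromosomes absent from the track were skipped")
  genes <- genes[keep, , drop = FALSE]
  mat <- matrix(0, nrow = nrow(genes), ncol = n_col,
                dimnames = list(genes$gene, NULL))
  flagged <- matrix(FALSE, nrow = nrow(genes), ncol = n_col)
  bs <- track$bin_size
  for (r in seq_len(nrow(genes))) {
    chrom <- genes$chrom[r]
    clen <- track$chrom_sizes[[chrom]]
    v <- track$values[[chrom]]
    tss <- if (genes$strand[r] == "+") genes$start[r] else genes$end[r]
    # per-bp signal over the window, 0 outside the chromosome
    pos <- seq(tss - flank, tss + flank - 1)
    inside <- pos >= 0 & pos < clen
    bp_val <- numeric(length(pos))
    bp_val[inside] <- v[floor(pos[inside] / bs) + 1]
    row_vals <- colMeans(matrix(bp_val, nrow = matrix_bin))
    row_flag <- colSums(matrix(!inside, nrow = matrix_bin)) > 0
    if (genes$strand[r] == "-") {
      row_vals <- rev(row_vals)
      row_flag <- rev(row_flag)
    }
    mat[r, ] <- row_vals
    flagged[r, ] <- row_flag
  }
  structure(mat, flank = flank, bin_size = matrix_bin, flagged = flagged,
            class = c("signal_matrix", "matrix", "array"))
}

#' Column-wise mean profile of a signal matrix
#'
#' Arithmetic mean of each column, ignoring cells flagged as
#' out-of-chromosome. Errors on an empty matrix.
#'
#' @param matrix a `signal_matrix` from [tss_matrix()].
#' @return numeric vector of per-column means.
#' @export
mean_profile <- function(matrix) {
  if (!inherits(matrix, "signal_matrix")) stop("expected a signal_matrix")
  if (nrow(matrix) == 0) stop("cannot profile an empty matrix")
  m <- unclass(matrix)
  m[attr(matrix, "flagged")] <- NA_real_
  colMeans(m, na.rm = TRUE)
}
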