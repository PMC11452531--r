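#' Read a BED3/BED6/BED12 file
#'
#' Tab-separated, no header; `track` and `browser` lines and `#` comments
#' are skipped. Columns beyond the first three are kept when present
#' (name, score, strand); BED12 block columns are ignored.
#'
#' @param path file path.
#' @return an [interval_set].
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  if (length(lines) == 0)
    return(sort_and_validate(data.frame(chrom = character(),
                                        start = numeric(), end = numeric())))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols < 3))
    stop(sprintf("BED line %d has fewer than 3 columns",
                 which(ncols < 3)[1]))
  n <- min(ncols, 6)
  df <- data.frame(chrom = vapply(fields, `[`, "", 1),
                   start = as.numeric(vapply(fields, `[`, "", 2)),
                   end = as.numeric(vapply(fields, `[`, "", 3)))
  if (n >= 4) df$name <- vapply(fields, function(f) if (length(f) >= 4) f[4] else ".", "")
  if (n >= 5) df$score <- suppressWarnings(as.numeric(
    vapply(fields, function(f) if (length(f) >= 5) f[5] else "0", "")))
  if (n >= 6) df$strand <- vapply(fields, function(f) if (length(f) >= 6) f[6] else ".", "")
  sort_and_validate(df)
}

#' Write intervals as BED
#'
#' Writes `chrom`, `start`, `end` and, when present, `name`, `score`,
#' `strand` as tab-separated BED with no header.
#'
#' @param x interval set or data frame.
#' @param path output path.
#' @export
write_bed <- function(x, path) {
  x <- as.data.frame(x)
  cols <- intersect(c("chrom", "start", "end", "name", "score", "strand"),
                    names(x))
  # BED columns are positional: stop at the first absent optional column
  want <- c("chrom", "start", "end", "name", "score", "strand")
  keep <- want[seq_len(max(which(want %in% cols & cumsum(!want %in% cols) == 0)))]
  df <- x[, keep, drop = FALSE]
  df$start <- format_bp(df$start)
  df$end <- format_bp(df$end)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

format_bp <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read an ENCODE narrowPeak file
#'
#' Expects the 10-column narrowPeak layout (BED6 + signalValue, -log10 P,
#' -log10 Q, summit offset); column 8 is the peak's -log10 P value. Track
#' and comment lines are skipped. Malformed rows (wrong column count,
#' end <= start, missing -log10 P) raise an error naming the line.
#'
#' @param path file path.
#' @return a sorted data frame of peak calls with columns `chrom`, `start`,
#'   `end`, `name`, `score`, `strand`, `signal`, `neg_log10_p`,
#'   `neg_log10_q`, `summit`.
#' @export
read_narrowpeak <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  empty <- data.frame(chrom = character(), start = numeric(), end = numeric(),
                      name = character(), score = numeric(),
                      strand = character(), signal = numeric(),
                      neg_log10_p = numeric(), neg_log10_q = numeric(),
                      summit = numeric())
  if (length(lines) == 0) return(sort_and_validate(empty))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 10)
  if (length(bad) > 0)
    stop(sprintf("narrowPeak line %d: expected 10 columns, found %d",
                 lineno[bad[1]], lengths(fields)[bad[1]]))
  m <- do.call(rbind, fields)
  df <- data.frame(chrom = m[, 1],
                   start = as.numeric(m[, 2]),
                   end = as.numeric(m[, 3]),
                   name = m[, 4],
                   score = suppressWarnings(as.numeric(m[, 5])),
                   strand = m[, 6],
                   signal = suppressWarnings(as.numeric(m[, 7])),
                   neg_log10_p = suppressWarnings(as.numeric(m[, 8])),
                   neg_log10_q = suppressWarnings(as.numeric(m[, 9])),
                   summit = suppressWarnings(as.numeric(m[, 10])))
  bad_p <- which(is.na(df$neg_log10_p) | df$neg_log10_p < 0)
  if (length(bad_p) > 0)
    stop(sprintf("narrowPeak line %d: missing or negative -log10 P",
                 lineno[bad_p[1]]))
  bad_iv <- which(is.na(df$start) | is.na(df$end) | df$end <= df$start)
  if (length(bad_iv) > 0)
    stop(sprintf("narrowPeak line %d: end <= start", lineno[bad_iv[1]]))
  sort_and_validate(df)
}

#' Write peak calls as narrowPeak
#'
#' @param peaks data frame as returned by [read_narrowpeak()]; absent
#'   optional columns are filled with narrowPeak placeholders.
#' @param path output path.
#' @export
write_narrowpeak <- function(peaks, path) {
  peaks <- as.data.frame(peaks)
  n <- nrow(peaks)
  get <- function(col, default) if (col %in% names(peaks)) peaks[[col]] else rep(default, n)
  df <- data.frame(chrom = peaks$chrom,
                   start = format_bp(peaks$start),
                   end = format_bp(peaks$end),
                   name = get("name", "."),
                   score = get("score", 0),
                   strand = get("strand", "."),
                   signal = get("signal", 0),
                   neg_log10_p = peaks$neg_log10_p,
                   neg_log10_q = get("neg_log10_q", -1),
                   summit = get("summit", -1))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
}

#' Read a bedGraph file into a binned signal track
#'
#' bedGraph records (chrom, start, end, value) are resampled onto
#' `bin_size`-bp bins by bp-weighted mean; base pairs not covered by any
#' record are treated as 0. `track` lines are ignored.
#'
#' @param path file path.
#' @param bin_size target bin width in bp.
#' @param chrom_sizes named vector of chromosome lengths.
#' @return a [signal_track].
#' @export
read_bedgraph <- function(path, bin_size, chrom_sizes) {
  lines <- readLines(path)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(lines)]
  chrom_sizes <- unlist(chrom_sizes)
  values <- lapply(chrom_sizes, function(len) numeric(ceiling(len / bin_size)))
  if (length(lines) > 0) {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 4)) stop("bedGraph line with fewer than 4 columns")
    m <- do.call(rbind, fields)
    chrom <- m[, 1]
    start <- as.numeric(m[, 2]); end <- as.numeric(m[, 3])
    val <- as.numeric(m[, 4])
    unknown <- setdiff(unique(chrom), names(chrom_sizes))
    if (length(unknown) > 0)
      stop("bedGraph chromosome(s) not in chrom_sizes: ",
           paste(unknown, collapse = ", "))
    for (cn in unique(chrom)) {
      sel <- chrom == cn
      n_bins <- length(values[[cn]])
      acc <- numeric(n_bins)
      for (j in which(sel)) {
        b1 <- floor(start[j] / bin_size) + 1
        b2 <- min(floor((end[j] - 1) / bin_size) + 1, n_bins)
        for (b in b1:b2) {
          lo <- max(start[j], (b - 1) * bin_size)
          hi <- min(end[j], b * bin_size)
          acc[b] <- acc[b] + val[j] * (hi - lo)
        }
      }
      width <- pmin(seq_len(n_bins) * bin_size, chrom_sizes[[cn]]) -
        (seq_len(n_bins) - 1) * bin_size
      values[[cn]] <- acc / width
    }
  }
  signal_track(values, bin_size, chrom_sizes)
}

#' Write a signal track as bedGraph
#'
#' Adjacent bins with identical values are collapsed into one record;
#' zero-valued runs are written too, so the file round-trips exactly.
#'
#' @param track a [signal_track].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(inherits(track, "signal_track"))
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (length(v) == 0) next
    r <- rle(v)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths + 1
    writeLines(sprintf("%s\t%s\t%s\t%s", chrom,
                       format_bp((starts_bin - 1) * track$bin_size),
                       format_bp(pmin(ends_bin * track$bin_size,
                                      track$chrom_sizes[[chrom]])),
                       format(r$values, scientific = FALSE, trim = TRUE)),
               con)
  }
  invisible(path)
}

#' Read gene models from BED6/BED12 or a minimal GTF
#'
#' BED input uses columns chrom/start/end/name/score/strand (0-based
#' half-open). GTF input uses only `gene` feature lines and requires a
#' `gene_name` (or `gene_id`) attribute; 1-based inclusive GTF coordinates
#' are converted to the 0-based half-open convention on read. When a
#' `gene_biotype`/`gene_type` attribute is present, it is kept so callers
#' can filter to protein-coding genes; otherwise all genes are accepted.
#'
#' @param path file path.
#' @param format `"bed"`, `"gtf"`, or `"auto"` (by file extension).
#' @return data frame of gene models: `chrom`, `start`, `end`, `gene`,
#'   `strand`, `length` and optionally `biotype`.
#' @export
read_gene_models <- function(path, format = c("auto", "bed", "gtf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.gtf$", path, ignore.case = TRUE)) "gtf" else "bed"
  if (format == "bed") {
    bed <- as.data.frame(read_bed(path))
    if (!"name" %in% names(bed)) stop("gene model BED needs a name column")
    if (!"strand" %in% names(bed)) stop("gene model BED needs a strand column")
    out <- data.frame(chrom = bed$chrom, start = bed$start, end = bed$end,
                      gene = bed$name, strand = bed$strand)
  } else {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(lines)]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 9)) stop("GTF line with fewer than 9 columns")
    m <- do.call(rbind, fields)
    gene_rows <- m[, 3] == "gene"
    if (!any(gene_rows)) stop("no 'gene' feature lines found in GTF")
    m <- m[gene_rows, , drop = FALSE]
    get_attr <- function(attrs, key) {
      hit <- regmatches(attrs, regexpr(paste0(key, ' "[^"]*"'), attrs))
      out <- rep(NA_character_, length(attrs))
      found <- grepl(paste0(key, ' "'), attrs)
      out[found] <- sub(paste0(key, ' "([^"]*)"'), "\\1", hit)
      out
    }
    name <- get_attr(m[, 9], "gene_name")
    id <- get_attr(m[, 9], "gene_id")
    gene <- ifelse(is.na(name), id, name)
    if (any(is.na(gene))) stop("GTF gene line without gene_name or gene_id")
    out <- data.frame(chrom = m[, 1],
                      start = as.numeric(m[, 4]) - 1,  # GTF is 1-based inclusive
                      end = as.numeric(m[, 5]),
                      gene = gene,
                      strand = m[, 7])
    biotype <- get_attr(m[, 9], "gene_biotype")
    biotype2 <- get_attr(m[, 9], "gene_type")
    biotype <- ifelse(is.na(biotype), biotype2, biotype)
    if (any(!is.na(biotype))) out$biotype <- biotype
  }
  if (!all(out$strand %in% c("+", "-")))
    stop("gene models must carry a +/- strand")
  out <- as.data.frame(sort_and_validate(out))
  out$length <- out$end - out$start
  out
}

#' Write gene models as BED6
#'
#' @param genes gene-model data frame (`chrom`, `start`, `end`, `gene`,
#'   `strand`).
#' @param path output path.
#' @export
write_gene_models <- function(genes, path) {
  df <- data.frame(chrom = genes$chrom, start = genes$start, end = genes$end,
                   name = genes$gene, score = 0, strand = genes$strand)
  write_bed(df, path)
}

#' Write a report table as commented-header TSV
#'
#' Tab-separated with a single header row prefixed by `#`, the layout used
#' for all tabular outputs of the pipeline.
#'
#' @param df data frame (list columns are comma-joined).
#' @param path output path.
#' @export
write_tsv_report <- function(df, path) {
  df <- as.data.frame(df)
  for (col in names(df))
    if (is.list(df[[col]]))
      df[[col]] <- vapply(df[[col]], paste, "", collapse = ",")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  if (nrow(df) > 0)
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a commented-header TSV written by [write_tsv_report()]
#'
#' @param path file path.
#' @return data frame with the header row restored as column names.
#' @export
read_tsv_report <- function(path) {
  header <- sub("^#", "", readLines(path, n = 1))
  cols <- strsplit(header, "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", skip = 1, header = FALSE,
                          col.names = cols, stringsAsFactors = FALSE,
                          quote = "", comment.char = "")
  df
}

#' Read a counts matrix TSV (gene x sample)
#'
#' First column is the gene name; remaining columns are per-sample counts.
#' A leading `#` on the header row is tolerated.
#'
#' @param path file path.
#' @return integer matrix with gene row names.
#' @export
read_counts <- function(path) {
  first <- readLines(path, n = 1)
  df <- utils::read.table(path, sep = "\t", header = !startsWith(first, "#"),
                          skip = if (startsWith(first, "#")) 1 else 0,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (startsWith(first, "#")) {
    cols <- strsplit(sub("^#", "", first), "\t", fixed = TRUE)[[1]]
    names(df) <- cols
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "double"
  m
}
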