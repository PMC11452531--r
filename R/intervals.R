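#' Genomic interval sets
#'
#' An `interval_set` is a data frame with at least the columns `chrom`
#' (character), `start` and `end` (0-based half-open, BED convention),
#' sorted by (chrom, start, end, name) with natural-number-aware chromosome
#' order (chr2 before chr10). The attribute `merged` records whether the set
#' is known to contain no overlapping or bookended intervals per chromosome.
#'
#' @name interval_set
NULL

# Natural chromosome order: split a trailing integer off the name so that
# chr2 < chr10; names without a trailing integer sort after numbered ones
# within the same prefix, then lexicographically.
chrom_order_key <- function(chrom) {
  num <- suppressWarnings(as.numeric(sub("^.*?([0-9]+)$", "\\1", chrom)))
  num[!grepl("[0-9]$", chrom)] <- Inf
  prefix <- sub("[0-9]+$", "", chrom)
  list(prefix = prefix, num = num, full = chrom)
}

#' Order indices for chromosome names
#'
#' @param chrom character vector of chromosome names.
#' @return integer permutation ordering `chrom` naturally (chr2 < chr10).
#' @keywords internal
order_chroms <- function(chrom) {
  k <- chrom_order_key(chrom)
  order(k$prefix, k$num, k$full)
}

new_interval_set <- function(df, merged = FALSE) {
  rownames(df) <- NULL
  structure(df, class = c("interval_set", "data.frame"), merged = merged)
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("interval_set: %d intervals on %d chromosome(s)%s\n",
              nrow(x), length(unique(x$chrom)),
              if (isTRUE(attr(x, "merged"))) " [merged]" else ""))
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat(sprintf("... and %d more\n", nrow(x) - 10))
  invisible(x)
}

#' Strip interval-set attributes back to a plain data frame
#'
#' @param x an `interval_set`.
#' @param ... unused.
#' @export
as.data.frame.interval_set <- function(x, ...) {
  attr(x, "merged") <- NULL
  attr(x, "members") <- NULL
  class(x) <- "data.frame"
  x
}

#' Validate and sort genomic intervals
#'
#' Checks the interval invariants (`end > start >= 0`, non-empty chromosome
#' name) and sorts by chromosome (naturally ordered), start, end and, for
#' ties, name. Duplicates are preserved; the result is flagged unmerged.
#'
#' @param x data frame with columns `chrom`, `start`, `end`; optional
#'   `name`, `score`, `strand`.
#' @return an [interval_set].
#' @export
#' @examples
#' sort_and_validate(data.frame(chrom = "chr1", start = c(10, 0), end = c(20, 5)))
sort_and_validate <- function(x) {
  x <- as.data.frame(x)
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0)
    stop("missing interval column(s): ", paste(missing_cols, collapse = ", "))
  if (nrow(x) == 0) {
    x$chrom <- as.character(x$chrom)
    return(new_interval_set(x, merged = FALSE))
  }
  x$chrom <- as.character(x$chrom)
  x$start <- as.numeric(x$start)
  x$end <- as.numeric(x$end)
  bad <- which(is.na(x$chrom) | !nzchar(x$chrom) |
                 is.na(x$start) | is.na(x$end) |
                 x$start < 0 | x$end <= x$start)
  if (length(bad) > 0) {
    b <- bad[1]
    stop(sprintf(
      "invalid interval at record %d: %s:%s-%s (need end > start >= 0 and a chromosome name)",
      b, x$chrom[b], format(x$start[b], scientific = FALSE),
      format(x$end[b], scientific = FALSE)))
  }
  if ("strand" %in% names(x)) {
    if (!all(x$strand %in% c("+", "-", ".")))
      stop("strand must be one of '+', '-', '.'")
  }
  key <- chrom_order_key(x$chrom)
  nm <- if ("name" %in% names(x)) as.character(x$name) else rep("", nrow(x))
  ord <- order(key$prefix, key$num, key$full, x$start, x$end, nm)
  new_interval_set(x[ord, , drop = FALSE], merged = FALSE)
}

as_interval_set <- function(x) {
  if (inherits(x, "interval_set")) x else sort_and_validate(x)
}

#' Merge intervals separated by at most a maximum gap
#'
#' Computes, per chromosome, the transitive closure of the relation
#' "gap(a, b) <= max_gap" where `gap(a, b) = b$start - a$end` for `a`
#' preceding `b`. Overlapping and bookended intervals (gap 0) always merge,
#' matching the `bedtools merge -d` convention. The operation is idempotent
#' and never decreases total covered base pairs.
#'
#' @param x an [interval_set] (or coercible data frame).
#' @param max_gap maximum inter-interval distance in bp (>= 0) for merging.
#' @return a merged [interval_set] with columns `chrom`, `start`, `end` and
#'   `n_members` (number of input intervals absorbed into each output
#'   interval). The attribute `members` holds, for each output interval, the
#'   integer indices of its members in the sorted input.
#' @export
merge_with_gap <- function(x, max_gap = 0) {
  if (!is.numeric(max_gap) || length(max_gap) != 1 || is.na(max_gap) || max_gap < 0)
    stop("max_gap must be a single non-negative number")
  x <- as_interval_set(x)
  if (nrow(x) == 0) {
    out <- new_interval_set(
      data.frame(chrom = character(), start = numeric(), end = numeric(),
                 n_members = integer()), merged = TRUE)
    attr(out, "members") <- list()
    return(out)
  }
  # sorted by (chrom, start): within a chromosome a running maximum of `end`
  # identifies cluster breaks where the gap to the next start exceeds max_gap
  chrom_chg <- c(TRUE, x$chrom[-1] != x$chrom[-nrow(x)])
  run_end <- numeric(nrow(x))
  grp <- integer(nrow(x))
  g <- 0L
  cur_end <- -Inf
  for (i in seq_len(nrow(x))) {
    if (chrom_chg[i] || x$start[i] - cur_end > max_gap) {
      g <- g + 1L
      cur_end <- x$end[i]
    } else {
      cur_end <- max(cur_end, x$end[i])
    }
    grp[i] <- g
    run_end[i] <- cur_end
  }
  idx <- split(seq_len(nrow(x)), grp)
  out <- data.frame(
    chrom = vapply(idx, function(i) x$chrom[i[1]], character(1)),
    start = vapply(idx, function(i) min(x$start[i]), numeric(1)),
    end = vapply(idx, function(i) max(x$end[i]), numeric(1)),
    n_members = lengths(idx))
  out <- new_interval_set(out, merged = TRUE)
  attr(out, "members") <- unname(idx)
  out
}

#' Coverage of a query interval set by a subject set
#'
#' Reports, for `query` regions against `subject` regions, the number and
#' fraction of query regions with at least 1 bp of intersection, and the
#' number and fraction of query base pairs covered by the subject. The
#' subject is internally merged (gap 0) first so overlapping subject
#' intervals are not double-counted; query intervals are counted as given,
#' one `n_overlapping` contribution per query region regardless of how many
#' subject intervals it touches. The roles are not symmetric.
#'
#' @param query,subject interval sets (or coercible data frames).
#' @return an object of class `overlap_report`: a list with `n_query`,
#'   `n_overlapping`, `region_fraction`, `query_bp`, `intersect_bp`,
#'   `bp_fraction`, `empty_query`, and `per_query` (bp of each sorted query
#'   interval covered by the subject).
#' @export
coverage_report <- function(query, subject) {
  query <- as_interval_set(query)
  subject <- merge_with_gap(subject, 0)
  if (nrow(query) == 0) {
    rep0 <- list(n_query = 0L, n_overlapping = 0L, region_fraction = 0,
                 query_bp = 0, intersect_bp = 0, bp_fraction = 0,
                 empty_query = TRUE, per_query = numeric(0))
    return(structure(rep0, class = "overlap_report"))
  }
  per_query <- numeric(nrow(query))
  sub_chrom <- split(seq_len(nrow(subject)), subject$chrom)
  q_chrom <- split(seq_len(nrow(query)), query$chrom)
  for (chrom in names(q_chrom)) {
    qi <- q_chrom[[chrom]]
    si <- sub_chrom[[chrom]]
    if (is.null(si)) next
    s <- subject$start[si]; e <- subject$end[si]
    cumlen <- cumsum(e - s)
    a <- query$start[qi]; b <- query$end[qi]
    # merged subject => s and e strictly increasing, intervals non-touching
    lo <- findInterval(a, e) + 1L        # first subject with end > a
    hi <- findInterval(b - 0.5, s)       # last subject with start < b
    ov <- numeric(length(qi))
    ok <- lo <= hi
    if (any(ok)) {
      l <- lo[ok]; h <- hi[ok]
      cum0 <- c(0, cumlen)
      total <- cum0[h + 1L] - cum0[l]
      trim_left <- pmax(0, a[ok] - s[l])
      trim_right <- pmax(0, e[h] - b[ok])
      ov[ok] <- total - trim_left - trim_right
    }
    per_query[qi] <- ov
  }
  query_bp <- sum(query$end - query$start)
  intersect_bp <- sum(per_query)
  rep <- list(
    n_query = nrow(query),
    n_overlapping = sum(per_query >= 1),
    region_fraction = sum(per_query >= 1) / nrow(query),
    query_bp = query_bp,
    intersect_bp = intersect_bp,
    bp_fraction = intersect_bp / query_bp,
    empty_query = FALSE,
    per_query = per_query)
  structure(rep, class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf(
    "overlap_report: %d/%d query regions overlap (%.1f%%); %s/%s bp covered (%.1f%%)%s\n",
    x$n_overlapping, x$n_query, 100 * x$region_fraction,
    format(x$intersect_bp, big.mark = ","), format(x$query_bp, big.mark = ","),
    100 * x$bp_fraction, if (x$empty_query) " [empty query]" else ""))
  invisible(x)
}

#' Convert an overlap report to a one-row data frame
#'
#' @param x an `overlap_report`.
#' @param ... unused.
#' @export
as.data.frame.overlap_report <- function(x, ...) {
  data.frame(n_query = x$n_query, n_overlapping = x$n_overlapping,
             region_fraction = x$region_fraction, query_bp = x$query_bp,
             intersect_bp = x$intersect_bp, bp_fraction = x$bp_fraction)
}

#' Threshold a binned signal track into intervals
#'
#' Returns maximal runs of bins whose value satisfies the predicate
#' (`>= threshold` or `<= threshold`), merged into half-open intervals and
#' clamped to the chromosome length. Used e.g. to turn a replication-timing
#' track into a set of late-replicating regions.
#'
#' @param track a [signal_track].
#' @param threshold numeric cutoff.
#' @param direction `"ge"` (value >= threshold) or `"le"` (value <= threshold).
#' @return a merged [interval_set].
#' @export
threshold_track_to_intervals <- function(track, threshold, direction = c("ge", "le")) {
  direction <- match.arg(direction)
  stopifnot(inherits(track, "signal_track"))
  rows <- list()
  for (chrom in names(track$values)) {
    v <- track$values[[chrom]]
    if (length(v) == 0) next
    pred <- if (direction == "ge") v >= threshold else v <= threshold
    pred[is.na(pred)] <- FALSE
    r <- rle(pred)
    ends_bin <- cumsum(r$lengths)
    starts_bin <- ends_bin - r$lengths + 1L
    keep <- which(r$values)
    if (length(keep) == 0) next
    rows[[chrom]] <- data.frame(
      chrom = chrom,
      start = (starts_bin[keep] - 1) * track$bin_size,
      end = pmin(ends_bin[keep] * track$bin_size, track$chrom_sizes[[chrom]]))
  }
  if (length(rows) == 0)
    return(merge_with_gap(data.frame(chrom = character(), start = numeric(),
                                     end = numeric()), 0))
  out <- sort_and_validate(do.call(rbind, rows))
  attr(out, "merged") <- TRUE
  out
}

#' Rename chromosomes using an explicit map
#'
#' Chromosome-name reconciliation (e.g. "1" vs "chr1") is opt-in: overlap
#' operations never strip or add prefixes silently, so mismatched naming
#' yields zero overlap with a warning rather than a silently wrong answer.
#'
#' @param x an interval set or data frame with a `chrom` column.
#' @param map named character vector, old name -> new name.
#' @return `x` with renamed chromosomes, re-sorted.
#' @export
rename_chroms <- function(x, map) {
  stopifnot(is.character(map), !is.null(names(map)))
  x <- as.data.frame(x)
  hit <- x$chrom %in% names(map)
  x$chrom[hit] <- unname(map[x$chrom[hit]])
  sort_and_validate(x)
}
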