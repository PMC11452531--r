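# Independent brute-force oracles for the interval algebra. These are kept
# deliberately naive (per-base boolean arrays, explicit transitive closure)
# so they share no code path with the implementation they check.

# transitive closure of "gap <= max_gap" by repeated pairwise sweeps
oracle_merge <- function(df, max_gap) {
  out <- list()
  for (chrom in unique(df$chrom)) {
    iv <- df[df$chrom == chrom, c("start", "end"), drop = FALSE]
    iv <- iv[order(iv$start, iv$end), , drop = FALSE]
    comp <- seq_len(nrow(iv))
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(iv))) for (j in seq_len(nrow(iv))) {
        if (comp[i] == comp[j]) next
        gap <- max(iv$start[i], iv$start[j]) - min(iv$end[i], iv$end[j])
        if (gap <= max_gap) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
      if (!changed) break
    }
    for (cc in unique(comp)) {
      sel <- comp == cc
      out[[length(out) + 1]] <- data.frame(
        chrom = chrom, start = min(iv$start[sel]), end = max(iv$end[sel]))
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), start = numeric(), end = numeric()))
  out <- do.call(rbind, out)
  out[order(out$chrom, out$start), , drop = FALSE]
}

# per-base merge oracle: dilate every interval by the gap on the right,
# take maximal covered runs of the boolean array, trim the dilation
oracle_merge_perbase <- function(df, max_gap) {
  out <- list()
  for (chrom in sort(unique(df$chrom))) {
    iv <- df[df$chrom == chrom, , drop = FALSE]
    maxc <- max(iv$end) + max_gap + 1
    cov <- logical(maxc)
    for (j in seq_len(nrow(iv)))
      cov[seq(iv$start[j] + 1, iv$end[j] + max_gap)] <- TRUE
    r <- rle(cov)
    pos <- cumsum(r$lengths)
    runs_end <- pos[r$values]
    runs_start <- runs_end - r$lengths[r$values] + 1
    out[[chrom]] <- data.frame(chrom = chrom, start = runs_start - 1,
                               end = runs_end - max_gap)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

# per-base boolean-array coverage oracle
oracle_coverage <- function(query, subject) {
  query <- as.data.frame(query); subject <- as.data.frame(subject)
  per_query <- numeric(nrow(query))
  for (chrom in unique(query$chrom)) {
    qsel <- which(query$chrom == chrom)
    ssel <- subject$chrom == chrom
    maxc <- max(c(query$end[qsel], subject$end[ssel], 1))
    cov <- logical(maxc)
    for (j in which(ssel))
      cov[seq(subject$start[j] + 1, subject$end[j])] <- TRUE
    for (q in qsel)
      per_query[q] <- sum(cov[seq(query$start[q] + 1, query$end[q])])
  }
  list(per_query = per_query,
       n_overlapping = sum(per_query >= 1),
       intersect_bp = sum(per_query),
       query_bp = sum(query$end - query$start))
}

# random interval set on a small genome
random_intervals <- function(n, n_chrom = 2, max_coord = 1e6, max_width = 5000) {
  chrom <- paste0("chr", sample.int(n_chrom, n, replace = TRUE))
  start <- floor(runif(n, 0, max_coord - max_width))
  width <- ceiling(runif(n, 1, max_width))
  data.frame(chrom = chrom, start = start, end = start + width)
}

# brute-force two-sample KS statistic by scanning every pooled value
oracle_ks_D <- function(a, b) {
  grid <- c(a, b)
  max(vapply(grid, function(x) abs(mean(a <= x) - mean(b <= x)), numeric(1)))
}
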