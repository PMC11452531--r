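test_that("sort_and_validate orders records and rejects malformed intervals", {
  s <- sort_and_validate(data.frame(chrom = "chr1",
                                    start = c(10, 0), end = c(20, 5)))
  expect_equal(s$start, c(0, 10))
  expect_false(attr(s, "merged"))

  empty <- sort_and_validate(data.frame(chrom = character(),
                                        start = numeric(), end = numeric()))
  expect_equal(nrow(empty), 0)

  expect_error(sort_and_validate(data.frame(chrom = "chr1", start = 5, end = 5)),
               "invalid interval")
  expect_error(sort_and_validate(data.frame(chrom = "chr1", start = -1, end = 5)),
               "invalid interval")
  expect_error(sort_and_validate(data.frame(chrom = "", start = 0, end = 5)),
               "invalid interval")
  # duplicates preserved
  dup <- sort_and_validate(data.frame(chrom = "chr1", start = c(1, 1),
                                      end = c(5, 5)))
  expect_equal(nrow(dup), 2)
})

test_that("chromosome order is natural-number aware", {
  s <- sort_and_validate(data.frame(chrom = c("chr10", "chr2", "chrX", "chr1"),
                                    start = 0, end = 10))
  expect_equal(s$chrom, c("chr1", "chr2", "chr10", "chrX"))
})

test_that("merge_with_gap handles bookends, the 50-kb rule, and idempotence", {
  # bookended intervals merge at gap 0 (bedtools convention)
  m0 <- merge_with_gap(data.frame(chrom = "chr1", start = c(0, 100),
                                  end = c(100, 200)), 0)
  expect_equal(as.data.frame(m0)[, c("start", "end")],
               data.frame(start = 0, end = 200))

  # a gap of exactly max_gap merges; a larger one does not
  df <- data.frame(chrom = "chr1", start = c(0, 50100, 150000),
                   end = c(100, 50200, 150100))
  m <- merge_with_gap(df, 50000)
  expect_equal(m$start, c(0, 150000))
  expect_equal(m$end, c(50200, 150100))

  # idempotence
  m2 <- merge_with_gap(as.data.frame(m)[, c("chrom", "start", "end")], 50000)
  expect_equal(m2$start, m$start)
  expect_equal(m2$end, m$end)

  expect_error(merge_with_gap(df, -1), "non-negative")
  expect_true(attr(m, "merged"))
})

test_that("merge_with_gap matches the transitive-closure oracle on random sets", {
  set.seed(42)
  for (rep in 1:60) {
    df <- random_intervals(sample(1:40, 1), n_chrom = 2, max_coord = 2e5,
                           max_width = 3e4)
    gap <- sample(c(0, 10, 1000, 2e4), 1)
    got <- as.data.frame(merge_with_gap(df, gap))
    want <- oracle_merge(df, gap)
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    # conservation: covered bp never exceeds multiset sum
    expect_lte(sum(got$end - got$start) - 1e-9, sum(df$end - df$start))
  }
})

test_that("merge_with_gap agrees with GenomicRanges reduce", {
  skip_if_not_installed("GenomicRanges")
  set.seed(7)
  for (rep in 1:20) {
    df <- random_intervals(50, n_chrom = 2)
    gap <- sample(c(0, 500, 50000), 1)
    got <- as.data.frame(merge_with_gap(df, gap))
    gr <- GenomicRanges::reduce(
      GenomicRanges::GRanges(factor(df$chrom, levels = sort(unique(df$chrom))),
                             IRanges::IRanges(df$start + 1, df$end)),
      min.gapwidth = gap + 1)
    gr <- sort(gr)
    expect_equal(got$start, GenomicRanges::start(gr) - 1)
    expect_equal(got$end, GenomicRanges::end(gr))
  }
})

test_that("coverage_report matches hand-worked examples", {
  one <- data.frame(chrom = "chr1", start = 0, end = 100)
  r <- coverage_report(one, one)
  expect_equal(r$region_fraction, 1)
  expect_equal(r$bp_fraction, 1)

  r2 <- coverage_report(one, data.frame(chrom = "chr2", start = 0, end = 100))
  expect_equal(r2$region_fraction, 0)
  expect_equal(r2$bp_fraction, 0)

  r3 <- coverage_report(one, data.frame(chrom = "chr1", start = 50, end = 150))
  expect_equal(r3$n_overlapping, 1)
  expect_equal(r3$intersect_bp, 50)
  expect_equal(r3$bp_fraction, 0.5)

  r4 <- coverage_report(data.frame(chrom = character(), start = numeric(),
                                   end = numeric()), one)
  expect_equal(r4$n_query, 0)
  expect_equal(r4$region_fraction, 0)
  expect_true(r4$empty_query)
})

test_that("coverage_report matches the per-base oracle and is monotone in subject", {
  set.seed(99)
  for (rep in 1:40) {
    q <- random_intervals(sample(1:30, 1), max_coord = 1e5, max_width = 5000)
    s <- random_intervals(sample(1:30, 1), max_coord = 1e5, max_width = 5000)
    got <- coverage_report(q, s)
    want <- oracle_coverage(sort_and_validate(q), s)
    expect_equal(got$per_query, want$per_query)
    expect_equal(got$n_overlapping, want$n_overlapping)
    expect_equal(got$intersect_bp, want$intersect_bp)
    expect_equal(got$query_bp, want$query_bp)

    # adding subject intervals never decreases either fraction
    extra <- rbind(s, random_intervals(5, max_coord = 1e5, max_width = 5000))
    grown <- coverage_report(q, extra)
    expect_gte(grown$region_fraction, got$region_fraction)
    expect_gte(grown$bp_fraction, got$bp_fraction)
  }
})

test_that("threshold_track_to_intervals extracts maximal qualifying runs", {
  cs <- c(chr1 = 400)
  flat1 <- signal_track(list(chr1 = rep(1, 13)), 32, cs)
  expect_equal(nrow(threshold_track_to_intervals(flat1, 2, "ge")), 0)

  all1 <- threshold_track_to_intervals(flat1, 1, "ge")
  expect_equal(as.data.frame(all1)[, c("start", "end")],
               data.frame(start = 0, end = 400))  # clamped to chrom length

  alt <- signal_track(list(chr1 = rep(c(0, 5), length.out = 13)), 32, cs)
  iv <- threshold_track_to_intervals(alt, 3, "ge")
  expect_equal(nrow(iv), 6)                  # every value-5 bin separately
  expect_equal(iv$start, 32 * seq(1, 11, 2))
  expect_equal(iv$end, 32 * seq(2, 12, 2))
  # per-bin predicate oracle
  bins_ok <- which(rep(c(0, 5), length.out = 13) >= 3)
  expect_equal(sum(iv$end - iv$start), 32 * length(bins_ok))

  le <- threshold_track_to_intervals(alt, 3, "le")
  expect_equal(nrow(le), 7)

  empty <- signal_track(list(chr1 = numeric(0)), 32, c(chr1 = 0))
  expect_error(signal_track(list(chr1 = numeric(1)), 32, c(chr1 = 0)))
})

test_that("rename_chroms remaps names opt-in", {
  x <- rename_chroms(data.frame(chrom = c("1", "chr2"), start = 0, end = 10),
                     c("1" = "chr1"))
  expect_equal(sort(unique(x$chrom)), c("chr1", "chr2"))
})
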