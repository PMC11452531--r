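chrom_sizes_1 <- c(chr1 = 10000)

test_that("extend_tags extends strand-aware and clamps to the chromosome", {
  cs <- c(chr1 = 100000)
  plus <- extend_tags(data.frame(chrom = "chr1", start = 100, end = 175,
                                 strand = "+"), 200, cs)
  expect_equal(c(plus$start, plus$end), c(100, 300))

  minus <- extend_tags(data.frame(chrom = "chr1", start = 300, end = 375,
                                  strand = "-"), 200, cs)
  expect_equal(c(minus$start, minus$end), c(175, 375))

  clamped <- extend_tags(data.frame(chrom = "chr1", start = 50, end = 125,
                                    strand = "-"), 200, cs)
  expect_equal(c(clamped$start, clamped$end), c(0, 125))

  right <- extend_tags(data.frame(chrom = "chr1", start = 99950, end = 99990,
                                  strand = "+"), 200, cs)
  expect_equal(c(right$start, right$end), c(99950, 100000))

  expect_error(extend_tags(data.frame(chrom = "chrZ", start = 0, end = 75,
                                      strand = "+"), 200, cs),
               "unknown chromosome")
})

test_that("bin_density counts overlapping fragments per bin", {
  none <- bin_density(data.frame(chrom = character(), start = numeric(),
                                 end = numeric()), 32, chrom_sizes_1)
  expect_true(all(none$values$chr1 == 0))
  expect_length(none$values$chr1, ceiling(10000 / 32))

  one <- bin_density(data.frame(chrom = "chr1", start = 0, end = 200), 32,
                     chrom_sizes_1)
  # bin 7 spans 192-224 and still touches the fragment; bin 8 does not
  expect_equal(one$values$chr1[1:8], c(rep(1, 7), 0))

  two <- bin_density(data.frame(chrom = "chr1", start = c(0, 0),
                                end = c(200, 200)), 32, chrom_sizes_1)
  expect_equal(two$values$chr1, 2 * one$values$chr1)

  # per-bin overlap oracle on random fragments
  set.seed(5)
  frags <- data.frame(chrom = "chr1", start = floor(runif(50, 0, 9000)))
  frags$end <- frags$start + sample(1:500, 50, replace = TRUE)
  got <- bin_density(frags, 32, chrom_sizes_1)$values$chr1
  for (b in sample(seq_along(got), 40)) {
    lo <- (b - 1) * 32; hi <- b * 32
    expect_equal(got[b], sum(frags$start < hi & frags$end > lo))
  }
  # every fragment covers at least one bin
  expect_gte(sum(got > 0), 1)
})

test_that("log2_ratio computes scaled and unscaled ratios with guards", {
  t1 <- signal_track(list(chr1 = c(3, 1, 2, 0)), 32, c(chr1 = 128))
  expect_true(all(log2_ratio(t1, t1)$values$chr1 == 0))

  s <- signal_track(list(chr1 = c(3)), 32, c(chr1 = 32))
  i <- signal_track(list(chr1 = c(1)), 32, c(chr1 = 32))
  expect_equal(log2_ratio(s, i, pseudocount = 1, scale = "none")$values$chr1,
               log2(4 / 2))
  # CPM scaling equalizes single-bin tracks of different totals
  expect_equal(log2_ratio(s, i, pseudocount = 1, scale = "cpm")$values$chr1, 0)

  zero_in <- signal_track(list(chr1 = c(3, 0)), 32, c(chr1 = 64))
  expect_error(log2_ratio(t1 <- signal_track(list(chr1 = c(1, 1)), 32, c(chr1 = 64)),
                          zero_in, pseudocount = 0, scale = "none"),
               "pseudocount")
  short <- signal_track(list(chr1 = c(1)), 32, c(chr1 = 32))
  expect_error(log2_ratio(short, zero_in), "mismatched shape")
})

test_that("tss_matrix anchors rows at the TSS with strand-aware flipping", {
  cs <- c(chr1 = 60000)
  const <- signal_track(list(chr1 = rep(2.5, ceiling(60000 / 32))), 32, cs)
  genes <- data.frame(chrom = "chr1", start = c(20000, 30000),
                      end = c(25000, 36000), strand = c("+", "-"),
                      gene = c("gA", "gB"))
  m <- tss_matrix(const, genes, flank = 5000, matrix_bin = 50)
  expect_equal(ncol(m), 200)
  expect_equal(nrow(m), 2)
  expect_true(all(abs(m - 2.5) < 1e-12))

  # spike in the 32-bp bin containing a minus-strand gene end (TSS)
  v <- numeric(ceiling(60000 / 32))
  v[floor(36000 / 32) + 1] <- 100
  spike <- signal_track(list(chr1 = v), 32, cs)
  ms <- tss_matrix(spike, genes, flank = 5000, matrix_bin = 50)
  hot <- which(ms["gB", ] > 0)
  expect_true(all(abs(hot - 100.5) <= 2))  # center columns of the row

  # out-of-chromosome columns flagged, gene on unknown chrom skipped
  edge <- data.frame(chrom = "chr1", start = 1000, end = 2000,
                     strand = "+", gene = "gE")
  me <- tss_matrix(const, edge, flank = 5000, matrix_bin = 50)
  expect_true(any(attr(me, "flagged")[1, 1:80]))
  expect_warning(
    mm <- tss_matrix(const, rbind(genes, data.frame(chrom = "chrZ", start = 1,
                                                    end = 10, strand = "+",
                                                    gene = "gZ")),
                     5000, 50),
    "skipped")
  expect_equal(nrow(mm), 2)
})

test_that("mean_profile averages columns and ignores flagged cells", {
  cs <- c(chr1 = 60000)
  const <- signal_track(list(chr1 = rep(1, ceiling(60000 / 32))), 32, cs)
  g1 <- data.frame(chrom = "chr1", start = 20000, end = 25000,
                   strand = "+", gene = "gA")
  m1 <- tss_matrix(const, g1)
  expect_equal(unname(mean_profile(m1)), as.numeric(m1[1, ]))

  g2 <- rbind(g1, data.frame(chrom = "chr1", start = 30000, end = 36000,
                             strand = "-", gene = "gB"))
  m2 <- tss_matrix(const, g2)
  expect_equal(unname(mean_profile(m2)),
               as.numeric((m2[1, ] + m2[2, ]) / 2))

  expect_error(mean_profile(m2[0, , drop = FALSE]), "signal_matrix")
})

test_that("tss matrix is invariant under genome reversal", {
  # reversing coordinates and strands mirrors tags and genes; rebuilding the
  # matrix must reproduce it exactly
  cs <- c(chr1 = 64000)
  L <- 64000
  set.seed(21)
  frags <- data.frame(chrom = "chr1", start = floor(runif(400, 0, L - 500)))
  frags$end <- frags$start + 320  # multiple of the 32-bp bin keeps binning exact
  genes <- data.frame(chrom = "chr1", start = c(20000, 40000),
                      end = c(22016, 42016), strand = c("+", "-"),
                      gene = c("gA", "gB"))
  fwd <- tss_matrix(bin_density(frags, 32, cs), genes, 4000, 50)

  rev_frags <- data.frame(chrom = "chr1", start = L - frags$end,
                          end = L - frags$start)
  rev_genes <- data.frame(chrom = "chr1", start = L - genes$end,
                          end = L - genes$start,
                          strand = c("-", "+"), gene = genes$gene)
  bwd <- tss_matrix(bin_density(rev_frags, 32, cs), rev_genes, 4000, 50)
  expect_equal(unclass(bwd)[rownames(fwd), ], unclass(fwd)[, ],
               tolerance = 1e-12)
})
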