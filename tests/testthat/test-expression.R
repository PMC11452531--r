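mk_counts <- function(m, genes = sprintf("g%d", seq_len(nrow(m))),
                      samples = sprintf("s%d", seq_len(ncol(m)))) {
  dimnames(m) <- list(genes, samples)
  m
}

test_that("normalize_counts computes median-of-ratios size factors", {
  single <- mk_counts(matrix(c(5, 9, 2), ncol = 1))
  ns <- normalize_counts(single)
  expect_equal(unname(ns$size_factors), 1)

  same <- mk_counts(matrix(rep(c(10, 20, 30), 3), ncol = 3))
  expect_equal(unname(normalize_counts(same)$size_factors), rep(1, 3),
               tolerance = 1e-12)

  # doubling a sample doubles its factor relative to the other
  a <- c(10, 50, 200, 7)
  doubled <- mk_counts(cbind(a, 2 * a))
  nf <- normalize_counts(doubled)$size_factors
  expect_equal(unname(nf[2] / nf[1]), 2, tolerance = 1e-12)

  expect_error(normalize_counts(mk_counts(matrix(c(1, 0, 0, 1), 2))),
               "cannot normalize")

  # rank order within each sample is preserved
  set.seed(3)
  m <- mk_counts(matrix(rnbinom(60, mu = 50, size = 5) + 1, 12, 5))
  nm <- normalize_counts(m)$normalized
  for (j in seq_len(ncol(m)))
    expect_equal(order(nm[, j]), order(m[, j]))
})

test_that("normalize_counts agrees with the DESeq2 reference implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(17)
  m <- mk_counts(matrix(rnbinom(200, mu = 100, size = 2) + 1, 40, 5))
  ours <- normalize_counts(m)$size_factors
  ref <- DESeq2::estimateSizeFactorsForMatrix(m)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("detect_expressed requires the floor in both genotypes", {
  m <- mk_counts(rbind(c(0, 0, 0, 0),
                       c(100, 120, 0, 2),
                       c(50, 60, 40, 45),
                       c(1, 2, 1, 1)))
  geno <- c("mut", "mut", "comp", "comp")
  got <- detect_expressed(m, geno, min_mean = 10)
  expect_equal(unname(got), c(FALSE, FALSE, TRUE, FALSE))
  # threshold 0: any count in both genotypes qualifies
  expect_equal(unname(detect_expressed(m, geno, min_mean = 0)),
               c(TRUE, TRUE, TRUE, TRUE))
  expect_error(detect_expressed(m, c("a", "a", "a", "a")), "two genotypes")
})

test_that("classify_de applies the fold-change and significance thresholds", {
  rec <- data.frame(log2_fold_change = c(1.5, -0.5, 2.0, -1.4, 1.0),
                    adjusted_p = c(0.01, 0.001, 0.2, 0.04, 0.01))
  got <- classify_de(rec)
  expect_equal(as.character(got$de_class), c("up", "ns", "ns", "down", "ns"))
  # boundary: log2FC exactly at the threshold is not called
  expect_equal(as.character(classify_de(
    data.frame(log2_fold_change = 1, adjusted_p = 1e-9))$de_class), "ns")
  expect_error(classify_de(data.frame(log2_fold_change = 1)), "adjusted_p")
})

test_that("classify_de is threshold-monotone", {
  set.seed(23)
  rec <- data.frame(log2_fold_change = rnorm(200, 0, 1.5),
                    adjusted_p = runif(200))
  strict <- classify_de(rec, lfc_threshold = 1, alpha = 0.05)$de_class
  lax <- classify_de(rec, lfc_threshold = 0.5, alpha = 0.2)$de_class
  moved_to_ns <- strict %in% c("up", "down") & lax == "ns"
  expect_false(any(moved_to_ns))
  # calls never flip sign between thresholds
  expect_false(any(strict == "up" & lax == "down"))
  expect_false(any(strict == "down" & lax == "up"))
})

test_that("welch_de orients the fold change and adjusts with BH", {
  set.seed(41)
  mut <- matrix(rnbinom(40, mu = 100, size = 20), 10, 4)
  comp <- matrix(rnbinom(40, mu = c(rep(400, 12), rep(100, 28)), size = 20), 10, 4)
  m <- mk_counts(cbind(mut, comp))
  geno <- rep(c("mutant", "complemented"), each = 4)
  de <- welch_de(m, geno, numerator_genotype = "complemented")
  expect_gt(de$log2_fold_change[1], 1)            # planted 4x up genes
  expect_equal(de$adjusted_p, p.adjust(de$p_value, "BH"))
  expect_error(welch_de(m[, 1, drop = FALSE], "mutant"), "two genotypes")
})

test_that("bbr_expression_report joins bound genes and counts both significance
           readings", {
  rec <- data.frame(gene = c("A", "B", "C", "D"),
                    log2_fold_change = c(2, -3, 0.2, 1.6),
                    adjusted_p = c(0.01, 0.2, 0.001, 0.03),
                    expressed = c(TRUE, TRUE, TRUE, FALSE))
  rep <- bbr_expression_report(c("A", "B", "D", "Z"), rec)
  expect_equal(rep$summary$n_bound, 4)
  expect_equal(rep$summary$n_expressed, 2)            # A, B (D not expressed)
  expect_equal(rep$summary$n_large_lfc, 2)            # A, B among expressed
  expect_equal(rep$summary$n_significant, 2)          # A, D
  expect_equal(rep$summary$n_expressed_significant, 1)  # A
  expect_true(rep$table$missing_data[rep$table$gene == "Z"])
  expect_false(any(rep$table$missing_data[rep$table$gene != "Z"]))

  empty <- bbr_expression_report(character(0), rec)
  expect_equal(empty$summary$n_bound, 0)
  expect_equal(nrow(empty$table), 0)

  # all bound genes unexpressed
  rec0 <- transform(rec, expressed = FALSE)
  expect_equal(bbr_expression_report(c("A", "B"), rec0)$summary$n_expressed, 0)
})

test_that("planted expression effects are recovered from synthetic counts", {
  cfg <- sim_config(seed = 29)
  genome <- generate_genome(cfg)
  expr <- generate_expression(cfg, genome)
  norm <- normalize_counts(expr$counts)
  de <- welch_de(norm$normalized, expr$genotype,
                 numerator_genotype = "complemented")
  de <- classify_de(de)
  truth <- expr$truth[match(de$gene, expr$truth$gene), ]
  # estimated log2FC within +/- 0.5 of the planted value for >= 90% of DE genes
  de_idx <- truth$class != "ns"
  err <- abs(de$log2_fold_change[de_idx] - truth$log2_fold_change[de_idx])
  expect_gte(mean(err <= 0.5), 0.9)
  # no sign errors: no truly-ns gene is called, in either direction, with
  # the wrong sign; no planted gene flips direction
  called <- as.character(de$de_class)
  expect_false(any(called == "up" & truth$class == "down"))
  expect_false(any(called == "down" & truth$class == "up"))
})
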