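test_that("promoter windows are strand-aware, clipped, and sized upstream+downstream", {
  genes <- data.frame(gene_id = c("plus", "minus", "edge"),
                      chrom = "chr1",
                      start = c(1000L, 1000L, 100L),
                      end = c(5000L, 5000L, 900L),
                      strand = c("+", "-", "+"),
                      stringsAsFactors = FALSE)
  w <- promoter_window(genes)
  expect_equal(w$start, c(550L, 4950L, 0L))
  expect_equal(w$end, c(1050L, 5450L, 150L))
  expect_equal(w$tss_pos, c(1000L, 5000L, 100L))
  # unclipped windows span upstream + downstream
  expect_equal((w$end - w$start)[1:2], c(500L, 500L))
  expect_error(promoter_window(transform(genes, strand = "*")), "strand")
})

test_that("peak-overlap table matches Fisher oracle values and conserves margins", {
  # 8/2 hits in set A vs 2/8 in set B, constructed explicitly
  mk_windows <- function(prefix, n_hit, n_miss) {
    data.frame(gene_id = paste0(prefix, 1:(n_hit + n_miss)), chrom = "chr1",
               start = c(seq(0, by = 1000, length.out = n_hit),
                         seq(500000, by = 1000, length.out = n_miss)),
               end = c(seq(500, by = 1000, length.out = n_hit),
                       seq(500500, by = 1000, length.out = n_miss)),
               stringsAsFactors = FALSE)
  }
  pa <- mk_windows("a", 8, 2)
  pb <- mk_windows("b", 2, 8)
  peaks <- data.frame(chrom = "chr1", start = seq(0, by = 1000, length.out = 8),
                      end = seq(400, by = 1000, length.out = 8))
  res <- cbr_overlap_test(pa, pb, peaks)
  expect_equal(unname(res$table[, "setA"]), c(8L, 2L))
  expect_equal(unname(res$table[, "setB"]), c(2L, 8L))
  expect_equal(res$odds_ratio, 16.0)
  expect_equal(res$p, 0.0230, tolerance = 5e-3)
  expect_equal(unname(colSums(res$table)), c(nrow(pa), nrow(pb)))

  empty_peaks <- peaks[0, ]
  res0 <- cbr_overlap_test(pa, pb, empty_peaks)
  expect_equal(sum(res0$table["hit", ]), 0)
  expect_equal(res0$p, 1)
  expect_error(cbr_overlap_test(pa[0, ], pb, peaks), "non-empty")
})

test_that("the bidirectional-promoter doubling rule adds exactly one hit", {
  # a divergent pair whose two promoter windows overlap each other and the
  # same peak
  pa <- data.frame(gene_id = c("gA", "gB", "gC"), chrom = "chr1",
                   start = c(100L, 300L, 10000L),
                   end = c(600L, 800L, 10500L),
                   stringsAsFactors = FALSE)
  pb <- data.frame(gene_id = c("x1", "x2"), chrom = "chr1",
                   start = c(0L, 5000L), end = c(400L, 5400L),
                   stringsAsFactors = FALSE)
  peaks <- data.frame(chrom = "chr1", start = 350L, end = 450L)
  div <- data.frame(gene_a = "gA", gene_b = "gB", stringsAsFactors = FALSE)

  unique_mode <- cbr_overlap_test(pa, pb, peaks, divergent_pairs_in_A = div,
                                  doubling = FALSE)
  doubled <- cbr_overlap_test(pa, pb, peaks, divergent_pairs_in_A = div,
                              doubling = TRUE)
  expect_equal(doubled$table["hit", "setA"] - unique_mode$table["hit", "setA"], 1L)
  expect_equal(unique_mode$table["hit", "setA"], 1L)
  expect_equal(doubled$table["hit", "setA"], 2L)
})

test_that("Fisher p-values agree with exhaustive enumeration on small tables", {
  # enumerate all 2x2 tables with the observed margins and sum those at
  # least as extreme under the hypergeometric null
  fisher_enum <- function(tab) {
    rs <- rowSums(tab); cs <- colSums(tab)
    a_range <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
    probs <- vapply(a_range, function(a)
      dhyper(a, rs[1], rs[2], cs[1]), numeric(1))
    p_obs <- dhyper(tab[1, 1], rs[1], rs[2], cs[1])
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  }
  set.seed(14)
  for (rep in 1:6) {
    tab <- matrix(rpois(4, 6) + 1, nrow = 2)
    expect_equal(fisher.test(tab)$p.value, fisher_enum(tab), tolerance = 1e-8)
  }
})

test_that("consensus peaks require support in every replicate", {
  r1 <- data.frame(chrom = "chr1", start = c(0L, 1000L, 2000L),
                   end = c(100L, 1100L, 2100L))
  r2 <- data.frame(chrom = "chr1", start = c(50L, 2050L), end = c(80L, 2090L))
  r3 <- data.frame(chrom = "chr1", start = 2000L, end = 2200L)
  cons <- consensus_peaks(list(r1, r2, r3))
  expect_equal(cons$start, 2000L)  # reported on first replicate coordinates
  expect_equal(cons$end, 2100L)
})

test_that("per-gene CNV assignment averages in-gene plus nearest flanking SNPs", {
  gene <- list(gene_id = "g", chrom = "chr1", start = 1000L, end = 2000L)
  snps <- data.frame(chrom = "chr1",
                     pos = c(500L, 900L, 1200L, 1800L, 2100L, 3000L),
                     value = c(9, 0.0, 0.2, 0.4, 0.6, 9))
  res <- cnv_gene_value(gene, snps)
  expect_equal(res$mean_cnv, 0.3)
  expect_equal(res$n_snps, 4L)

  flanks_only <- cnv_gene_value(gene, data.frame(chrom = "chr1",
                                                 pos = c(100L, 2500L),
                                                 value = c(1, 3)))
  expect_equal(flanks_only$mean_cnv, 2.0)

  no_upstream <- cnv_gene_value(gene, data.frame(chrom = "chr1",
                                                 pos = c(1500L, 2500L),
                                                 value = c(1, 2)))
  expect_equal(no_upstream$n_snps, 2L)
  expect_error(cnv_gene_value(gene, data.frame(chrom = "chr2", pos = 1L, value = 1)),
               "no SNPs")
})

test_that("matched CNV comparison uses the exact signed-rank distribution", {
  a <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10)
  same <- cnv_matched_test(a, a)
  expect_equal(same$p, 1)

  shift <- cnv_matched_test(a + 1, a)  # constant shift, tied magnitudes
  expect_lt(shift$p, 0.01)

  # distinct magnitudes, all signs positive: exact two-sided p = 2 / 2^10
  exact <- cnv_matched_test(a + (1:10) / 10, a)
  expect_equal(exact$p, 2 / 1024, tolerance = 1e-10)

  expect_error(cnv_matched_test(1:3, 4:6), "at least 6")
  expect_error(cnv_matched_test(1:6, 1:5), "equal length")
})
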