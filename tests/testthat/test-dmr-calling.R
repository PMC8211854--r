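test_that("window_test matches the exact binomial oracle at phi = 0", {
  ## brute-force oracle over all splits for totals <= 50, equal libs
  for (tot in c(1, 7, 20, 35, 50)) {
    for (sA in unique(round(seq(0, tot, length.out = 6)))) {
      counts <- matrix(0L, 1, 4)
      counts[1, 1] <- sA; counts[1, 3] <- tot - sA
      se <- mk_se(counts, groups = c("A", "A", "B", "B"),
                  lib_sizes = rep(1e6, 4))
      p <- window_test(se, dmr_params(dispersion_mode = "fixed",
                                      dispersion = 0))
      expect_equal(as.numeric(p), oracle_binom_two_sided(sA, tot, 0.5),
                   tolerance = 1e-12,
                   info = sprintf("total %d split %d", tot, sA))
    }
  }
  ## the spec'd instance: sums 30 vs 5 equals binom.test(30, 35, 0.5)
  counts <- matrix(c(15L, 15L, 3L, 2L), 1, 4)
  se <- mk_se(counts, c("A", "A", "B", "B"), rep(1e6, 4))
  p <- window_test(se, dmr_params(dispersion_mode = "fixed",
                                  dispersion = 0))
  expect_equal(as.numeric(p),
               binom.test(30, 35, 0.5)$p.value, tolerance = 1e-12)
})

test_that("window_test: identical groups give p = 1; input validation", {
  counts <- matrix(rep(c(7L, 7L), each = 2), 1, 4)
  se <- mk_se(counts, c("A", "A", "B", "B"), rep(1e6, 4))
  p <- window_test(se, dmr_params(dispersion_mode = "fixed",
                                  dispersion = 0.1))
  expect_equal(as.numeric(p), 1)
  expect_error(window_test(mk_se(counts, c("A", "A", "B", "B"),
                                 c(0, 0, 1e6, 1e6)),
                           dmr_params()),
               "zero total library size")
  expect_error(window_test(mk_se(counts[, 1:3, drop = FALSE],
                                 c("A", "B", "B"), rep(1e6, 3)),
                           dmr_params()),
               "2 replicates")
})

test_that("null simulation is calibrated within 3 binomial SDs", {
  g <- small_genome(c(chr1 = 2.5e6))  # 5000 windows
  sim <- simulate_window_counts(
    g, simulation_params(planted_fraction = 0, dispersion = 0.1,
                         seed = 31))
  se <- to_rpkm(sim$se)
  p <- window_test(se, dmr_params())
  rate <- mean(p < 0.01)
  band <- 3 * sqrt(0.01 * 0.99 / length(p))
  expect_lt(abs(rate - 0.01), band)
  ## moment dispersion recovers the generating value
  expect_lt(abs(attr(p, "dispersion") - 0.1), 0.02)
})

test_that("call_windows applies the fold and p gates with direction", {
  rpkm <- rbind(c(10, 10, 14, 14),   # ratio 1.4: fold gate blocks
                c(10, 10, 20, 20),   # ratio ~2: hyper
                c(10, 10, 5, 5),     # ratio ~0.5: hypo
                c(10, 10, 20, 20))   # p gate blocks
  se <- mk_se(matrix(0L, 4, 4), c("A", "A", "B", "B"), rep(1e6, 4))
  assay(se, "rpkm", withDimnames = FALSE) <- rpkm
  p <- c(1e-6, 0.005, 0.005, 0.5)
  fl <- call_windows(se, p, dmr_params())
  expect_equal(length(fl), 2L)
  expect_equal(mcols(fl)$direction, c("hyper", "hypo"))
  ## flagged windows are rows 2 and 3
  expect_equal(start(fl), start(rowRanges(se))[2:3])
})

test_that("merge_adjacent merges same-direction runs and is idempotent", {
  ws <- 500L
  win <- function(i) GRanges("chr1", IRanges((i - 1L) * ws + 1L,
                                             width = ws))
  fl <- c(win(3), win(4), win(5), win(7), win(8), win(10))
  mcols(fl) <- S4Vectors::DataFrame(
    direction = c("hyper", "hyper", "hyper", "hyper", "hypo", "hypo"),
    fold = c(2, 3, 4, 2, 0.4, 0.5),
    p = c(1e-3, 1e-5, 1e-4, 1e-3, 1e-3, 1e-6))
  dm <- merge_adjacent(fl)
  expect_equal(length(dm), 4L)
  ## windows 3-5 merge into one 1500 bp hyper DMR
  d1 <- dm[start(dm) == 1001]
  expect_equal(width(d1), 1500)
  expect_equal(mcols(d1)$n_windows, 3L)
  expect_equal(mcols(d1)$p, 1e-5)
  expect_equal(mcols(d1)$fold, mean(c(2, 3, 4)))  # equal widths
  ## hyper window 7 adjacent to hypo window 8: direction split
  expect_equal(mcols(dm)$direction[start(dm) %in% c(3001, 3501)],
               c("hyper", "hypo"))
  ## isolated flagged window is retained as a 500 bp DMR
  expect_true(any(width(dm) == 500 & start(dm) == 4501))
  ## idempotence
  dm2 <- merge_adjacent(dm)
  expect_equal(granges(dm), granges(dm2))
  expect_equal(mcols(dm)$n_windows, mcols(dm2)$n_windows)
  ## strict length mode drops the singleton
  expect_false(any(width(filter_dmr_length(
    dm, dmr_params(strict_length = TRUE))) == 500))
  ## empty input
  expect_length(merge_adjacent(fl[0]), 0L)
})

test_that("mask_dmrs removes >=1 bp overlaps and keeps book-ended DMRs", {
  mask <- GRanges("chr1", IRanges(5001, 10000))
  dmrs <- GRanges("chr1", IRanges(c(6001, 10001, 4801), width = 500))
  mcols(dmrs)$direction <- "hyper"
  out <- mask_dmrs(dmrs, mask)
  expect_equal(attr(out, "removed"), 2L)  # inside + 1bp-overlap
  expect_equal(start(out), 10001)         # book-ended: kept
})

test_that("combine_lists concatenates order-stably without dedup", {
  mk <- function(n, chrom = "chr1") {
    gr <- GRanges(chrom, IRanges(seq(1, by = 1000, length.out = n),
                                 width = 500))
    mcols(gr)$direction <- "hyper"
    gr
  }
  a <- mk(3); b <- mk(2, "chr2"); c0 <- mk(4)
  out <- combine_lists(a, b, c0)
  expect_length(out, 9L)
  expect_equal(as.character(seqnames(out))[4:5], c("chr2", "chr2"))
  expect_length(combine_lists(list(a[0], b[0])), 0L)
  ## a duplicated interval is kept twice
  expect_length(combine_lists(a, a), 6L)
})

test_that("intersect_sets partitions by >=1 bp overlap", {
  a <- GRanges("chr1", IRanges(c(1, 5001), width = 500))
  b <- GRanges("chr1", IRanges(c(401, 9001), width = 500))
  r <- intersect_sets(list(A = a, B = b))
  ## [1,500] and [401,900] share >=1 bp -> one A&B locus
  expect_equal(as.integer(r$counts[["A&B"]]), 1L)
  expect_equal(as.integer(r$counts[["A"]]), 1L)
  expect_equal(as.integer(r$counts[["B"]]), 1L)
  ## identical lists: everything common
  r2 <- intersect_sets(list(x = a, y = a))
  expect_equal(names(r2$counts), "x&y")
  ## disjoint lists: all unique
  r3 <- intersect_sets(list(x = a, y = shift(a, 20000)))
  expect_false("x&y" %in% names(r3$counts))
})

test_that("planted DMRs are recovered (sensitivity and windows hit)", {
  g <- small_genome(c(chr1 = 2e6))
  sim <- simulate_window_counts(
    g, simulation_params(mean_rpkm = 10, dispersion = 0.1,
                         planted_fraction = 0.02, fold_changes = 3,
                         seed = 33))
  se <- to_rpkm(sim$se)
  p <- window_test(se, dmr_params(), background = background_methylome(se))
  dm <- merge_adjacent(call_windows(se, p, dmr_params()))
  tw <- rowRanges(se)[sim$truth$window]
  expect_gte(mean(overlapsAny(tw, dm)), 0.9)
})

test_that("masking and merging commute for mask-disjoint DMRs", {
  ws <- 500L
  fl <- GRanges("chr1", IRanges(c(1, 501, 20001, 20501), width = ws))
  mcols(fl) <- S4Vectors::DataFrame(direction = "hyper", fold = 2,
                                    p = 1e-3)
  mask <- GRanges("chr1", IRanges(100001, 120000))
  a <- mask_dmrs(merge_adjacent(fl), mask)
  b <- merge_adjacent(mask_dmrs(fl, mask))
  expect_equal(granges(a), granges(b))
})
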