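test_that("extend_fragments follows the 5'-extension definition", {
  g <- small_genome(c(chr1 = 10000))
  ## BED coords [100, 400) are 1-based [101, 400]
  plus <- GRanges("chr1", IRanges(101, 150), strand = "+")
  fs <- extend_fragments(plus, g, quant_params(extend = 300))
  expect_equal(start(fs$fragments), 101)
  expect_equal(end(fs$fragments), 400)
  ## minus-strand read with 5' end at 1-based 400 mirrors to [101,400]
  minus <- GRanges("chr1", IRanges(351, 400), strand = "-")
  fs <- extend_fragments(minus, g, quant_params(extend = 300))
  expect_equal(start(fs$fragments), 101)
  expect_equal(end(fs$fragments), 400)
  ## clipping at the chromosome end yields a short fragment
  near_end <- GRanges("chr1", IRanges(9901, 9950), strand = "+")
  fs <- extend_fragments(near_end, g, quant_params(extend = 300))
  expect_equal(width(fs$fragments), 100)
  expect_error(
    extend_fragments(GRanges("chrX", IRanges(1, 50), strand = "+"), g),
    "unknown chromosome")
  expect_error(
    extend_fragments(GRanges("chr1", IRanges(1, 50), strand = "*"), g),
    "strand")
})

test_that("uniq filter: Poisson cap, disabled threshold, idempotence", {
  ## lambda = 0.01: 20,000 fragments on a 1 Mb genome (2e6 start
  ## positions over both strands).  P(X>=1) = 9.95e-3 >= 1e-3,
  ## P(X>=2) = 4.97e-5 < 1e-3, so s_max = 2: a stack of 10 keeps 2.
  g <- make_genome(c(chr1 = 1e6))
  starts <- c(rep(5001L, 10L), seq(10001L, by = 45L,
                                   length.out = 19990L))
  reads <- GRanges("chr1", IRanges(starts, width = 50), strand = "+")
  fs <- structure(list(fragments = reads, library_size = length(reads)),
                  class = "fragment_set")
  out <- apply_uniq_filter(fs, 1e-3, g)
  expect_equal(attr(out, "s_max"), 2L)
  expect_equal(attr(out, "removed"), 8L)
  expect_equal(out$library_size, 19992L)
  ## uniq_p = 1 disables removal
  out1 <- apply_uniq_filter(fs, 1, g)
  expect_equal(out1$library_size, fs$library_size)
  ## no duplicated starts: identity
  fs_nodup <- structure(list(fragments = reads[-(1:9)],
                             library_size = length(reads) - 9L),
                        class = "fragment_set")
  expect_equal(apply_uniq_filter(fs_nodup, 1e-3, g)$library_size,
               fs_nodup$library_size)
  ## idempotence on a deeply duplicated library
  g2 <- make_genome(c(chr1 = 2e5))
  reads2 <- simulate_fragments(g2, 60000, seed = 3)
  fs2 <- extend_fragments(reads2, g2, quant_params())
  once <- apply_uniq_filter(fs2, 1e-3)
  twice <- apply_uniq_filter(once, 1e-3)
  expect_gt(attr(once, "removed"), 0L)
  expect_identical(granges(once$fragments), granges(twice$fragments))
})

test_that("window counting: overlap semantics and midpoint conservation", {
  g <- small_genome(c(chr1 = 5000))
  mk_fs <- function(gr) structure(list(fragments = gr,
                                       library_size = length(gr)),
                                  class = "fragment_set")
  ## BED [100,400) -> 1-based [101,400]: inside window 1 only
  ## BED [400,700) -> 1-based [401,700]: spans windows 1 and 2
  fr <- GRanges("chr1", IRanges(c(101, 401), c(400, 700)), strand = "+")
  se <- window_counts(list(a = mk_fs(fr)), g, quant_params())
  cnt <- assay(se, "counts")[, 1]
  expect_equal(cnt[1:3], c(2, 1, 0), ignore_attr = TRUE)
  ## empty replicate: all-zero column flagged
  expect_message(
    se2 <- window_counts(list(a = mk_fs(fr), b = mk_fs(GRanges())), g,
                         quant_params()),
    "library size 0")
  expect_true(all(assay(se2, "counts")[, 2] == 0))
  ## midpoint oracle mode conserves the library size exactly
  reads <- simulate_fragments(g, 500, seed = 5)
  fs <- extend_fragments(reads, g, quant_params())
  se_mid <- window_counts(list(a = fs), g, quant_params(),
                          mode = "midpoint")
  expect_equal(sum(assay(se_mid, "counts")), fs$library_size)
  ## overlap mode counts at least one window per fragment
  se_ov <- window_counts(list(a = fs), g, quant_params())
  expect_gte(sum(assay(se_ov, "counts")), fs$library_size)
  ## genome mismatch rejected
  bad <- mk_fs(GRanges("chrZ", IRanges(1, 100), strand = "+"))
  expect_error(window_counts(list(bad), g, quant_params()),
               "different genome")
})

test_that("RPKM closed form, homogeneity and error cases", {
  counts <- matrix(c(10, 0, 5, 20), nrow = 2)
  se <- mk_se(counts, groups = c("A", "B"), lib_sizes = c(1e6, 2e6))
  se <- to_rpkm(se)
  rpkm <- assay(se, "rpkm")
  ## count 10, ws 500, lib 1e6 -> 10 / (0.5 * 1) = 20
  expect_equal(unname(rpkm[1, 1]), 20)
  expect_equal(unname(rpkm[2, 1]), 0)
  ## doubling the library halves RPKM: column 2 has lib 2e6
  expect_equal(unname(rpkm[1, 2]), 5 / 0.5 / 2)
  ## closed form everywhere to machine precision
  expected <- sweep(counts / (width(rowRanges(se)) / 1000), 2L,
                    c(1, 2), `/`)
  expect_equal(rpkm, expected, tolerance = 1e-12, ignore_attr = TRUE)
  se0 <- mk_se(counts, c("A", "B"), c(0, 1e6))
  expect_error(to_rpkm(se0), "library size")
})

test_that("background methylome uses a strict > 1.0 on summed group means", {
  ## windows engineered to group means (0.4, 0.7), (0.5, 0.5), (0, 0)
  rpkm <- rbind(c(0.4, 0.4, 0.7, 0.7),
                c(0.5, 0.5, 0.5, 0.5),
                c(0, 0, 0, 0))
  se <- mk_se(matrix(0L, 3, 4), groups = c("A", "A", "B", "B"),
              lib_sizes = rep(1e6, 4))
  assay(se, "rpkm", withDimnames = FALSE) <- rpkm
  expect_equal(background_methylome(se), c(TRUE, FALSE, FALSE))
})

test_that("qc_pca separates planted groups and breaks ties by order", {
  g <- small_genome(c(chr1 = 1e6))
  sim <- simulate_window_counts(
    g, simulation_params(planted_fraction = 0.2, fold_changes = 8,
                         dispersion = 0.05, seed = 21), ws = 5000L)
  se <- to_rpkm(sim$se)
  co <- qc_pca(se, top_n = 100)
  grp <- colData(se)$group
  ## strong planted signal: first axis separates the groups
  expect_true(max(co$PC1[grp == "A"]) < min(co$PC1[grp == "B"]) ||
              min(co$PC1[grp == "A"]) > max(co$PC1[grp == "B"]))
  ## identical samples get identical coordinates
  cnt <- matrix(rep(c(5L, 9L, 1L, 14L), 4), ncol = 4)
  se2 <- mk_se(cnt, groups = c("A", "A", "B", "B"),
               lib_sizes = rep(1e6, 4))
  co2 <- qc_pca(se2, top_n = 4)
  expect_equal(co2$PC1[1], co2$PC1[2])
  ## fewer windows than requested: warn and use all
  expect_warning(qc_pca(se2, top_n = 50), "using all")
  expect_error(qc_pca(se2[, 1:2], 4), "at least 3 samples")
})
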