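test_that("classification is total, exclusive and follows precedence", {
  g <- small_genome(c(chr1 = 100000))
  genes <- GRanges("chr1", IRanges(10001, 30000), strand = "+",
                   gene_id = "g1")
  exons <- GRanges("chr1", IRanges(c(10001, 20001), c(12000, 22000)),
                   strand = "+", gene_id = "g1")
  tss <- resize(genes, 1, fix = "start")
  ann <- list(genes = genes, exons = exons, tss = tss)
  q <- GRanges("chr1", IRanges(
    c(11001,   # inside an exon
      15001,   # inside an intron
      11901,   # spans exon/intron boundary: exon by precedence
      9401,    # promoter (1 kb upstream of TSS at 10001)
      50001),  # intergenic
    width = 300))
  d <- classify_intervals(q, ann, "genic")
  expect_equal(as.character(d$assignment),
               c("exon", "intron", "exon", "promoter", "intergenic"))
  ## totality and exclusivity
  expect_equal(sum(d$counts), length(q))
  expect_equal(sum(d$fractions), 1, tolerance = 1e-9)
  expect_error(classify_intervals(q, ann, "nonsense"))
})

test_that("cgi scheme: island > shore (2 kb) > shelf (2-4 kb) > open sea", {
  ann <- list(cgis = GRanges("chr1", IRanges(50001, 52000)))
  q <- GRanges("chr1", IRanges(
    c(50501,  # inside island
      52501,  # 501 bp from edge: shore
      55001,  # 3001 bp from edge: shelf
      60001), # 8 kb away: open sea
    width = 200))
  d <- classify_intervals(q, ann, "cgi")
  expect_equal(as.character(d$assignment),
               c("island", "shore", "shelf", "open_sea"))
  ## interval 1 kb from the edge is shore (2 kb rule)
  q2 <- GRanges("chr1", IRanges(53000, 53100))
  expect_equal(as.character(classify_intervals(q2, ann,
                                               "cgi")$assignment),
               "shore")
  ## shore and shelf bands never overlap the island
  shores <- setdiff(ann$cgis + 2000, ann$cgis)
  expect_equal(sum(width(intersect(shores, ann$cgis))), 0)
})

test_that("repeat scheme precedence LTR > LINE > SINE > other > unique", {
  reps <- GRanges("chr1", IRanges(c(1000, 1100, 5000, 9000),
                                  width = 300),
                  class = c("LTR", "LINE", "SINE", "simple"))
  ann <- list(repeats = reps)
  q <- GRanges("chr1", IRanges(c(1150, 5100, 9100, 20000), width = 100))
  d <- classify_intervals(q, ann, "repeat")
  ## first query overlaps both LTR and LINE: LTR wins
  expect_equal(as.character(d$assignment),
               c("LTR", "SINE", "other_repeat", "unique"))
})

test_that("chi-squared vs background matches the textbook computation", {
  bg <- mk_dist(c(50, 50))
  ob <- mk_dist(c(30, 70))
  r <- chisq_vs_background(ob, bg)
  expect_equal(r$statistic, 16)  # (30-50)^2/50 + (70-50)^2/50
  expect_equal(r$p.value, pchisq(16, 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(r$p.value, 6.334248e-05, tolerance = 1e-6)
  ## equal distributions: chi2 = 0, p = 1
  r0 <- chisq_vs_background(mk_dist(c(25, 75)), mk_dist(c(250, 750)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p.value, 1)
  ## random toys vs stats::chisq.test oracle
  set.seed(42)
  for (i in 1:5) {
    k <- sample(3:6, 1)
    obs <- as.numeric(rmultinom(1, 200, rep(1 / k, k)))
    bgf <- as.numeric(rmultinom(1, 1000, runif(k) + 0.5))
    r1 <- chisq_vs_background(mk_dist(obs, letters[1:k]),
                              mk_dist(bgf, letters[1:k]))
    r2 <- suppressWarnings(chisq.test(obs, p = bgf / sum(bgf)))
    expect_equal(r1$statistic, unname(r2$statistic), tolerance = 1e-9)
    expect_equal(r1$p.value, r2$p.value, tolerance = 1e-9)
  }
  ## degenerate single category
  expect_error(chisq_vs_background(mk_dist(10), mk_dist(5)), "single")
  ## low expected counts warn
  expect_warning(chisq_vs_background(mk_dist(c(1, 1)),
                                     mk_dist(c(1, 999))),
                 "below 1")
})

test_that("tss_distance applies the closest-boundary formula", {
  ## 0-based interval [1999,2500) with TSS at 0-based 1500 -> +500
  tss <- GRanges("chr1", IRanges(1501, 1501), strand = "+")
  iv <- GRanges("chr1", IRanges(2000, 2500))
  expect_equal(tss_distance(iv, tss)$distance, 500)
  ## interval ending at 0-based 1499 (1-based 1500): distance 0
  iv2 <- GRanges("chr1", IRanges(1001, 1500))
  expect_equal(tss_distance(iv2, tss)$distance, 0)
  ## interval containing the TSS: flagged, rule still applied
  iv3 <- GRanges("chr1", IRanges(1401, 1700))
  r3 <- tss_distance(iv3, tss)
  expect_true(r3$overlapping)
  ## closest boundary is 1401 (|1401-1501| = 100 < |1700-1501| = 199)
  expect_equal(r3$distance, 1401 - 1501 + 1)
  ## minus-strand TSS mirrors the sign
  tssm <- GRanges("chr1", IRanges(1501, 1501), strand = "-")
  expect_equal(tss_distance(iv, tssm)$distance, 1501 - 2000 + 1)
  ## no TSS on the chromosome: NA
  iv4 <- GRanges("chr2", IRanges(100, 200))
  expect_true(is.na(tss_distance(iv4, tss)$distance))
})

test_that("enhancer_overlap reports planted overlaps exactly", {
  g <- small_genome()
  withr::with_seed(5, {
    enh <- GRanges("chr1", IRanges(seq(10001, by = 50000,
                                       length.out = 12),
                                   width = 400),
                   enhancer_id = paste0("enh", 1:12))
    ## 8 DMRs placed on enhancers, 5 elsewhere
    dmrs <- c(GRanges("chr1", IRanges(start(enh)[1:8] + 100,
                                      width = 500)),
              GRanges("chr1", IRanges(seq(700001, by = 30000,
                                          length.out = 5),
                                      width = 500)))
  })
  eo <- enhancer_overlap(dmrs, enh)
  expect_equal(attr(eo, "n_overlapping"), 8L)
  expect_equal(eo$enhancer_ids[1], "enh1")
  ## no enhancers: zero overlaps
  expect_equal(attr(enhancer_overlap(dmrs, enh[0]), "n_overlapping"), 0L)
  ## DMR equal to an enhancer: one overlap
  expect_equal(enhancer_overlap(enh[1], enh)$n_enhancers[1], 1L)
})
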