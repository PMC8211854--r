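test_that("genotype calls partition [0,1] at the stated boundaries", {
  ## 95/100 hom; 90/100 het (> 90% required for hom); 20/100 none
  expect_equal(call_genotype(5, 95), "hom")
  expect_equal(call_genotype(10, 90), "het")
  expect_equal(call_genotype(70, 30), "het")
  expect_equal(call_genotype(80, 20), "none")
  ## fine-grained boundary sweep: 0.29 none, 0.30 het, 0.90 het,
  ## 0.91 hom
  expect_equal(call_genotype(c(71, 70, 10, 9), c(29, 30, 90, 91)),
               c("none", "het", "het", "hom"))
  ## zero depth is uncallable
  expect_true(is.na(call_genotype(0, 0)))
  ## every fraction lands in exactly one state
  f <- seq(0, 1, by = 0.01)
  calls <- call_genotype(round(100 * (1 - f)), round(100 * f))
  expect_true(all(calls %in% c("hom", "het", "none")))
  expect_equal(sum(calls == "hom"), sum(f > 0.90))
  expect_equal(sum(calls == "het"), sum(f >= 0.30 & f <= 0.90))
  expect_error(genotype_params(hom_fraction = 0.2, het_fraction = 0.3))
})

test_that("filter cascade on the hand-built fixture matches manual rules", {
  vt <- suppressWarnings(read_variant_vcf(fixture_vcf_path()))
  expect_length(vt$sites, 20L)
  res <- filter_variants(vt)
  expect_equal(unname(res$status), unname(fixture_expected_status))
  ## boundary cases called out: MQ=40 kept, homopolymer=8 kept,
  ## dinucleotide=14 kept, SRP=9 kept, exactly 3 hets/10 kb kept
  keep <- names(fixture_expected_status)[
    fixture_expected_status == "pass"]
  expect_true(all(c("v02", "v04", "v06", "v09", "v13", "v14", "v15")
                  %in% keep))
  expect_length(res$passed$sites, sum(fixture_expected_status == "pass"))
  ## order independence: permuting variants permutes the verdicts
  perm <- withr::with_seed(1, sample.int(20))
  vt_p <- variant_table(vt$sites[perm],
                        vt$ref_reads[perm, ], vt$alt_reads[perm, ],
                        vt$mq[perm], vt$context[perm, ])
  res_p <- filter_variants(vt_p)
  expect_equal(unname(res_p$status),
               unname(fixture_expected_status[perm]))
})

test_that("het-cluster rule: 4 hets in < 10 kb removed, 3 kept", {
  mk_vt <- function(pos, het_sample1 = TRUE) {
    n <- length(pos)
    sites <- GRanges("chr1", IRanges(pos, width = 1))
    alt <- matrix(c(rep(15L, n), rep(0L, n)), ncol = 2)
    ref <- matrix(c(rep(15L, n), rep(30L, n)), ncol = 2)
    ctx <- data.frame(simple_repeat_period = NA_real_,
                      homopolymer_len = 2, dinucleotide_len = 0,
                      in_annotated_repeat = FALSE)[rep(1, n), ]
    variant_table(sites, ref, alt, rep(60, n), ctx)
  }
  ## 4 hets spanning 9 kb: all removed under (vi)
  res4 <- filter_variants(mk_vt(c(1000, 4000, 7000, 10000)))
  expect_equal(unname(res4$status), rep("vi", 4))
  ## 3 hets in 10 kb: kept
  res3 <- filter_variants(mk_vt(c(1000, 5000, 10999)))
  expect_equal(unname(res3$status), rep("pass", 3))
  ## 5 hets where only a sliding 4-window qualifies: all 4 in-window
  ## removed, the distant 5th kept
  res5 <- filter_variants(mk_vt(c(1000, 3000, 5000, 7000, 50000)))
  expect_equal(unname(res5$status), c(rep("vi", 4), "pass"))
  ## missing context feature rejected with the field named
  vt_bad <- mk_vt(c(1000, 20000))
  vt_bad$context$homopolymer_len[1] <- NA
  expect_error(filter_variants(vt_bad), "homopolymer_len")
})

test_that("shared_variants uses all-cases / no-controls semantics", {
  g <- small_genome()
  sv <- simulate_variants(g, seed = 13, n_sites = 120, n_shared = 25)
  sh <- shared_variants(sv$vt, sv$cases, sv$controls)
  expect_equal(sum(sh), 25L)
  expect_equal(which(sh), which(sv$truth$planted == "shared"))
  ## variant in 5/6 cases excluded; in all cases + 1 control excluded
  calls <- call_genotypes(sv$vt)
  idx <- which(sh)[1]
  vt2 <- sv$vt
  vt2$alt_reads[idx, sv$cases[1]] <- 0L  # now absent in one case
  expect_false(shared_variants(vt2, sv$cases, sv$controls)[idx])
  vt3 <- sv$vt
  vt3$alt_reads[idx, sv$controls[1]] <-
    vt3$ref_reads[idx, sv$controls[1]]  # control becomes het
  expect_false(shared_variants(vt3, sv$cases, sv$controls)[idx])
  ## monotonicity: dropping a case can only grow the shared set
  sh_sub <- shared_variants(sv$vt, sv$cases[-6], sv$controls)
  expect_true(all(sh_sub[sh]))
})

test_that("variant_region_proximity flags SNP content and SV distance", {
  dmrs <- GRanges("chr1", IRanges(c(10000, 50000, 90000), width = 1000))
  snps <- GRanges("chr1", IRanges(10500, width = 1))
  ## GRanges distance is the gap: SV 999 bp away flagged, 1000 not
  svs <- GRanges("chr1", IRanges(c(11000 + 1000,   # gap 1000 from dmr1
                                   51000 + 999),   # gap 999 from dmr2
                                 width = 200))
  out <- variant_region_proximity(dmrs, snps, svs, window_bp = 1000)
  expect_equal(mcols(out)$contains_snp, c(TRUE, FALSE, FALSE))
  expect_equal(mcols(out)$sv_distance[1:2], c(1000, 999))
  expect_equal(mcols(out)$sv_near, c(FALSE, TRUE, FALSE))
  ## overlapping SV: distance 0, flagged
  out2 <- variant_region_proximity(dmrs[1], snps,
                                   GRanges("chr1", IRanges(10100, 10200)))
  expect_equal(mcols(out2)$sv_distance, 0)
  expect_true(mcols(out2)$sv_near)
  ## no variants at all: flags false, distance NA
  out0 <- variant_region_proximity(dmrs, snps[0], svs[0])
  expect_false(any(mcols(out0)$contains_snp))
  expect_false(any(mcols(out0)$sv_near))
  expect_true(all(is.na(mcols(out0)$sv_distance)))
})

test_that("sequence-derived context features on toy sequences", {
  refseq <- Biostrings::DNAStringSet(c(
    chrA = paste0(strrep("T", 30), strrep("A", 9), strrep("G", 30)),
    chrB = paste0(strrep("T", 30), strrep("AC", 10), strrep("G", 30)),
    chrC = paste0(strrep("T", 30), strrep("GAT", 5), strrep("C", 30))))
  ## homopolymer of 9 covering the site
  ctx <- sequence_context(refseq, "chrA", 35)
  expect_equal(ctx$homopolymer_len, 9L)
  expect_equal(ctx$dinucleotide_len, 0L)
  ## AC dinucleotide repeat of 20 bp
  ctx2 <- sequence_context(refseq, "chrB", 40)
  expect_equal(ctx2$dinucleotide_len, 20L)
  expect_equal(ctx2$simple_repeat_period, 2L)
  ## GAT trinucleotide: smallest qualifying periodicity 3
  ctx3 <- sequence_context(refseq, "chrC", 38)
  expect_equal(ctx3$simple_repeat_period, 3L)
  ## unique sequence: no repeat context
  refu <- Biostrings::DNAStringSet(c(chrU = "TTTTTACGTGCATGCCGTAAAAA"))
  ctxu <- sequence_context(refu, "chrU", 12)
  expect_true(is.na(ctxu$simple_repeat_period))
  expect_equal(ctxu$homopolymer_len, 1L)
})

test_that("VCF round trip preserves sites, depths and context", {
  g <- small_genome()
  sv <- simulate_variants(g, seed = 19, n_sites = 40, n_shared = 5)
  path <- tempfile(fileext = ".vcf")
  write_variant_vcf(sv$vt, path, g)
  vt2 <- suppressWarnings(read_variant_vcf(path))
  expect_equal(start(vt2$sites), start(sv$vt$sites))
  expect_equal(unname(vt2$alt_reads), unname(sv$vt$alt_reads),
               ignore_attr = TRUE)
  expect_equal(unname(vt2$ref_reads), unname(sv$vt$ref_reads),
               ignore_attr = TRUE)
  expect_equal(vt2$mq, sv$vt$mq)
  expect_equal(vt2$context$simple_repeat_period,
               as.numeric(sv$vt$context$simple_repeat_period))
  expect_equal(vt2$context$in_annotated_repeat,
               sv$vt$context$in_annotated_repeat)
  ## filter verdicts written as FILTER column survive a re-read
  res <- filter_variants(sv$vt)
  path2 <- tempfile(fileext = ".vcf")
  write_filtered_vcf(sv$vt, res$status, path2, g)
  lines <- readLines(path2)
  recs <- lines[!startsWith(lines, "#")]
  filt <- vapply(strsplit(recs, "\t"), `[`, character(1), 7L)
  expect_equal(sum(filt == "PASS"), sum(res$status == "pass"))
})
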