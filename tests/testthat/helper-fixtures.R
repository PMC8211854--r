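suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(SummarizedExperiment)
})

## small default genome used across tests
small_genome <- function(sizes = c(chr1 = 2e6, chr2 = 1e6), seed = 1L)
  make_genome(sizes, seed = seed)

## bare context_distribution for oracle-style chi-squared tests
mk_dist <- function(counts, categories = letters[seq_along(counts)]) {
  structure(list(assignment = NULL, counts = counts,
                 categories = categories,
                 fractions = counts / sum(counts),
                 n = sum(counts), scheme = "toy"),
            class = "context_distribution")
}

## build a window-count SummarizedExperiment directly from matrices
mk_se <- function(counts, groups, lib_sizes, ws = 500L,
                  chrom = "chr1") {
  nw <- nrow(counts)
  gr <- GRanges(chrom, IRanges(start = (seq_len(nw) - 1L) * ws + 1L,
                               width = ws))
  colnames(counts) <- paste0("s", seq_len(ncol(counts)))
  SummarizedExperiment(
    assays = list(counts = counts), rowRanges = gr,
    colData = S4Vectors::DataFrame(group = groups, lib_size = lib_sizes,
                                   row.names = colnames(counts)))
}

## independent oracle: two-sided exact binomial p by full enumeration,
## written against first principles (log-space binomial pmf)
oracle_binom_two_sided <- function(k, n, p0) {
  j <- 0:n
  logp <- lchoose(n, j) + j * log(p0) + (n - j) * log1p(-p0)
  pk <- logp[k + 1L]
  sum(exp(logp[logp <= pk + log(1 + 1e-7)]))
}

## expected status for the hand-built 20-variant fixture, from manual
## application of rules (i)-(vi)
fixture_expected_status <- c(
  v01 = "pass", v02 = "pass", v03 = "iv", v04 = "pass", v05 = "ii",
  v06 = "pass", v07 = "iii", v08 = "i", v09 = "pass", v10 = "pass",
  v11 = "v", v12 = "ii,iv", v13 = "pass", v14 = "pass", v15 = "pass",
  v16 = "vi", v17 = "vi", v18 = "vi", v19 = "vi", v20 = "pass")

fixture_vcf_path <- function()
  system.file("extdata", "synthetic_filter_fixture.vcf",
              package = "medipr")
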