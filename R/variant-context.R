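## Repeat-context features computed from reference sequence.
##
## When a reference sequence is available the filter-cascade context
## features (homopolymer length, dinucleotide repeat length, simple
## repeat periodicity) are measured in a +/- `flank` bp window around
## the site; otherwise they are read from annotation columns.

## longest single-base run covering position `pos` (1-based) of `seq`
.homopolymer_at <- function(seq, pos) {
  b <- substring(seq, pos, pos)
  l <- pos
  while (l > 1L && substring(seq, l - 1L, l - 1L) == b) l <- l - 1L
  r <- pos
  while (r < nchar(seq) && substring(seq, r + 1L, r + 1L) == b) r <- r + 1L
  r - l + 1L
}

## longest tandem repeat of period `p` covering `pos`: maximal run of
## positions i with seq[i] == seq[i + p]; repeat length is run + p
.period_repeat_at <- function(seq, pos, p) {
  n <- nchar(seq)
  s <- strsplit(seq, "")[[1]]
  match_at <- function(i) i >= 1L && i + p <= n && s[i] == s[i + p]
  ## find the maximal interval of matching offsets containing a point
  ## near pos (the site may sit anywhere inside the repeat)
  best <- 0L
  for (anchor in max(1L, pos - p):pos) {
    if (!match_at(anchor)) next
    l <- anchor
    while (match_at(l - 1L)) l <- l - 1L
    r <- anchor
    while (match_at(r + 1L)) r <- r + 1L
    ## repeat occupies [l, r + p]; require it to cover pos
    if (l <= pos && pos <= r + p) best <- max(best, r - l + 1L + p)
  }
  best
}

#' Repeat-context features at a site from reference sequence
#'
#' Measures, inside a window of `flank` bp either side of the site:
#' the longest homopolymer run covering the site, the longest
#' dinucleotide tandem repeat covering it, and the smallest period
#' `p` (2..`max_period`) of a tandem repeat covering the site with at
#' least two full copies (`NA` when none).
#'
#' @param refseq a [Biostrings::DNAStringSet] named by chromosome
#' @param chrom,pos site coordinates (1-based)
#' @param flank half-window in bp (default 50)
#' @param max_period largest periodicity probed (default 15)
#' @return one-row data.frame with `simple_repeat_period`,
#'   `homopolymer_len`, `dinucleotide_len`
#' @export
sequence_context <- function(refseq, chrom, pos, flank = 50L,
                             max_period = 15L) {
  full <- as.character(refseq[[chrom]])
  lo <- max(1L, pos - flank)
  hi <- min(nchar(full), pos + flank)
  win <- substring(full, lo, hi)
  at <- pos - lo + 1L
  hp <- .homopolymer_at(win, at)
  di <- .period_repeat_at(win, at, 2L)
  ## dinucleotide repeat length only counts genuine 2-periodicity
  ## (exclude pure homopolymers, which have period 1)
  if (di > 0 && hp >= di) di <- 0L
  period <- NA_integer_
  for (p in 2:max_period) {
    len <- .period_repeat_at(win, at, p)
    if (len >= 2L * p) {
      ## skip periods that are just homopolymer runs in disguise
      if (hp >= len) next
      period <- p
      break
    }
  }
  data.frame(simple_repeat_period = period,
             homopolymer_len = hp,
             dinucleotide_len = di)
}

#' Populate variant-table context features from a reference sequence
#'
#' @param vt a [variant_table()]
#' @param refseq a [Biostrings::DNAStringSet] named by chromosome
#' @param repeats optional GRanges of annotated repeats used to set
#'   `in_annotated_repeat`
#' @inheritParams sequence_context
#' @return `vt` with recomputed context columns
#' @export
add_sequence_context <- function(vt, refseq, repeats = NULL, flank = 50L) {
  rows <- lapply(seq_along(vt$sites), function(i)
    sequence_context(refseq, as.character(seqnames(vt$sites))[i],
                     start(vt$sites)[i], flank = flank))
  ctx <- do.call(rbind, rows)
  ctx$in_annotated_repeat <- if (is.null(repeats))
    vt$context$in_annotated_repeat else overlapsAny(vt$sites, repeats)
  variant_table(vt$sites, vt$ref_reads, vt$alt_reads, vt$mq, ctx)
}
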