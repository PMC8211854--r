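## Random placement of disjoint regions on a genome.
##
## Two samplers share the same contract -- uniform placement over the
## allowed space (genome minus exclusions), regions fully inside
## chromosomes, pairwise disjoint, reproducible for a given seed:
##
##  * sample_disjoint_uniform(): equal-length regions, batched
##    rejection sampling; scales to tens of thousands of draws and
##    backs the Monte-Carlo expected-overlap null.
##  * place_disjoint_regions(): arbitrary length multisets with
##    optional per-region chromosome constraints, exact sequential
##    placement over the remaining free space; backs the
##    chromosome-matched shuffled baseline and annotation simulation.

## Allowed space as a GRanges: genome minus exclusions, reduced.
allowed_space <- function(genome, exclusions = NULL) {
  full <- GRanges(names(genome$chrom_sizes),
                  IRanges(1L, as.integer(genome$chrom_sizes)))
  seqlevels(full) <- names(genome$chrom_sizes)
  seqlengths(full) <- as.integer(genome$chrom_sizes)
  if (!is.null(exclusions) && length(exclusions)) {
    excl <- as_genome_granges(exclusions, genome, clip = TRUE)
    full <- setdiff(full, excl)
  }
  reduce(full)
}

## Draw one batch of candidate starts uniformly over all positions
## where a region of length `len` fits inside an allowed segment.
.sample_starts <- function(n, segs, len) {
  navail <- pmax(width(segs) - len + 1L, 0L)
  if (sum(navail) == 0)
    stop("allowed genome too small: no segment can hold a region of ",
         len, " bp")
  idx <- sample.int(length(segs), n, replace = TRUE,
                    prob = navail / sum(navail))
  off <- floor(runif(n) * navail[idx])
  GRanges(seqnames(segs)[idx], IRanges(start(segs)[idx] + off, width = len))
}

#' Sample disjoint equal-length regions uniformly over a genome
#'
#' Draws `n` regions of fixed length uniformly over the allowed genome
#' (outside `exclusions`, fully inside chromosome bounds), pairwise
#' disjoint, by batched rejection sampling.  Used as the random-region
#' null ("proxy regions") for overlap-enrichment analysis.
#'
#' @param n number of regions
#' @param len region length in bp
#' @param genome a `synthetic_genome`
#' @param exclusions optional GRanges mask never intersected
#' @param seed integer seed (reproducible draws)
#' @return GRanges of `n` disjoint regions of width `len`
#' @export
sample_disjoint_uniform <- function(n, len, genome, exclusions = NULL,
                                    seed = 1L) {
  stopifnot(n > 0, len > 0)
  segs <- allowed_space(genome, exclusions)
  if (n * len > sum(width(segs)))
    stop("allowed genome too small to place ", n, " disjoint regions of ",
         len, " bp")
  withr::with_seed(seed, {
    accepted <- GRanges()
    stalls <- 0L
    while (length(accepted) < n) {
      need <- n - length(accepted)
      cand <- .sample_starts(ceiling(need * 1.3) + 50L, segs, len)
      if (length(accepted))
        cand <- cand[!overlapsAny(cand, accepted)]
      if (length(cand)) {
        hits <- findOverlaps(cand, cand)
        hits <- hits[queryHits(hits) < subjectHits(hits)]
        if (length(hits)) cand <- cand[-unique(subjectHits(hits))]
      }
      if (length(cand) == 0L) {
        stalls <- stalls + 1L
        if (stalls > 20L) {
          ## dense occupancy: finish with exact sequential placement
          excl2 <- if (is.null(exclusions)) accepted
            else c(as_genome_granges(exclusions, genome, clip = TRUE),
                   granges(accepted))
          rest <- place_disjoint_regions(rep(len, need), genome,
                                         exclusions = excl2,
                                         seed = sample.int(.Machine$integer.max - 1L, 1L))
          accepted <- c(accepted, rest)
          break
        }
        next
      }
      stalls <- 0L
      accepted <- c(accepted, head(cand, need))
    }
    sort(accepted)
  })
}

#' Place disjoint regions of given lengths on a genome
#'
#' Places one region per entry of `lengths`, uniformly at random over
#' the free space remaining after earlier placements, optionally
#' constrained to a chromosome per region.  Placement is exact
#' (sequential over explicit free segments): an error names the first
#' chromosome whose demand cannot be met.
#'
#' @param lengths integer vector of region lengths
#' @param genome a `synthetic_genome`
#' @param exclusions optional GRanges mask
#' @param chroms optional character vector (same length as `lengths`)
#'   constraining each region to a chromosome
#' @param seed integer seed
#' @return GRanges of `length(lengths)` disjoint regions, parallel to
#'   the input order
#' @export
place_disjoint_regions <- function(lengths, genome, exclusions = NULL,
                                   chroms = NULL, seed = 1L) {
  stopifnot(all(lengths > 0))
  if (!is.null(chroms)) stopifnot(length(chroms) == length(lengths))
  segs <- allowed_space(genome, exclusions)
  seg_chr <- as.character(seqnames(segs))
  seg_start <- start(segs)
  seg_end <- end(segs)
  ## longest-first improves feasibility; results mapped back to input order
  ord <- order(lengths, decreasing = TRUE)
  out_chr <- character(length(lengths))
  out_start <- integer(length(lengths))
  withr::with_seed(seed, {
    for (i in ord) {
      len <- lengths[i]
      ok <- (seg_end - seg_start + 1L) >= len
      if (!is.null(chroms)) ok <- ok & seg_chr == chroms[i]
      if (!any(ok)) {
        where <- if (is.null(chroms)) "genome" else chroms[i]
        stop("cannot place region of ", len, " bp on ", where,
             ": no free segment large enough")
      }
      w <- ifelse(ok, seg_end - seg_start + 2L - len, 0L)
      j <- sample.int(length(w), 1L, prob = w / sum(w))
      s <- seg_start[j] + floor(runif(1L) * w[j])
      e <- s + len - 1L
      out_chr[i] <- seg_chr[j]
      out_start[i] <- s
      ## split segment j = [A, B] around the placed region [s, e]
      A <- seg_start[j]; B <- seg_end[j]
      seg_start[j] <- 1L; seg_end[j] <- 0L   # mark consumed (width <= 0)
      if (s > A) {
        seg_chr <- c(seg_chr, seg_chr[j])
        seg_start <- c(seg_start, A)
        seg_end <- c(seg_end, s - 1L)
      }
      if (e < B) {
        seg_chr <- c(seg_chr, seg_chr[j])
        seg_start <- c(seg_start, e + 1L)
        seg_end <- c(seg_end, B)
      }
    }
  })
  gr <- GRanges(out_chr, IRanges(out_start, width = lengths))
  seqlevels(gr) <- names(genome$chrom_sizes)
  seqlengths(gr) <- as.integer(genome$chrom_sizes)
  gr
}
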