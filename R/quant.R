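#' Quantification parameters
#'
#' Defaults follow standard MeDIP window-based processing: 500 bp
#' windows, fragments extended to 300 bp from their 5' end, no shift,
#' stacked-read (duplicate) cap at a Poisson tail probability of 1e-3,
#' and sample QC on the 500 most variable 5 kb windows.
#'
#' @param ws analysis window size in bp
#' @param extend fragment extension in bp (3' direction from the 5'
#'   end); 0 keeps the read as given
#' @param shift bp shift of the 5' end in the 3' direction before
#'   extension
#' @param uniq_p Poisson tail threshold for the stacked-read cap, in
#'   `(0, 1]`; 1 disables the filter
#' @param qc_ws window size for PCA-based QC
#' @param qc_top_n number of most-variable windows used in QC
#' @return list of class `quant_params`
#' @export
quant_params <- function(ws = 500L, extend = 300L, shift = 0L,
                         uniq_p = 1e-3, qc_ws = 5000L, qc_top_n = 500L) {
  stopifnot(ws > 0, extend >= 0, uniq_p > 0, uniq_p <= 1,
            qc_ws > 0, qc_top_n > 0)
  structure(list(ws = as.integer(ws), extend = as.integer(extend),
                 shift = as.integer(shift), uniq_p = uniq_p,
                 qc_ws = as.integer(qc_ws), qc_top_n = as.integer(qc_top_n)),
            class = "quant_params")
}

#' Simulate stranded sequencing fragments
#'
#' Draws read 5' positions uniformly over the genome, optionally
#' enriched `enrich_fold`-fold inside `enriched` regions, with random
#' strand.  Returns raw reads of `read_len` bp (before extension), so
#' the extension and duplicate-cap operations are exercised faithfully.
#'
#' @param genome a `synthetic_genome`
#' @param n_fragments number of reads
#' @param seed integer seed
#' @param enriched optional GRanges of enriched regions
#' @param enrich_fold sampling weight of enriched bp relative to
#'   background
#' @param read_len raw read length in bp
#' @return GRanges of stranded reads
#' @export
simulate_fragments <- function(genome, n_fragments, seed = 1L,
                               enriched = NULL, enrich_fold = 1,
                               read_len = 50L) {
  stopifnot(n_fragments >= 1)
  segs <- allowed_space(genome)
  weights <- rep(1, length(segs))
  if (!is.null(enriched) && length(enriched) && enrich_fold != 1) {
    enr <- reduce(as_genome_granges(enriched, genome, clip = TRUE))
    bg <- setdiff(segs, enr)
    segs <- c(bg, enr)
    weights <- c(rep(1, length(bg)), rep(enrich_fold, length(enr)))
  }
  withr::with_seed(seed, {
    w <- width(segs) * weights
    idx <- sample.int(length(segs), n_fragments, replace = TRUE,
                      prob = w / sum(w))
    pos5 <- start(segs)[idx] +
      floor(runif(n_fragments) * width(segs)[idx])
    strand <- sample(c("+", "-"), n_fragments, replace = TRUE)
  })
  chrlen <- genome$chrom_sizes[as.character(seqnames(segs))[idx]]
  start <- ifelse(strand == "+", pos5,
                  pmax(1, pos5 - read_len + 1L))
  end <- ifelse(strand == "+", pmin(chrlen, pos5 + read_len - 1L), pos5)
  gr <- GRanges(seqnames(segs)[idx], IRanges(start, end), strand = strand)
  seqlevels(gr) <- names(genome$chrom_sizes)
  seqlengths(gr) <- as.integer(genome$chrom_sizes)
  sort(gr, ignore.strand = TRUE)
}

#' Extend reads from their 5' end
#'
#' Each read is replaced by an interval of `extend` bp running in the
#' 3' direction from its (optionally shifted) 5' end, clipped at
#' chromosome bounds; with `extend = 0` the read is kept as-is.  This
#' mimics reconstructing the sequenced fragment from a short read.
#'
#' @param reads GRanges with strand (`+` or `-`)
#' @param genome a `synthetic_genome`
#' @param params a [quant_params()]
#' @return object of class `fragment_set`: list with `fragments`
#'   (GRanges) and `library_size` (retained fragment count)
#' @export
extend_fragments <- function(reads, genome, params = quant_params()) {
  reads <- as_genome_granges(reads, genome)
  if (any(strand(reads) == "*"))
    stop("all reads must have a known strand for 5' extension")
  plus <- as.logical(strand(reads) == "+")
  pos5 <- ifelse(plus, start(reads), end(reads))
  if (params$shift != 0)
    pos5 <- pos5 + ifelse(plus, params$shift, -params$shift)
  ext <- if (params$extend > 0) params$extend else width(reads)
  s <- ifelse(plus, pos5, pos5 - ext + 1L)
  e <- ifelse(plus, pos5 + ext - 1L, pos5)
  chrlen <- genome$chrom_sizes[as.character(seqnames(reads))]
  s <- pmax(1L, pmin(s, chrlen))
  e <- pmax(1L, pmin(e, chrlen))
  out <- GRanges(seqnames(reads), IRanges(s, e), strand = strand(reads))
  seqlevels(out) <- names(genome$chrom_sizes)
  seqlengths(out) <- as.integer(genome$chrom_sizes)
  structure(list(fragments = out, library_size = length(out)),
            class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set:", x$library_size, "fragments\n")
  invisible(x)
}

#' Cap stacked reads at identical genomic positions
#'
#' Reads stacking at an identical (chromosome, start, strand) key are
#' capped at `s_max` copies, where `s_max` is the smallest integer `s`
#' with `P(X >= s) < uniq_p` for `X ~ Poisson(lambda)`, `lambda` being
#' the per-position expected stack height: library size divided by the
#' number of available start positions (genome length times two
#' strands).  With `uniq_p = 1` nothing is removed.  The removed count
#' is reported via `attr(, "removed")`, the cap via `attr(, "s_max")`.
#'
#' @param fragset a `fragment_set` from [extend_fragments()]
#' @param uniq_p Poisson tail threshold
#' @param genome a `synthetic_genome` (defines the number of available
#'   start positions)
#' @return a filtered `fragment_set`
#' @export
apply_uniq_filter <- function(fragset, uniq_p = 1e-3, genome = NULL) {
  stopifnot(inherits(fragset, "fragment_set"), uniq_p > 0, uniq_p <= 1)
  fr <- fragset$fragments
  if (uniq_p == 1 || length(fr) == 0L) {
    out <- fragset
    attr(out, "removed") <- 0L
    return(out)
  }
  key <- paste(seqnames(fr), start(fr), strand(fr))
  n_positions <- if (!is.null(genome)) 2 * genome_length(genome)
    else 2 * sum(as.numeric(seqlengths(fr)), na.rm = TRUE)
  if (!is.finite(n_positions) || n_positions <= 0)
    stop("genome size unknown: pass `genome` or set seqlengths")
  lambda <- length(fr) / n_positions
  s_max <- 1L
  while (ppois(s_max - 1L, lambda, lower.tail = FALSE) >= uniq_p)
    s_max <- s_max + 1L
  ord <- order(as.factor(key))
  fr <- fr[ord]; key <- key[ord]
  within_stack <- sequence(table(key)[unique(key)])
  keep <- within_stack <= s_max
  out_fr <- sort(fr[keep], ignore.strand = TRUE)
  out <- structure(list(fragments = out_fr, library_size = sum(keep)),
                   class = "fragment_set")
  attr(out, "removed") <- sum(!keep)
  attr(out, "s_max") <- s_max
  out
}

#' Count fragments into the genome window tiling
#'
#' Builds the window x replicate count matrix.  In the default
#' `"overlap"` mode a fragment increments every window it overlaps by
#' at least 1 bp; in `"midpoint"` mode (an oracle for conservation
#' checks) each fragment is assigned to the single window containing
#' its midpoint, so column sums equal library sizes exactly.
#'
#' @param fragsets named list of `fragment_set`s, one per replicate
#' @param genome a `synthetic_genome`
#' @param params a [quant_params()]
#' @param groups character vector of group labels parallel to
#'   `fragsets`
#' @param mode `"overlap"` (default) or `"midpoint"`
#' @return [SummarizedExperiment::SummarizedExperiment] with assay
#'   `counts`, window `rowRanges`, and colData `group`, `lib_size`
#' @export
window_counts <- function(fragsets, genome, params = quant_params(),
                          groups = NULL, mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  stopifnot(length(fragsets) >= 1)
  windows <- genome_windows(genome, params$ws)
  counts <- matrix(0L, nrow = length(windows), ncol = length(fragsets))
  lib_sizes <- integer(length(fragsets))
  for (i in seq_along(fragsets)) {
    fs <- fragsets[[i]]
    stopifnot(inherits(fs, "fragment_set"))
    fr <- fs$fragments
    bad <- setdiff(as.character(unique(seqnames(fr))),
                   names(genome$chrom_sizes))
    if (length(bad))
      stop("replicate ", i, " is on a different genome (chromosome(s) ",
           paste(bad, collapse = ", "), " unknown)")
    if (mode == "midpoint")
      fr <- GRanges(seqnames(fr),
                    IRanges(start(fr) + floor((width(fr) - 1) / 2),
                            width = 1L))
    counts[, i] <- countOverlaps(windows, fr, ignore.strand = TRUE)
    lib_sizes[i] <- fs$library_size
    if (fs$library_size == 0L)
      message("replicate ", i, " has library size 0 (all-zero column)")
  }
  nm <- names(fragsets)
  if (is.null(nm)) nm <- paste0("rep", seq_along(fragsets))
  colnames(counts) <- nm
  if (is.null(groups)) groups <- rep("A", length(fragsets))
  SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = windows,
    colData = S4Vectors::DataFrame(group = groups, lib_size = lib_sizes,
                                   row.names = nm))
}

#' Add an RPKM assay to a window-count experiment
#'
#' `rpkm = count / (width_kb * lib_size_millions)`, using the actual
#' window width (the final window of a chromosome may be shorter than
#' `ws`).
#'
#' @param se SummarizedExperiment with assay `counts` and colData
#'   `lib_size`
#' @return `se` with an added assay `rpkm`
#' @export
to_rpkm <- function(se) {
  lib <- colData(se)$lib_size
  if (any(lib <= 0))
    stop("library size must be > 0 for RPKM (offending replicate(s): ",
         paste(colnames(se)[lib <= 0], collapse = ", "), ")")
  kb <- width(rowRanges(se)) / 1000
  rpkm <- sweep(assay(se, "counts") / kb, 2L, lib / 1e6, `/`)
  assay(se, "rpkm") <- rpkm
  se
}

#' Background methylome mask
#'
#' A window belongs to the background methylome when the sum over
#' groups of its group-mean RPKM is strictly greater than `threshold`.
#'
#' @param se SummarizedExperiment with assay `rpkm` and colData `group`
#' @param threshold default 1.0
#' @return logical vector over windows
#' @export
background_methylome <- function(se, threshold = 1.0) {
  groups <- colData(se)$group
  if (any(table(groups) == 0) || length(unique(groups)) < 1)
    stop("each group needs at least one replicate")
  rpkm <- assay(se, "rpkm")
  gm <- vapply(unique(groups), function(g)
    rowMeans(rpkm[, groups == g, drop = FALSE]), numeric(nrow(se)))
  rowSums(gm) > threshold
}

#' PCA-based sample QC
#'
#' Ranks windows by across-sample variance of coverage (RPKM when the
#' assay is present, raw counts otherwise), keeps the `top_n` most
#' variable (ties broken by window order), and returns centred sample
#' coordinates on the first two principal axes.
#'
#' @param se SummarizedExperiment of QC windows (typically a coarser
#'   tiling than the analysis windows, e.g. 5 kb)
#' @param top_n number of windows used (all, with a warning, when
#'   fewer are available)
#' @return data.frame with rownames = samples, columns `PC1`, `PC2`
#'   and attribute `var_explained`
#' @export
qc_pca <- function(se, top_n = 500L) {
  if (ncol(se) < 3L) stop("PCA QC needs at least 3 samples")
  x <- if ("rpkm" %in% assayNames(se)) assay(se, "rpkm")
       else assay(se, "counts")
  v <- apply(x, 1L, var)
  if (nrow(x) < top_n) {
    warning("only ", nrow(x), " windows available; using all")
    top_n <- nrow(x)
  }
  ord <- order(-v, seq_along(v))  # ties broken by window order
  sel <- ord[seq_len(top_n)]
  pc <- prcomp(t(x[sel, , drop = FALSE]), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  out <- as.data.frame(pc$x[, seq_len(k), drop = FALSE])
  if (k == 1L) out$PC2 <- 0
  colnames(out) <- c("PC1", "PC2")
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  attr(out, "var_explained") <- ve[seq_len(min(2L, length(ve)))]
  out
}
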