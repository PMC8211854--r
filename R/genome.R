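#' Construct a synthetic genome from chromosome sizes
#'
#' A genome is represented by its chromosome-size table, the only
#' information the window-based pipeline needs.  Stands in for a real
#' assembly's `chrom.sizes` file.
#'
#' @param chrom_sizes named numeric vector or named list, chromosome
#'   name -> length in bp.  All lengths must be positive and names
#'   unique.
#' @param seed integer seed recorded with the genome; downstream
#'   simulators derive their randomness from it.
#' @return An object of class `synthetic_genome`: a list with elements
#'   `chrom_sizes` (named integer-valued numeric) and `seed`.
#' @examples
#' g <- make_genome(c(chr1 = 1e6, chr2 = 5e5), seed = 1)
#' genome_length(g)
#' @export
make_genome <- function(chrom_sizes, seed = 1L) {
  chrom_sizes <- unlist(chrom_sizes)
  if (length(chrom_sizes) == 0L)
    stop("empty genome: at least one chromosome is required")
  if (is.null(names(chrom_sizes)) || any(!nzchar(names(chrom_sizes))))
    stop("chromosome sizes must be named")
  if (anyDuplicated(names(chrom_sizes)))
    stop("duplicate chromosome name: ",
         paste(unique(names(chrom_sizes)[duplicated(names(chrom_sizes))]),
               collapse = ", "))
  if (any(!is.finite(chrom_sizes)) || any(chrom_sizes <= 0))
    stop("all chromosome lengths must be positive")
  structure(
    list(chrom_sizes = round(chrom_sizes), seed = as.integer(seed)),
    class = "synthetic_genome"
  )
}

#' @export
print.synthetic_genome <- function(x, ...) {
  cat("synthetic_genome:", length(x$chrom_sizes), "chromosome(s),",
      format(genome_length(x), big.mark = ","), "bp total\n")
  invisible(x)
}

#' Total genome length in bp
#' @param genome a `synthetic_genome`
#' @return numeric scalar
#' @export
genome_length <- function(genome) sum(genome$chrom_sizes)

#' Seqinfo for a synthetic genome
#' @param genome a `synthetic_genome`
#' @return a [GenomeInfoDb::Seqinfo] object
#' @export
genome_seqinfo <- function(genome) {
  Seqinfo(seqnames = names(genome$chrom_sizes),
          seqlengths = as.integer(genome$chrom_sizes))
}

#' Gapless window tiling of a genome
#'
#' Tiles every chromosome into consecutive non-overlapping windows of
#' `ws` bp.  The last window of a chromosome may be shorter than `ws`
#' so that the tiling covers the chromosome exactly.
#'
#' @param genome a `synthetic_genome`
#' @param ws window size in bp (default 500)
#' @return a [GenomicRanges::GRanges] of windows, ordered by chromosome
#'   then start, with seqlengths set.
#' @export
genome_windows <- function(genome, ws = 500L) {
  stopifnot(ws > 0)
  tiles <- tileGenome(genome_seqinfo(genome), tilewidth = ws,
                      cut.last.tile.in.chrom = TRUE)
  tiles
}

#' Read / write a chromosome-sizes table
#'
#' Plain two-column tab-separated file: chromosome name, length in bp
#' (the standard `chrom.sizes` layout).
#'
#' @param genome a `synthetic_genome`
#' @param path file path
#' @return `write_chrom_sizes` returns `path` invisibly;
#'   `read_chrom_sizes` returns a `synthetic_genome` (seed 0).
#' @export
write_chrom_sizes <- function(genome, path) {
  df <- data.frame(chrom = names(genome$chrom_sizes),
                   size = as.integer(genome$chrom_sizes))
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_chrom_sizes
#' @export
read_chrom_sizes <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("chrom", "size"),
                   colClasses = c("character", "numeric"))
  make_genome(setNames(df$size, df$chrom), seed = 0L)
}

## Coerce interval input (GRanges or BED-like data.frame) to GRanges on
## the genome, validating chromosome names and bounds.
as_genome_granges <- function(x, genome, clip = FALSE) {
  if (is.data.frame(x)) {
    strand <- if ("strand" %in% names(x)) x$strand else "*"
    x <- GRanges(x$chrom, IRanges(x$start + 1L, x$end), strand = strand)
  }
  stopifnot(is(x, "GRanges"))
  unknown <- setdiff(as.character(unique(seqnames(x))),
                     names(genome$chrom_sizes))
  if (length(unknown))
    stop("unknown chromosome(s): ", paste(unknown, collapse = ", "))
  seqlevels(x) <- names(genome$chrom_sizes)
  seqlengths(x) <- as.integer(genome$chrom_sizes)
  if (clip) x <- trim(x)
  x
}

## Internal: deterministic seed derivation (keeps derived seeds < 2^31)
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% .Machine$integer.max)
}
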