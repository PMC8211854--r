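#' Simulate an annotation bundle for a synthetic genome
#'
#' Generates the interval sets the context and enrichment modules
#' consume: genes with TSS and exons (introns are the within-gene
#' complement), CpG islands, repeats classed as LTR/LINE/SINE/other,
#' enhancers, nucleosome-retention regions and reprogramming-resistant
#' regions (pre-implantation and germline).  Each set is sorted,
#' clipped to chromosome bounds and non-overlapping within itself;
#' overlap across sets is allowed, as in real genomes.  Sets built to a
#' target covered fraction carry it (computed from the realised
#' intervals, so exact) as `metadata(set)$covered_fraction`.
#'
#' @param genome a `synthetic_genome`
#' @param seed integer seed
#' @param gene_density genes per bp (default one per 50 kb)
#' @param retention_fraction,resist_preimpl_fraction,resist_germline_fraction
#'   target fractions of the genome covered by nucleosome-retention and
#'   reprogramming-resistant region sets
#' @param repeat_fraction target genome fraction covered by repeats
#' @param n_enhancers number of enhancer elements (default one per
#'   100 kb)
#' @return named list of GRanges: `genes`, `tss`, `exons`, `cgis`,
#'   `repeats` (mcols column `class`), `enhancers`, `retention`,
#'   `resist_preimpl`, `resist_germline`
#' @export
simulate_annotations <- function(genome, seed = 1L,
                                 gene_density = 1 / 5e4,
                                 retention_fraction = 0.02,
                                 resist_preimpl_fraction = 0.05,
                                 resist_germline_fraction = 0.01,
                                 repeat_fraction = 0.15,
                                 n_enhancers = NULL) {
  glen <- genome_length(genome)
  n_genes <- max(1L, round(glen * gene_density))
  if (is.null(n_enhancers)) n_enhancers <- max(1L, round(glen / 1e5))

  withr::with_seed(derive_seed(seed, 11L), {
    gene_len <- pmin(round(exp(runif(n_genes, log(5e3), log(5e4)))),
                     max(genome$chrom_sizes))
  })
  genes <- place_disjoint_regions(gene_len, genome,
                                  seed = derive_seed(seed, 12L))
  withr::with_seed(derive_seed(seed, 13L), {
    strand(genes) <- sample(c("+", "-"), length(genes), replace = TRUE)
  })
  mcols(genes)$gene_id <- paste0("gene", seq_along(genes))
  genes <- sort(genes, ignore.strand = TRUE)
  mcols(genes)$gene_id <- paste0("gene", seq_along(genes))

  tss <- resize(genes, width = 1L, fix = "start")
  mcols(tss)$gene_id <- mcols(genes)$gene_id

  ## exons: 2-8 per gene, tiled from alternating chunk boundaries so
  ## every exon lies inside its gene body
  exons <- withr::with_seed(derive_seed(seed, 14L), {
    pieces <- lapply(seq_along(genes), function(i) {
      g <- genes[i]
      n_ex <- sample(2:8, 1L)
      bounds <- sort(sample(seq_len(width(g) - 1L),
                            min(2L * n_ex - 1L, width(g) - 1L)))
      bounds <- c(0L, bounds, width(g))
      ## odd chunks are exons
      starts <- bounds[-length(bounds)] + start(g)
      ends <- bounds[-1] + start(g) - 1L
      keep <- seq_along(starts) %% 2L == 1L
      GRanges(seqnames(g), IRanges(starts[keep], ends[keep]),
              strand = strand(g), gene_id = mcols(g)$gene_id)
    })
    do.call(c, pieces)
  })

  mk_fraction_set <- function(frac, len_lo, len_hi, offset) {
    target_bp <- round(frac * glen)
    withr::with_seed(derive_seed(seed, offset), {
      lens <- integer()
      while (sum(lens) < target_bp)
        lens <- c(lens, round(runif(64L, len_lo, len_hi)))
      cum <- cumsum(lens)
      k <- which(cum >= target_bp)[1L]
      lens <- lens[seq_len(k)]
      lens[k] <- lens[k] - (cum[k] - target_bp)  # hit the target exactly
      lens <- lens[lens > 0]
    })
    gr <- sort(place_disjoint_regions(lens, genome,
                                      seed = derive_seed(seed, offset + 1L)))
    S4Vectors::metadata(gr)$covered_fraction <- sum(width(gr)) / glen
    gr
  }

  cgis <- mk_fraction_set(0.01, 400, 2000, 21L)
  retention <- mk_fraction_set(retention_fraction, 500, 3000, 31L)
  resist_preimpl <- mk_fraction_set(resist_preimpl_fraction, 500, 5000, 41L)
  resist_germline <- mk_fraction_set(resist_germline_fraction, 500, 5000, 51L)

  repeats <- mk_fraction_set(repeat_fraction, 200, 6000, 61L)
  withr::with_seed(derive_seed(seed, 62L), {
    mcols(repeats)$class <- sample(c("LTR", "LINE", "SINE", "other"),
                                   length(repeats), replace = TRUE,
                                   prob = c(0.25, 0.35, 0.3, 0.1))
  })

  withr::with_seed(derive_seed(seed, 71L), {
    enh_len <- round(runif(n_enhancers, 200, 600))
  })
  enhancers <- sort(place_disjoint_regions(
    enh_len, genome, seed = derive_seed(seed, 72L)))
  mcols(enhancers)$enhancer_id <- paste0("enh", seq_along(enhancers))

  list(genes = genes, tss = tss, exons = sort(exons, ignore.strand = TRUE),
       cgis = cgis, repeats = repeats, enhancers = enhancers,
       retention = retention, resist_preimpl = resist_preimpl,
       resist_germline = resist_germline)
}

#' Write an annotation bundle as BED6 files
#'
#' One `<name>.bed` per set under `dir`; repeat class and gene/enhancer
#' identifiers go in the BED name column.
#'
#' @param annotations list as returned by [simulate_annotations()]
#' @param dir output directory (created if needed)
#' @return invisibly, the named vector of written paths
#' @export
write_annotation_beds <- function(annotations, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(annotations), function(nm) {
    gr <- annotations[[nm]]
    nmcol <- if ("gene_id" %in% names(mcols(gr))) mcols(gr)$gene_id
      else if ("class" %in% names(mcols(gr))) mcols(gr)$class
      else if ("enhancer_id" %in% names(mcols(gr))) mcols(gr)$enhancer_id
      else paste0(nm, seq_along(gr))
    out <- gr
    mcols(out) <- NULL
    mcols(out)$name <- nmcol
    path <- file.path(dir, paste0(nm, ".bed"))
    rtracklayer::export(out, path, format = "BED")
    path
  }, character(1))
  invisible(paths)
}
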