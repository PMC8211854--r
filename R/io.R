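## Plain-text interchange: BED via rtracklayer, count matrices and
## sample sheets as TSV, signal tracks as bedGraph.

#' Read stranded fragments / reads from a BED file
#'
#' @param path BED file (column 6 strand respected when present)
#' @param genome optional `synthetic_genome` used to validate
#'   chromosome names
#' @return GRanges
#' @export
read_fragments_bed <- function(path, genome = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(genome)) gr <- as_genome_granges(gr, genome)
  gr
}

#' Write intervals as BED
#'
#' @param gr GRanges
#' @param path output path
#' @return `path` invisibly
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Write / read a window-count experiment as TSV
#'
#' Two files: `<stem>.counts.tsv` (chrom, start \[0-based\], end, one
#' column per sample) and `<stem>.samples.tsv` (sample, group,
#' lib_size).
#'
#' @param se SummarizedExperiment with assay `counts`
#' @param stem output path stem
#' @return the two paths, invisibly
#' @export
write_count_matrix <- function(se, stem) {
  gr <- rowRanges(se)
  df <- cbind(data.frame(chrom = as.character(seqnames(gr)),
                         start = start(gr) - 1L, end = end(gr)),
              as.data.frame(assay(se, "counts")))
  p1 <- paste0(stem, ".counts.tsv")
  write.table(df, p1, sep = "\t", quote = FALSE, row.names = FALSE)
  sm <- data.frame(sample = colnames(se),
                   group = colData(se)$group,
                   lib_size = colData(se)$lib_size)
  p2 <- paste0(stem, ".samples.tsv")
  write.table(sm, p2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(p1, p2))
}

#' @rdname write_count_matrix
#' @param stem path stem used at write time
#' @export
read_count_matrix <- function(stem) {
  df <- read.table(paste0(stem, ".counts.tsv"), sep = "\t", header = TRUE,
                   check.names = FALSE)
  sm <- read.table(paste0(stem, ".samples.tsv"), sep = "\t",
                   header = TRUE)
  gr <- GRanges(df$chrom, IRanges(df$start + 1L, df$end))
  counts <- as.matrix(df[, -(1:3), drop = FALSE])
  SummarizedExperiment(
    assays = list(counts = counts), rowRanges = gr,
    colData = S4Vectors::DataFrame(group = sm$group,
                                   lib_size = sm$lib_size,
                                   row.names = sm$sample))
}

#' Read a bedGraph signal track
#'
#' @param path bedGraph path
#' @return GRanges with numeric `score`
#' @export
read_bedgraph <- function(path) {
  rtracklayer::import(path, format = "bedGraph")
}

#' Write a bedGraph signal track
#'
#' @param gr GRanges with `score`
#' @param path output path
#' @return `path` invisibly
#' @export
write_bedgraph <- function(gr, path) {
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read an annotation bundle from a directory of BED files
#'
#' Inverse of [write_annotation_beds()]: expects `genes.bed`,
#' `exons.bed`, `cgis.bed`, `repeats.bed` (class in the name column),
#' `enhancers.bed`, `retention.bed`, `resist_preimpl.bed`,
#' `resist_germline.bed`; missing files are skipped.  The TSS set is
#' derived from the genes' strand.
#'
#' @param dir directory path
#' @return named list of GRanges
#' @export
read_annotation_beds <- function(dir) {
  out <- list()
  for (nm in c("genes", "exons", "cgis", "repeats", "enhancers",
               "retention", "resist_preimpl", "resist_germline")) {
    path <- file.path(dir, paste0(nm, ".bed"))
    if (!file.exists(path)) next
    gr <- rtracklayer::import(path, format = "BED")
    if (nm %in% c("genes", "exons") && "name" %in% names(mcols(gr)))
      mcols(gr)$gene_id <- mcols(gr)$name
    if (nm == "repeats" && "name" %in% names(mcols(gr)))
      mcols(gr)$class <- mcols(gr)$name
    if (nm == "enhancers" && "name" %in% names(mcols(gr)))
      mcols(gr)$enhancer_id <- mcols(gr)$name
    out[[nm]] <- gr
  }
  if (!is.null(out$genes)) {
    tss <- resize(out$genes, width = 1L, fix = "start")
    mcols(tss) <- mcols(out$genes)["gene_id"]
    out$tss <- tss
  }
  out
}
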