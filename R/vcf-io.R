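## Minimal VCF 4.2 interchange for variant tables.
##
## Writing is plain text (header + one record per site) with the
## fields the filter cascade needs: INFO MQ/SRP/HPL/DNL/REP and
## per-sample GT:AD.  Reading goes through VariantAnnotation so any
## conforming VCF with AD genotypes can be ingested.

#' Write a variant table as a minimal VCF 4.2 file
#'
#' INFO carries `MQ` (mapping quality), `SRP` (simple-repeat
#' periodicity, omitted when absent), `HPL` (homopolymer length),
#' `DNL` (dinucleotide repeat length) and the flag `REP` (annotated
#' repeat overlap).  FORMAT is `GT:AD`; GT is written as `./.` since
#' genotype calling from AD is a downstream operation.
#'
#' @param vt a [variant_table()]
#' @param path output path
#' @param genome optional `synthetic_genome` for contig header lines
#' @return `path`, invisibly
#' @export
write_variant_vcf <- function(vt, path, genome = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=medipr",
    if (!is.null(genome))
      sprintf("##contig=<ID=%s,length=%d>", names(genome$chrom_sizes),
              as.integer(genome$chrom_sizes)),
    '##INFO=<ID=MQ,Number=1,Type=Float,Description="Mapping quality">',
    '##INFO=<ID=SRP,Number=1,Type=Integer,Description="Simple repeat periodicity">',
    '##INFO=<ID=HPL,Number=1,Type=Integer,Description="Homopolymer length">',
    '##INFO=<ID=DNL,Number=1,Type=Integer,Description="Dinucleotide repeat length">',
    '##INFO=<ID=REP,Number=0,Type=Flag,Description="Overlaps annotated repeat or segmental duplication">',
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Ref and alt read depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", vt$samples), collapse = "\t")
  )
  ref <- if ("ref" %in% names(mcols(vt$sites))) mcols(vt$sites)$ref
         else rep("N", length(vt$sites))
  alt <- if ("alt" %in% names(mcols(vt$sites))) mcols(vt$sites)$alt
         else rep("A", length(vt$sites))
  info <- vapply(seq_along(vt$sites), function(i) {
    parts <- c(sprintf("MQ=%g", vt$mq[i]),
               if (!is.na(vt$context$simple_repeat_period[i]))
                 sprintf("SRP=%d",
                         as.integer(vt$context$simple_repeat_period[i])),
               sprintf("HPL=%d", as.integer(vt$context$homopolymer_len[i])),
               sprintf("DNL=%d", as.integer(vt$context$dinucleotide_len[i])),
               if (isTRUE(vt$context$in_annotated_repeat[i])) "REP")
    paste(parts, collapse = ";")
  }, character(1))
  gt <- matrix(sprintf("./.:%d,%d", vt$ref_reads, vt$alt_reads),
               nrow = nrow(vt$ref_reads))
  recs <- paste(as.character(seqnames(vt$sites)), start(vt$sites), ".",
                ref, alt, ".", ".", info, "GT:AD",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  if (length(vt$sites) == 0L) recs <- character()
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a VCF into a variant table
#'
#' Expects per-sample `AD` (ref, alt depths) and site-level `MQ`.
#' The repeat-context INFO fields written by [write_variant_vcf()]
#' (`SRP`, `HPL`, `DNL`, `REP`) are recovered when present and default
#' to "no repeat context" otherwise.
#'
#' @param path VCF path (plain text or bgzipped)
#' @return a [variant_table()]
#' @export
read_variant_vcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  n <- length(rr)
  sites <- GRanges(seqnames(rr), ranges(rr))
  mcols(sites)$ref <- as.character(rr$REF)
  alt_list <- rr$ALT
  mcols(sites)$alt <- vapply(seq_len(n), function(i)
    as.character(alt_list[[i]][1L]), character(1))
  ad <- VariantAnnotation::geno(vcf)$AD
  if (is.null(ad)) stop("VCF has no AD genotype field")
  take <- function(k) {
    m <- matrix(0L, nrow = n, ncol = ncol(ad), dimnames = dimnames(ad))
    for (j in seq_len(ncol(ad)))
      m[, j] <- vapply(ad[, j], function(x) as.integer(x[k]), integer(1))
    m
  }
  info <- VariantAnnotation::info(vcf)
  get_info <- function(field, default) {
    if (field %in% names(info)) {
      v <- info[[field]]
      if (is(v, "List") || is.list(v))
        v <- vapply(v, function(x) if (length(x)) x[1L] else NA_real_,
                    numeric(1))
      as.numeric(v)
    } else rep(default, n)
  }
  ctx <- data.frame(
    simple_repeat_period = get_info("SRP", NA_real_),
    homopolymer_len = get_info("HPL", 1),
    dinucleotide_len = get_info("DNL", 0),
    in_annotated_repeat = if ("REP" %in% names(info))
      as.logical(info$REP) else rep(FALSE, n)
  )
  ctx$homopolymer_len[is.na(ctx$homopolymer_len)] <- 1
  ctx$dinucleotide_len[is.na(ctx$dinucleotide_len)] <- 0
  mq <- get_info("MQ", NA_real_)
  variant_table(sites, take(1L), take(2L), mq, ctx)
}

#' Write the filter verdicts back as a VCF FILTER column
#'
#' Writes the full table with FILTER `PASS` or the semicolon-joined
#' reason codes from [filter_variants()].
#'
#' @param vt a [variant_table()]
#' @param status character vector from `filter_variants()$status`
#' @param path output path
#' @param genome optional `synthetic_genome` for contig lines
#' @return `path`, invisibly
#' @export
write_filtered_vcf <- function(vt, status, path, genome = NULL) {
  tmp <- tempfile(fileext = ".vcf")
  write_variant_vcf(vt, tmp, genome)
  lines <- readLines(tmp)
  is_rec <- !startsWith(lines, "#")
  recs <- strsplit(lines[is_rec], "\t", fixed = TRUE)
  filt <- ifelse(status == "pass", "PASS", gsub(",", ";", status))
  recs <- vapply(seq_along(recs), function(i) {
    r <- recs[[i]]; r[7] <- filt[i]; paste(r, collapse = "\t")
  }, character(1))
  extra <- sprintf(
    '##FILTER=<ID=%s,Description="Hard-filter rule %s fired">',
    c("i", "ii", "iii", "iv", "v", "vi"), c("i", "ii", "iii", "iv", "v", "vi"))
  hdr <- lines[!is_rec]
  hdr <- append(hdr, extra, after = 2L)
  writeLines(c(hdr, recs), path)
  unlink(tmp)
  invisible(path)
}
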