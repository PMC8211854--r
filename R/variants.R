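#' Genotype-calling thresholds
#'
#' A site is called homozygous-variant in a sample when the alternate
#' read fraction is strictly above `hom_fraction`, heterozygous when it
#' is at least `het_fraction` (and not above `hom_fraction`), and
#' reference ("none") below `het_fraction`.
#'
#' @param hom_fraction strict lower bound for a homozygous call
#'   (default 0.90)
#' @param het_fraction inclusive lower bound for a heterozygous call
#'   (default 0.30)
#' @return list of class `genotype_params`
#' @export
genotype_params <- function(hom_fraction = 0.90, het_fraction = 0.30) {
  stopifnot(het_fraction > 0, het_fraction < hom_fraction,
            hom_fraction <= 1)
  structure(list(hom_fraction = hom_fraction, het_fraction = het_fraction),
            class = "genotype_params")
}

#' Hard-filter thresholds for the variant cascade
#'
#' Rules (any firing removes the variant):
#' (i) inside a simple repeat with periodicity < `max_simple_repeat_period`;
#' (ii) homopolymer run > `max_homopolymer` bp;
#' (iii) dinucleotide repeat > `max_dinucleotide` bp;
#' (iv) mapping quality < `min_mq`;
#' (v) overlapping an annotated repeat or segmental duplication;
#' (vi) more than `het_cluster_max` heterozygous calls of the same
#' sample inside any `het_cluster_span` bp window.
#'
#' @param max_simple_repeat_period strict upper bound, default 9
#' @param max_homopolymer kept up to this length, default 8
#' @param max_dinucleotide kept up to this length, default 14
#' @param min_mq kept at or above this mapping quality, default 40
#' @param het_cluster_max kept up to this many hets per span, default 3
#' @param het_cluster_span span in bp for rule (vi), default 10000
#' @param sv_proximity_bp flag distance for SV proximity, default 1000
#' @return list of class `variant_filter_params`
#' @export
variant_filter_params <- function(max_simple_repeat_period = 9,
                                  max_homopolymer = 8,
                                  max_dinucleotide = 14,
                                  min_mq = 40,
                                  het_cluster_max = 3,
                                  het_cluster_span = 10000,
                                  sv_proximity_bp = 1000) {
  vals <- c(max_simple_repeat_period, max_homopolymer, max_dinucleotide,
            min_mq, het_cluster_max, het_cluster_span, sv_proximity_bp)
  stopifnot(all(vals > 0))
  structure(list(max_simple_repeat_period = max_simple_repeat_period,
                 max_homopolymer = max_homopolymer,
                 max_dinucleotide = max_dinucleotide,
                 min_mq = min_mq, het_cluster_max = het_cluster_max,
                 het_cluster_span = het_cluster_span,
                 sv_proximity_bp = sv_proximity_bp),
            class = "variant_filter_params")
}

#' Construct a variant table
#'
#' The working container for the variant module: sites plus per-sample
#' ref/alt read support, site mapping quality and repeat-context
#' features.
#'
#' @param sites GRanges of variant sites (1 bp for SNVs), with optional
#'   mcols `ref`/`alt` alleles
#' @param ref_reads,alt_reads integer matrices, sites x samples
#' @param mq numeric vector of per-site mapping qualities
#' @param context data.frame with columns `simple_repeat_period`
#'   (NA when not in a simple repeat), `homopolymer_len`,
#'   `dinucleotide_len`, `in_annotated_repeat` (logical)
#' @return object of class `variant_table`
#' @export
variant_table <- function(sites, ref_reads, alt_reads, mq, context) {
  ref_reads <- as.matrix(ref_reads); alt_reads <- as.matrix(alt_reads)
  n <- length(sites)
  stopifnot(nrow(ref_reads) == n, nrow(alt_reads) == n,
            ncol(ref_reads) == ncol(alt_reads), length(mq) == n,
            nrow(context) == n)
  stopifnot(all(ref_reads >= 0), all(alt_reads >= 0))
  needed <- c("simple_repeat_period", "homopolymer_len",
              "dinucleotide_len", "in_annotated_repeat")
  missing_ctx <- setdiff(needed, names(context))
  if (length(missing_ctx))
    stop("missing context feature(s): ", paste(missing_ctx, collapse = ", "))
  if (is.null(colnames(ref_reads)))
    colnames(ref_reads) <- colnames(alt_reads) <-
      paste0("sample", seq_len(ncol(ref_reads)))
  structure(list(sites = sites, ref_reads = ref_reads,
                 alt_reads = alt_reads, mq = as.numeric(mq),
                 context = context[, needed, drop = FALSE],
                 samples = colnames(ref_reads)),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat("variant_table:", length(x$sites), "site(s),",
      length(x$samples), "sample(s)\n")
  invisible(x)
}

#' Call a genotype from ref/alt read support
#'
#' Vectorised.  With `f = alt / (ref + alt)`: `f > hom_fraction` is
#' `"hom"`, `het_fraction <= f <= hom_fraction` is `"het"`, and
#' `f < het_fraction` is `"none"`.  Zero total depth is uncallable and
#' returns `NA`.
#'
#' @param ref_reads,alt_reads non-negative integer vectors
#' @param params a [genotype_params()]
#' @return character vector in `{"hom", "het", "none", NA}`
#' @export
call_genotype <- function(ref_reads, alt_reads, params = genotype_params()) {
  stopifnot(all(ref_reads >= 0), all(alt_reads >= 0))
  depth <- ref_reads + alt_reads
  f <- ifelse(depth > 0, alt_reads / depth, NA_real_)
  out <- ifelse(is.na(f), NA_character_,
         ifelse(f > params$hom_fraction, "hom",
         ifelse(f >= params$het_fraction, "het", "none")))
  out
}

#' Genotype-call matrix for a variant table
#'
#' @param vt a [variant_table()]
#' @param params a [genotype_params()]
#' @return character matrix (sites x samples) of calls
#' @export
call_genotypes <- function(vt, params = genotype_params()) {
  stopifnot(inherits(vt, "variant_table"))
  calls <- matrix(call_genotype(as.vector(vt$ref_reads),
                                as.vector(vt$alt_reads), params),
                  nrow = nrow(vt$ref_reads),
                  dimnames = dimnames(vt$ref_reads))
  calls
}

## rule (vi): indices of het calls lying in any window of more than
## `kmax` hets of one sample spanning < `span` bp
.het_cluster_hits <- function(vt, calls, kmax, span) {
  flagged <- rep(FALSE, length(vt$sites))
  chrom <- as.character(seqnames(vt$sites))
  pos <- start(vt$sites)
  for (s in seq_along(vt$samples)) {
    is_het <- !is.na(calls[, s]) & calls[, s] == "het"
    for (ch in unique(chrom[is_het])) {
      idx <- which(is_het & chrom == ch)
      idx <- idx[order(pos[idx])]
      p <- pos[idx]
      k <- kmax + 1L  # smallest offending cluster size
      if (length(p) < k) next
      for (i in seq_len(length(p) - k + 1L)) {
        if (p[i + k - 1L] - p[i] < span)
          flagged[idx[i:(i + k - 1L)]] <- TRUE
      }
    }
  }
  flagged
}

#' Apply the hard-filter cascade to a variant table
#'
#' Each variant accumulates the codes of every rule that fires; a
#' variant is removed when any rule fires.  Rule (vi) is evaluated per
#' sample with a sliding span: every heterozygous call that lies in any
#' `het_cluster_span` window containing more than `het_cluster_max`
#' hets of that sample is removed (record-level).  The result is
#' independent of input order.
#'
#' @param vt a [variant_table()]
#' @param params a [variant_filter_params()]
#' @param gt_params a [genotype_params()] used for rule (vi)
#' @param repeats optional GRanges of annotated repeats / segmental
#'   duplications for rule (v); when `NULL`, the context flag
#'   `in_annotated_repeat` is used instead
#' @return list with elements `passed` and `removed` (both
#'   `variant_table`s), `status` (character vector `"pass"` or
#'   comma-separated reason codes) and `reasons` (list of character
#'   vectors per variant)
#' @export
filter_variants <- function(vt, params = variant_filter_params(),
                            gt_params = genotype_params(),
                            repeats = NULL) {
  stopifnot(inherits(vt, "variant_table"))
  ctx <- vt$context
  if (anyNA(ctx$homopolymer_len) || anyNA(ctx$dinucleotide_len) ||
      anyNA(ctx$in_annotated_repeat))
    stop("missing context feature values: homopolymer_len, ",
         "dinucleotide_len and in_annotated_repeat must be populated")
  n <- length(vt$sites)
  fire <- list(
    i   = !is.na(ctx$simple_repeat_period) &
            ctx$simple_repeat_period < params$max_simple_repeat_period,
    ii  = ctx$homopolymer_len > params$max_homopolymer,
    iii = ctx$dinucleotide_len > params$max_dinucleotide,
    iv  = vt$mq < params$min_mq,
    v   = if (is.null(repeats)) ctx$in_annotated_repeat
          else overlapsAny(vt$sites, repeats)
  )
  calls <- call_genotypes(vt, gt_params)
  fire$vi <- .het_cluster_hits(vt, calls, params$het_cluster_max,
                               params$het_cluster_span)
  reasons <- lapply(seq_len(n), function(i)
    names(fire)[vapply(fire, `[`, logical(1), i)])
  removed <- lengths(reasons) > 0
  status <- ifelse(removed,
                   vapply(reasons, paste, character(1), collapse = ","),
                   "pass")
  subset_vt <- function(keep) {
    variant_table(vt$sites[keep], vt$ref_reads[keep, , drop = FALSE],
                  vt$alt_reads[keep, , drop = FALSE], vt$mq[keep],
                  vt$context[keep, , drop = FALSE])
  }
  list(passed = subset_vt(!removed), removed = subset_vt(removed),
       status = status, reasons = reasons)
}

#' Variants shared by all cases and absent from all controls
#'
#' A variant qualifies when every case sample carries a non-reference
#' call (`"het"` or `"hom"`) and every control sample is callable and
#' reference (`"none"`).
#'
#' @param vt a [variant_table()]
#' @param cases,controls character vectors of sample names
#' @param params a [genotype_params()]
#' @return logical vector over sites; `which()` it or subset `vt$sites`
#' @export
shared_variants <- function(vt, cases, controls,
                            params = genotype_params()) {
  stopifnot(length(cases) >= 1, length(controls) >= 1,
            all(c(cases, controls) %in% vt$samples))
  calls <- call_genotypes(vt, params)
  nonref <- !is.na(calls) & calls %in% c("het", "hom")
  refcall <- !is.na(calls) & calls == "none"
  rowSums(nonref[, cases, drop = FALSE]) == length(cases) &
    rowSums(refcall[, controls, drop = FALSE]) == length(controls)
}

#' Annotate intervals with SNP content and SV proximity
#'
#' @param intervals GRanges (e.g. DMRs)
#' @param snps GRanges of SNP sites (may be empty)
#' @param svs GRanges of structural variants (may be empty)
#' @param window_bp strict distance threshold for the proximity flag
#'   (default 1000: flagged when nearest SV is < 1 kb away; an
#'   overlapping SV has distance 0)
#' @return `intervals` with added mcols `contains_snp` (logical),
#'   `sv_distance` (bp gap to nearest SV; 0 if overlapping; NA if no
#'   SV on any chromosome) and `sv_near` (logical,
#'   `sv_distance < window_bp`)
#' @export
variant_region_proximity <- function(intervals, snps, svs,
                                     window_bp = 1000) {
  out <- intervals
  mcols(out)$contains_snp <- if (length(snps)) overlapsAny(out, snps)
    else rep(FALSE, length(out))
  dist <- rep(NA_real_, length(out))
  if (length(svs)) {
    hits <- distanceToNearest(out, svs)
    dist[queryHits(hits)] <- mcols(hits)$distance
  }
  mcols(out)$sv_distance <- dist
  mcols(out)$sv_near <- !is.na(dist) & dist < window_bp
  out
}
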