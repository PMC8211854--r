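#' Classify intervals by genomic context
#'
#' Assigns each query interval exactly one category under the chosen
#' scheme, by fixed whole-interval precedence (an interval overlapping
#' several categories takes the highest-precedence one):
#'
#'  * `"genic"`: exon > intron > promoter (1 kb upstream of the TSS,
#'    strand-aware) > intergenic.  Introns are the within-gene
#'    complement of the exons.
#'  * `"repeat"`: LTR > LINE > SINE > other_repeat > unique.
#'  * `"cgi"`: island > shore (within 2 kb of an island edge) > shelf
#'    (2-4 kb) > open_sea.  Shores and shelves are symmetric bands
#'    around islands and never overlap them.
#'
#' @param intervals GRanges to classify
#' @param annotations list as from [simulate_annotations()]; the genic
#'   scheme needs `genes`, `exons`, `tss`, the repeat scheme `repeats`
#'   (mcols `class`), the cgi scheme `cgis`
#' @param scheme one of `"genic"`, `"repeat"`, `"cgi"`
#' @param promoter_bp promoter extent upstream of the TSS (genic
#'   scheme)
#' @param shore_bp,shelf_bp CGI band edges in bp from the island
#' @return object of class `context_distribution`: list with
#'   `assignment` (factor per interval), `counts`, `fractions`,
#'   `scheme`
#' @export
classify_intervals <- function(intervals, annotations,
                               scheme = c("genic", "repeat", "cgi"),
                               promoter_bp = 1000L,
                               shore_bp = 2000L, shelf_bp = 4000L) {
  scheme <- match.arg(scheme)
  n <- length(intervals)
  if (scheme == "genic") {
    genes <- annotations$genes
    exons <- annotations$exons
    tss <- annotations$tss
    introns <- setdiff(reduce(genes, ignore.strand = TRUE),
                       reduce(exons, ignore.strand = TRUE))
    promoters <- trim(promoters(tss, upstream = promoter_bp,
                                downstream = 0L))
    cats <- list(exon = exons, intron = introns, promoter = promoters)
    levels <- c("exon", "intron", "promoter", "intergenic")
    fallback <- "intergenic"
  } else if (scheme == "repeat") {
    reps <- annotations$repeats
    cls <- mcols(reps)$class
    cats <- list(LTR = reps[cls == "LTR"], LINE = reps[cls == "LINE"],
                 SINE = reps[cls == "SINE"],
                 other_repeat = reps[!cls %in% c("LTR", "LINE", "SINE")])
    levels <- c("LTR", "LINE", "SINE", "other_repeat", "unique")
    fallback <- "unique"
  } else {
    cgis <- reduce(annotations$cgis, ignore.strand = TRUE)
    shores <- setdiff(suppressWarnings(trim(cgis + shore_bp)), cgis)
    shelves <- setdiff(suppressWarnings(trim(cgis + shelf_bp)),
                       suppressWarnings(trim(cgis + shore_bp)))
    cats <- list(island = cgis, shore = shores, shelf = shelves)
    levels <- c("island", "shore", "shelf", "open_sea")
    fallback <- "open_sea"
  }
  assignment <- rep(fallback, n)
  for (nm in rev(names(cats))) {  # apply lowest precedence first
    hit <- overlapsAny(intervals, cats[[nm]], minoverlap = 1L,
                       ignore.strand = TRUE)
    assignment[hit] <- nm
  }
  assignment <- factor(assignment, levels = levels)
  counts <- table(assignment)
  structure(list(assignment = assignment,
                 counts = as.vector(counts),
                 categories = names(counts),
                 fractions = if (n > 0) as.vector(counts) / n
                             else rep(NA_real_, length(counts)),
                 n = n, scheme = scheme),
            class = "context_distribution")
}

#' @export
print.context_distribution <- function(x, ...) {
  cat("context_distribution (", x$scheme, " scheme, n = ", x$n, ")\n",
      sep = "")
  print(data.frame(category = x$categories, count = x$counts,
                   fraction = round(x$fractions, 4)))
  invisible(x)
}

#' Chi-squared goodness-of-fit against a background distribution
#'
#' Expected counts are the background fractions scaled to the query
#' total; the statistic is `sum((O - E)^2 / E)` with `df = k - 1` and
#' an upper-tail p-value.  Categories with zero background fraction
#' are dropped (they carry no expectation); any expected count below 1
#' triggers a warning.
#'
#' @param query,background `context_distribution`s on the same scheme
#' @return list with `statistic`, `df`, `p.value`, `observed`,
#'   `expected`
#' @export
chisq_vs_background <- function(query, background) {
  stopifnot(inherits(query, "context_distribution"),
            inherits(background, "context_distribution"),
            identical(query$categories, background$categories))
  keep <- background$fractions > 0
  if (any(query$counts[!keep] > 0))
    stop("query has observations in categories absent from background")
  O <- query$counts[keep]
  E <- background$fractions[keep] * query$n
  if (length(O) < 2L)
    stop("chi-squared test is degenerate with a single category (df 0)")
  if (any(E < 1))
    warning("expected count below 1 in ", sum(E < 1), " cell(s)")
  stat <- sum((O - E)^2 / E)
  df <- length(O) - 1L
  list(statistic = stat, df = df,
       p.value = pchisq(stat, df, lower.tail = FALSE),
       observed = O, expected = E)
}

#' Signed distance from intervals to transcription start sites
#'
#' For each interval, the closest of its two boundary coordinates to
#' the (nearest, or supplied) TSS, minus the TSS coordinate, plus 1.
#' For minus-strand TSS the sign is mirrored so that positive
#' distances are always downstream of transcription.  Intervals
#' containing the TSS are flagged `overlapping`; the closest-boundary
#' rule still applies.
#'
#' @param intervals GRanges
#' @param tss GRanges of TSS points (width 1, strand used for
#'   orientation); the nearest TSS on the same chromosome is chosen
#'   per interval
#' @return data.frame with `tss_index`, `distance` (NA when no TSS
#'   shares the chromosome) and `overlapping`
#' @export
tss_distance <- function(intervals, tss) {
  n <- length(intervals)
  out <- data.frame(tss_index = rep(NA_integer_, n),
                    distance = rep(NA_real_, n),
                    overlapping = rep(FALSE, n))
  if (length(tss) == 0L || n == 0L) return(out)
  hits <- suppressWarnings(
    nearest(intervals, tss, select = "all", ignore.strand = TRUE))
  ## nearest() never pairs across chromosomes; keep the first hit
  first <- !duplicated(queryHits(hits))
  qi <- queryHits(hits)[first]; ti <- subjectHits(hits)[first]
  s <- start(intervals)[qi]; e <- end(intervals)[qi]
  tpos <- start(tss)[ti]
  closest <- ifelse(abs(s - tpos) <= abs(e - tpos), s, e)
  d <- closest - tpos + 1
  minus <- as.logical(strand(tss)[ti] == "-")
  d[minus] <- tpos[minus] - closest[minus] + 1
  out$tss_index[qi] <- ti
  out$distance[qi] <- d
  out$overlapping[qi] <- s <= tpos & tpos <= e
  out
}

#' Overlap of DMRs with enhancer elements
#'
#' @param dmrs GRanges
#' @param enhancers GRanges (optional mcols `enhancer_id`)
#' @return data.frame, one row per DMR: `n_enhancers` and
#'   comma-separated `enhancer_ids`; total overlapping DMRs in
#'   `attr(, "n_overlapping")`
#' @export
enhancer_overlap <- function(dmrs, enhancers) {
  ids <- if ("enhancer_id" %in% names(mcols(enhancers)))
    mcols(enhancers)$enhancer_id else paste0("enh", seq_along(enhancers))
  hits <- findOverlaps(dmrs, enhancers, minoverlap = 1L,
                       ignore.strand = TRUE)
  by_dmr <- split(ids[subjectHits(hits)],
                  factor(queryHits(hits), levels = seq_along(dmrs)))
  out <- data.frame(
    n_enhancers = lengths(by_dmr),
    enhancer_ids = vapply(by_dmr, paste, character(1), collapse = ","))
  rownames(out) <- NULL
  attr(out, "n_overlapping") <- sum(out$n_enhancers > 0)
  out
}
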