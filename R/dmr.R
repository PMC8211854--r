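#' DMR-calling parameters
#'
#' A window is flagged when its group-mean RPKM ratio is at least
#' `fold_threshold` (or at most its reciprocal) and its two-group test
#' p-value is below `p_threshold`; adjacent flagged windows of the
#' same direction are merged.  No multiple-testing correction is
#' applied: the raw per-window p-value is thresholded, matching the
#' window-based convention this pipeline reproduces.
#'
#' @param fold_threshold minimum group-mean RPKM fold change (> 1)
#' @param p_threshold per-window p-value threshold, in (0, 1)
#' @param min_locus_bp with `strict_length = TRUE`, merged loci must be
#'   strictly longer than this to be reported (drops single-window
#'   DMRs at the 500 bp default); the default keeps them
#' @param strict_length apply the strict length cut?
#' @param pseudo pseudo-RPKM added to both group means before the fold
#'   ratio, guarding against division by zero
#' @param dispersion_mode `"moment"` estimates a common NB dispersion
#'   from the data; `"fixed"` uses `dispersion` as given
#' @param dispersion fixed dispersion value (used when
#'   `dispersion_mode = "fixed"`); 0 gives the Poisson/conditional
#'   binomial exact test
#' @return list of class `dmr_params`
#' @export
dmr_params <- function(fold_threshold = 1.5, p_threshold = 0.01,
                       min_locus_bp = 500L, strict_length = FALSE,
                       pseudo = 0.1,
                       dispersion_mode = c("moment", "fixed"),
                       dispersion = 0) {
  stopifnot(fold_threshold > 1, p_threshold > 0, p_threshold < 1,
            pseudo >= 0, dispersion >= 0)
  structure(list(fold_threshold = fold_threshold,
                 p_threshold = p_threshold,
                 min_locus_bp = as.integer(min_locus_bp),
                 strict_length = strict_length, pseudo = pseudo,
                 dispersion_mode = match.arg(dispersion_mode),
                 dispersion = dispersion),
            class = "dmr_params")
}

#' Moment estimate of the common negative-binomial dispersion
#'
#' Counts are scaled to a common library size; for each window the
#' within-group pooled variance `v` and overall mean `m` give a local
#' estimate `(v - m) / m^2`.  The median over informative windows
#' (mean >= `min_mean`), floored at zero, is returned.  The median is
#' robust to a minority of genuinely differential windows.
#'
#' @param se SummarizedExperiment with assay `counts`, colData `group`
#'   and `lib_size`
#' @param windows optional logical/integer subset of windows (e.g. the
#'   background methylome) used for estimation
#' @param min_mean smallest scaled mean for a window to contribute
#' @return non-negative scalar dispersion
#' @export
estimate_dispersion <- function(se, windows = NULL, min_mean = 1) {
  counts <- assay(se, "counts")
  if (!is.null(windows)) counts <- counts[windows, , drop = FALSE]
  lib <- colData(se)$lib_size
  groups <- colData(se)$group
  y <- sweep(counts, 2L, mean(lib) / lib, `*`)
  m <- rowMeans(y)
  resid2 <- matrix(0, nrow(y), ncol(y))
  for (g in unique(groups)) {
    j <- groups == g
    resid2[, j] <- (y[, j, drop = FALSE] -
                      rowMeans(y[, j, drop = FALSE]))^2
  }
  v <- rowSums(resid2) / (ncol(y) - length(unique(groups)))
  ok <- m >= min_mean
  if (!any(ok)) return(0)
  ## ratio-of-sums moment estimator: Sum(v - m) / Sum(m^2).  More
  ## stable than a per-window median and far less biased at these
  ## replicate counts; a small planted-DMR fraction perturbs it little
  ## because within-group variances are used.
  max(0, sum(v[ok] - m[ok]) / sum(m[ok]^2))
}

## Exact two-group test on group sums, conditional on the total.
## Under the null the two group sums are NB (or Poisson when phi = 0)
## with means proportional to the group library sizes; the two-sided
## p-value sums the conditional probabilities of all splits at most as
## likely as the observed one (binom.test convention, relative
## tolerance 1 + 1e-7).
.exact_split_test <- function(sA, sB, qA, phiA, phiB) {
  T <- sA + sB
  if (T == 0) return(1)
  k <- 0:T
  if (phiA == 0 && phiB == 0) {
    logw <- dbinom(k, T, qA, log = TRUE)
  } else {
    muA <- T * qA; muB <- T * (1 - qA)
    la <- if (phiA == 0) dpois(k, muA, log = TRUE)
          else dnbinom(k, size = 1 / phiA, mu = muA, log = TRUE)
    lb <- if (phiB == 0) dpois(T - k, muB, log = TRUE)
          else dnbinom(T - k, size = 1 / phiB, mu = muB, log = TRUE)
    logw <- la + lb
  }
  logw <- logw - max(logw)
  w <- exp(logw)
  pobs <- w[sA + 1L]
  sum(w[w <= pobs * (1 + 1e-7)]) / sum(w)
}

#' Per-window two-group exact test
#'
#' Collapses replicates to library-size-weighted group sums and
#' applies an exact negative-binomial split test conditional on the
#' window total.  The group-sum dispersion is derived from the common
#' per-replicate dispersion `phi` by moment matching
#' (`phi_g = phi * sum(L_r^2) / (sum L_r)^2` over the group's library
#' sizes, i.e. `phi / n` for equal libraries); `phi = 0` reduces to
#' the conditional binomial (Poisson) exact test.
#'
#' @param se SummarizedExperiment with assay `counts`, colData `group`
#'   (exactly two levels) and `lib_size`
#' @param params a [dmr_params()]; controls how the dispersion is
#'   obtained
#' @param background optional logical mask of windows used for the
#'   moment dispersion estimate
#' @return numeric vector of two-sided p-values, one per window, with
#'   the dispersion used in `attr(, "dispersion")`
#' @export
window_test <- function(se, params = dmr_params(), background = NULL) {
  groups <- colData(se)$group
  lev <- unique(groups)
  stopifnot(length(lev) == 2L)
  if (any(table(groups) < 2L))
    stop("need at least 2 replicates per group")
  counts <- assay(se, "counts")
  if (any(counts < 0)) stop("counts must be non-negative")
  lib <- colData(se)$lib_size
  LA <- sum(lib[groups == lev[1]]); LB <- sum(lib[groups == lev[2]])
  if (LA <= 0 || LB <= 0)
    stop("a group has zero total library size")
  phi <- switch(params$dispersion_mode,
                moment = estimate_dispersion(se, windows = background),
                fixed = params$dispersion)
  phiA <- phi * sum(lib[groups == lev[1]]^2) / LA^2
  phiB <- phi * sum(lib[groups == lev[2]]^2) / LB^2
  sA <- rowSums(counts[, groups == lev[1], drop = FALSE])
  sB <- rowSums(counts[, groups == lev[2], drop = FALSE])
  qA <- LA / (LA + LB)
  p <- vapply(seq_along(sA), function(i)
    .exact_split_test(sA[i], sB[i], qA, phiA, phiB), numeric(1))
  attr(p, "dispersion") <- phi
  p
}

#' Flag differential windows by fold change and p-value
#'
#' With group means `mA` (control, first group level) and `mB` (case):
#' hyper when `(mB + pseudo) / (mA + pseudo) >= fold_threshold` and
#' `p < p_threshold`; hypo when the ratio is at most
#' `1 / fold_threshold` with the same p cut.
#'
#' @param se SummarizedExperiment with assay `rpkm` and colData `group`
#' @param p per-window p-values from [window_test()]
#' @param params a [dmr_params()]
#' @return GRanges of flagged windows with mcols `direction`
#'   (`"hyper"`/`"hypo"`), `fold` (pseudo-stabilised case/control RPKM
#'   ratio) and `p`
#' @export
call_windows <- function(se, p, params = dmr_params()) {
  stopifnot(length(p) == nrow(se))
  groups <- colData(se)$group
  lev <- unique(groups)
  rpkm <- assay(se, "rpkm")
  mA <- rowMeans(rpkm[, groups == lev[1], drop = FALSE])
  mB <- rowMeans(rpkm[, groups == lev[2], drop = FALSE])
  ratio <- (mB + params$pseudo) / (mA + params$pseudo)
  sig <- p < params$p_threshold
  hyper <- sig & ratio >= params$fold_threshold
  hypo <- sig & ratio <= 1 / params$fold_threshold
  idx <- which(hyper | hypo)
  out <- rowRanges(se)[idx]
  mcols(out) <- S4Vectors::DataFrame(
    direction = ifelse(hyper[idx], "hyper", "hypo"),
    fold = ratio[idx], p = p[idx])
  out
}

#' Merge adjacent flagged windows into DMRs
#'
#' Maximal runs of overlapping or book-ended flagged windows of the
#' same direction become one DMR carrying the member count, the
#' minimum member p-value and the length-weighted mean fold.
#' Idempotent: merging a merged set returns it unchanged.
#'
#' @param flagged GRanges from [call_windows()] (mcols `direction`,
#'   `fold`, `p`; `n_windows` honoured if already present)
#' @return GRanges of DMR records with mcols `direction`, `fold`, `p`,
#'   `n_windows`, sorted
#' @export
merge_adjacent <- function(flagged) {
  if (length(flagged) == 0L) {
    mcols(flagged) <- S4Vectors::DataFrame(direction = character(),
                                           fold = numeric(), p = numeric(),
                                           n_windows = integer())
    return(flagged)
  }
  nw <- if ("n_windows" %in% names(mcols(flagged)))
    mcols(flagged)$n_windows else rep(1L, length(flagged))
  pieces <- lapply(split(seq_along(flagged), mcols(flagged)$direction),
                   function(idx) {
    gr <- flagged[idx]
    nw <- nw[idx]
    red <- reduce(gr, min.gapwidth = 1L, with.revmap = TRUE,
                  ignore.strand = TRUE)
    rev <- mcols(red)$revmap
    mcols(red) <- S4Vectors::DataFrame(
      direction = rep(mcols(gr)$direction[1], length(red)),
      fold = vapply(rev, function(j)
        sum(mcols(gr)$fold[j] * width(gr)[j]) / sum(width(gr)[j]),
        numeric(1)),
      p = vapply(rev, function(j) min(mcols(gr)$p[j]), numeric(1)),
      n_windows = vapply(rev, function(j) sum(nw[j]), integer(1)))
    red
  })
  out <- sort(do.call(c, unname(pieces)), ignore.strand = TRUE)
  out
}

#' Drop DMRs below the strict length threshold
#'
#' @param dmrs GRanges of DMR records
#' @param params a [dmr_params()]; only acts when
#'   `params$strict_length` is TRUE (keeps loci strictly longer than
#'   `min_locus_bp`)
#' @return filtered GRanges
#' @export
filter_dmr_length <- function(dmrs, params = dmr_params()) {
  if (!params$strict_length) return(dmrs)
  dmrs[width(dmrs) > params$min_locus_bp]
}

#' Remove DMRs overlapping a mask region
#'
#' Any DMR overlapping the mask by at least 1 bp is removed (a DMR
#' merely book-ended with the mask is kept).  The removed count is
#' reported via `attr(, "removed")`.
#'
#' @param dmrs GRanges of DMR records
#' @param mask GRanges mask (e.g. a confounded 20 Mb strain region)
#' @return filtered GRanges
#' @export
mask_dmrs <- function(dmrs, mask) {
  drop <- overlapsAny(dmrs, mask, minoverlap = 1L)
  out <- dmrs[!drop]
  attr(out, "removed") <- sum(drop)
  out
}

#' Concatenate DMR lists without deduplication
#'
#' @param ... GRanges of DMR records (or a single list of them)
#' @return order-stable concatenation; length is the sum of the input
#'   lengths
#' @export
combine_lists <- function(...) {
  lists <- list(...)
  if (length(lists) == 1L && is.list(lists[[1]]) &&
      !is(lists[[1]], "GRanges"))
    lists <- lists[[1]]
  if (length(lists) == 0L) return(GRanges())
  keep <- Reduce(intersect, lapply(lists, function(x) names(mcols(x))))
  lists <- lapply(lists, function(x) {
    mcols(x) <- mcols(x)[, keep, drop = FALSE]
    x
  })
  ## inputs may come from different chromosome subsets
  suppressWarnings(do.call(c, unname(lists)))
}

#' Overlap-based intersection of DMR sets
#'
#' Regions from all lists are pooled and merged into loci; each locus
#' is labelled with the subset of input lists it overlaps by at least
#' 1 bp.  Returns Venn-style partition counts over loci plus the
#' per-locus membership.
#'
#' @param dmr_lists named list of GRanges
#' @return list with `loci` (GRanges, mcols one logical column per
#'   input list and `pattern`), and `counts` (table of pattern ->
#'   locus count)
#' @export
intersect_sets <- function(dmr_lists) {
  stopifnot(is.list(dmr_lists), length(dmr_lists) >= 2)
  if (is.null(names(dmr_lists)))
    names(dmr_lists) <- paste0("set", seq_along(dmr_lists))
  pooled <- reduce(do.call(c, unname(lapply(dmr_lists, granges))),
                   ignore.strand = TRUE)
  member <- vapply(dmr_lists, function(gr)
    overlapsAny(pooled, gr, minoverlap = 1L), logical(length(pooled)))
  member <- matrix(member, nrow = length(pooled),
                   dimnames = list(NULL, names(dmr_lists)))
  pattern <- apply(member, 1L, function(row)
    paste(names(dmr_lists)[row], collapse = "&"))
  mcols(pooled) <- S4Vectors::DataFrame(member, pattern = pattern)
  list(loci = pooled, counts = table(pattern))
}

#' Write DMR records as BED6+
#'
#' Columns: chrom, start, end, name (DMR id), score (-10 log10 p,
#' capped at 1000), strand (`.`), then fold, direction, n_windows.
#'
#' @param dmrs GRanges of DMR records
#' @param path output path
#' @return `path` invisibly
#' @export
write_dmr_bed <- function(dmrs, path) {
  score <- pmin(1000, round(-10 * log10(pmax(mcols(dmrs)$p, 1e-100)), 2))
  df <- data.frame(chrom = as.character(seqnames(dmrs)),
                   start = start(dmrs) - 1L, end = end(dmrs),
                   name = paste0("DMR", seq_along(dmrs)),
                   score = score, strand = ".",
                   fold = round(mcols(dmrs)$fold, 4),
                   direction = mcols(dmrs)$direction,
                   n_windows = mcols(dmrs)$n_windows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
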