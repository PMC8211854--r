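#' Scaled-region profile parameters
#'
#' Defaults match the common meta-region layout: region bodies
#' rescaled to 3 kb, 6 kb unscaled flanks either side, 200 bp bins —
#' a 75-column matrix (30 upstream + 15 body + 30 downstream bins).
#'
#' @param body_bp scaled body width (divisible by `bin_bp`)
#' @param flank_bp flank width either side (divisible by `bin_bp`)
#' @param bin_bp bin width
#' @param seed integer seed used when drawing shuffled baselines
#' @return list of class `profile_params`
#' @export
profile_params <- function(body_bp = 3000L, flank_bp = 6000L,
                           bin_bp = 200L, seed = 1L) {
  stopifnot(body_bp > 0, flank_bp >= 0, bin_bp > 0)
  if (body_bp %% bin_bp != 0 || flank_bp %% bin_bp != 0)
    stop("body_bp and flank_bp must be divisible by bin_bp")
  structure(list(body_bp = as.integer(body_bp),
                 flank_bp = as.integer(flank_bp),
                 bin_bp = as.integer(bin_bp), seed = as.integer(seed)),
            class = "profile_params")
}

#' Chromosome-matched shuffled baseline regions
#'
#' Places one baseline region per input region, of identical length
#' and on the same chromosome, uniformly over the free space outside
#' `exclusions` and previously placed baselines (pairwise disjoint).
#' Mirrors `bedtools shuffle -chrom -noOverlapping -excl`.
#'
#' @param regions GRanges input regions
#' @param genome a `synthetic_genome`
#' @param exclusions optional GRanges mask
#' @param seed integer seed
#' @return GRanges parallel to `regions` (same order, lengths and
#'   chromosomes)
#' @export
shuffle_baseline <- function(regions, genome, exclusions = NULL,
                             seed = 1L) {
  place_disjoint_regions(width(regions), genome, exclusions = exclusions,
                         chroms = as.character(seqnames(regions)),
                         seed = seed)
}

## mean signal over [lo, hi] of a per-bp numeric vector indexed from
## `offset` (positions outside [offset, offset + length - 1] are NA)
.bin_means <- function(vals, offset, lo, hi, bin) {
  edges <- seq(lo, hi + 1L, by = bin)
  vapply(seq_len(length(edges) - 1L), function(j) {
    a <- edges[j]; b <- edges[j + 1L] - 1L
    ia <- a - offset + 1L; ib <- b - offset + 1L
    sel <- max(ia, 1L):min(ib, length(vals))
    if (sel[1] > sel[length(sel)] || ia > length(vals) || ib < 1L)
      return(NA_real_)
    v <- vals[sel]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

## areal rescaling: mean-preserving projection of a length-L per-bp
## signal onto nbins equal destination bins
.scale_body <- function(vals, nbins) {
  L <- length(vals)
  cs <- c(0, cumsum(ifelse(is.na(vals), 0, vals)))
  na <- c(0, cumsum(is.na(vals)))
  interp <- function(x, v) {
    ## linear interpolation of the cumulative sum at fractional bp
    i <- floor(x)
    frac <- x - i
    v[i + 1L] + frac * (v[pmin(i + 2L, length(v))] - v[i + 1L])
  }
  edges <- L * (0:nbins) / nbins
  tot <- interp(edges[-1], cs) - interp(edges[-(nbins + 1L)], cs)
  nas <- interp(edges[-1], na) - interp(edges[-(nbins + 1L)], na)
  wid <- diff(edges)
  out <- tot / (wid - nas)
  out[wid - nas <= 0] <- NA_real_
  out
}

#' Scaled-region signal matrix
#'
#' For each region: the upstream flank (unscaled), the body linearly
#' rescaled to `body_bp`, and the downstream flank, all averaged into
#' `bin_bp` bins.  Body rescaling is areal (length-weighted), so the
#' mean over the scaled body equals the mean of the raw body signal.
#' Bins outside chromosome bounds (or with no signal coverage) are
#' `NA`, distinct from a true 0.  Regions carrying strand are oriented
#' 5'→3'; unstranded regions are taken in plus orientation.
#'
#' @param regions GRanges
#' @param signal GRanges with a numeric `score` (bedGraph-style; bases
#'   not covered by any interval are treated as NA unless
#'   `missing_as_zero`)
#' @param params a [profile_params()]
#' @param missing_as_zero treat uncovered bases as 0 signal (bigWig
#'   converters often omit zero runs); default TRUE
#' @param genome optional `synthetic_genome`; when given, chromosome
#'   bounds (rather than the track's extent) decide which flank bases
#'   are out of range
#' @return matrix (regions x bins) of class `profile_matrix` with
#'   attribute `bin_axis`
#' @export
profile_matrix <- function(regions, signal, params = profile_params(),
                           missing_as_zero = TRUE, genome = NULL) {
  nb_flank <- params$flank_bp %/% params$bin_bp
  nb_body <- params$body_bp %/% params$bin_bp
  width_total <- 2L * nb_flank + nb_body
  chroms <- unique(as.character(seqnames(signal)))
  cov <- coverage(signal, weight = mcols(signal)$score)
  covered <- coverage(signal)  # interval multiplicity; 0 = no data
  out <- matrix(NA_real_, nrow = length(regions), ncol = width_total)
  keep <- rep(TRUE, length(regions))
  for (i in seq_along(regions)) {
    ch <- as.character(seqnames(regions))[i]
    if (!ch %in% chroms) {
      warning("region ", i, " on chromosome ", ch,
              " absent from signal track; skipped")
      keep[i] <- FALSE
      next
    }
    rle <- cov[[ch]]
    clen <- if (!is.null(genome)) as.integer(genome$chrom_sizes[[ch]])
            else length(rle)
    s <- start(regions)[i]; e <- end(regions)[i]
    lo <- s - params$flank_bp; hi <- e + params$flank_bp
    grab <- function(a, b) {
      if (b < a) return(numeric(0))
      v <- rep(NA_real_, b - a + 1L)
      aa <- max(a, 1L); bb <- min(b, clen)
      if (aa <= bb) {
        vv <- rep(if (missing_as_zero) 0 else NA_real_, bb - aa + 1L)
        tt <- min(bb, length(rle))
        if (aa <= tt) {
          got <- as.numeric(window(rle, aa, tt))
          if (!missing_as_zero) {
            cv <- as.numeric(window(covered[[ch]], aa, tt))
            got[cv == 0] <- NA_real_
          }
          vv[seq_len(tt - aa + 1L)] <- got
        }
        v[(aa - a + 1L):(bb - a + 1L)] <- vv
      }
      v
    }
    up <- .bin_means(grab(lo, s - 1L), lo, lo, s - 1L, params$bin_bp)
    body <- .scale_body(grab(s, e), nb_body)
    down <- .bin_means(grab(e + 1L, hi), e + 1L, e + 1L, hi,
                       params$bin_bp)
    row <- c(up, body, down)
    if (as.character(strand(regions))[i] == "-") row <- rev(row)
    out[i, ] <- row
  }
  out <- out[keep, , drop = FALSE]
  colnames(out) <- c(paste0("up", seq_len(nb_flank)),
                     paste0("body", seq_len(nb_body)),
                     paste0("down", seq_len(nb_flank)))
  attr(out, "bin_axis") <- rep(c("upstream", "body", "downstream"),
                               c(nb_flank, nb_body, nb_flank))
  class(out) <- c("profile_matrix", class(out))
  out
}

#' Per-bin mean profile with standard errors
#'
#' Missing bins are excluded bin-wise; the contributing region count
#' is reported per bin.  A bin with no data at all has mean `NA`.
#'
#' @param pm a [profile_matrix()]
#' @return data.frame with `bin`, `section`, `mean`, `se`, `n`
#' @export
mean_profile <- function(pm) {
  stopifnot(nrow(pm) >= 1)
  n <- colSums(!is.na(pm))
  m <- colMeans(pm, na.rm = TRUE)
  m[n == 0] <- NA_real_
  s <- apply(pm, 2L, function(col) {
    k <- sum(!is.na(col))
    if (k >= 2) stats::sd(col, na.rm = TRUE) / sqrt(k) else NA_real_
  })
  data.frame(bin = seq_len(ncol(pm)),
             section = attr(pm, "bin_axis"),
             mean = unname(m), se = unname(s), n = unname(n))
}
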