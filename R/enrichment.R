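#' Enrichment-analysis parameters
#'
#' Defaults reproduce the standard random-proxy null: 10,000 random
#' regions of 500 bp drawn genome-wide (chromosome chosen
#' proportionally to allowed length), disjoint from each other,
#' outside the exclusion mask and inside chromosome bounds.
#'
#' @param n_random number of proxy regions
#' @param region_len proxy region length in bp
#' @param exclusions optional GRanges mask (e.g. the confounded
#'   strain region)
#' @param seed integer seed
#' @return list of class `enrichment_params`
#' @export
enrichment_params <- function(n_random = 10000L, region_len = 500L,
                              exclusions = NULL, seed = 1L) {
  stopifnot(n_random > 0, region_len > 0)
  structure(list(n_random = as.integer(n_random),
                 region_len = as.integer(region_len),
                 exclusions = exclusions, seed = as.integer(seed)),
            class = "enrichment_params")
}

#' Summarise query overlap with a reference region set
#'
#' A query interval counts as overlapping when it intersects any
#' reference interval by at least 1 bp.  The percentage is reported to
#' one decimal place.
#'
#' @param query GRanges (e.g. DMRs)
#' @param reference GRanges reference set
#' @return list of class `overlap_summary`: `n_total`,
#'   `n_overlapping`, `percent`
#' @export
overlap_summary <- function(query, reference) {
  k <- sum(overlapsAny(query, reference, minoverlap = 1L,
                       ignore.strand = TRUE))
  n <- length(query)
  structure(list(n_total = n, n_overlapping = k,
                 percent = round(100 * k / max(n, 1L), 1)),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat(x$n_overlapping, "of", x$n_total, "overlapping (",
      x$percent, "%)\n")
  invisible(x)
}

#' Summarise query overlap with both of two reference sets
#'
#' Counts query intervals overlapping set A and set B (each by at
#' least 1 bp, not necessarily at the same position).
#'
#' @param query GRanges
#' @param setA,setB GRanges reference sets
#' @return an `overlap_summary`
#' @export
joint_overlap <- function(query, setA, setB) {
  hit <- overlapsAny(query, setA, minoverlap = 1L, ignore.strand = TRUE) &
         overlapsAny(query, setB, minoverlap = 1L, ignore.strand = TRUE)
  structure(list(n_total = length(query), n_overlapping = sum(hit),
                 percent = round(100 * sum(hit) / max(length(query), 1L),
                                 1)),
            class = "overlap_summary")
}

#' Monte-Carlo expected overlap frequency with a reference set
#'
#' Draws `n_random` disjoint proxy regions of `region_len` bp
#' uniformly over the allowed genome and returns the fraction
#' overlapping the reference, with its binomial Monte-Carlo standard
#' error.  Seed-reproducible.
#'
#' @param genome a `synthetic_genome`
#' @param reference GRanges reference set
#' @param params an [enrichment_params()]
#' @return list with `expected_fraction`, `se`, `n_random`,
#'   `n_overlapping` and the proxy `regions`
#' @export
expected_overlap <- function(genome, reference,
                             params = enrichment_params()) {
  regions <- sample_disjoint_uniform(params$n_random, params$region_len,
                                     genome,
                                     exclusions = params$exclusions,
                                     seed = params$seed)
  k <- sum(overlapsAny(regions, reference, minoverlap = 1L,
                       ignore.strand = TRUE))
  f <- k / params$n_random
  list(expected_fraction = f,
       se = sqrt(f * (1 - f) / params$n_random),
       n_random = params$n_random, n_overlapping = k, regions = regions)
}

#' Exact two-sided binomial enrichment test
#'
#' Tests the observed overlap count `k` of `n` against the expected
#' probability `p0`, summing the probabilities of all outcomes at most
#' as likely as the observed one (minimum-likelihood two-sided
#' convention, relative tolerance 1 + 1e-7, as in
#' [stats::binom.test()]).  A Wilson score confidence interval for the
#' observed fraction is reported alongside.
#'
#' @param k observed overlap count
#' @param n number of queries
#' @param p0 expected overlap probability, in `[0, 1]`
#' @param conf_level Wilson interval coverage
#' @return list of class `enrichment_result`: `observed_fraction`,
#'   `expected_fraction`, `p.value`, `conf_int` (Wilson), `k`, `n`
#' @export
binomial_enrichment <- function(k, n, p0, conf_level = 0.95) {
  stopifnot(k >= 0, k <= n, n >= 1, p0 >= 0, p0 <= 1)
  if (p0 == 0) {
    p <- if (k == 0) 1 else 0
  } else if (p0 == 1) {
    p <- if (k == n) 1 else 0
  } else {
    d <- dbinom(0:n, n, p0)
    p <- min(1, sum(d[d <= d[k + 1L] * (1 + 1e-7)]))
  }
  structure(list(observed_fraction = k / n, expected_fraction = p0,
                 p.value = p, conf_int = wilson_ci(k, n, conf_level),
                 k = k, n = n),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "observed %d/%d = %.4f vs expected %.4f; exact binomial p = %.3g\n",
    x$k, x$n, x$observed_fraction, x$expected_fraction, x$p.value))
  invisible(x)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param k successes, `n` trials, `conf_level` coverage
#' @param n number of trials
#' @param conf_level interval coverage (default 0.95)
#' @return length-2 numeric vector (lower, upper)
#' @export
wilson_ci <- function(k, n, conf_level = 0.95) {
  z <- qnorm(1 - (1 - conf_level) / 2)
  ph <- k / n
  den <- 1 + z^2 / n
  centre <- (ph + z^2 / (2 * n)) / den
  half <- z * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2)) / den
  c(max(0, centre - half), min(1, centre + half))
}

#' Table of overlap summaries against several reference sets
#'
#' Convenience wrapper producing one row per (query list, reference
#' set) pair, in the layout of a published DMR-overlap table.
#'
#' @param queries named list of GRanges query sets
#' @param references named list of GRanges reference sets; an entry
#'   may itself be a list of two GRanges for a joint-overlap row
#' @return data.frame with `query`, `reference`, `n`, `k`, `percent`
#' @export
overlap_table <- function(queries, references) {
  rows <- list()
  for (qn in names(queries)) {
    for (rn in names(references)) {
      ref <- references[[rn]]
      s <- if (is.list(ref) && !is(ref, "GRanges"))
        joint_overlap(queries[[qn]], ref[[1]], ref[[2]])
      else overlap_summary(queries[[qn]], ref)
      rows[[length(rows) + 1L]] <-
        data.frame(query = qn, reference = rn, n = s$n_total,
                   k = s$n_overlapping, percent = s$percent)
    }
  }
  do.call(rbind, rows)
}
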