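#' Parameters for the window-count simulator
#'
#' Defaults describe a realistic two-group MeDIP-seq design: 8
#' biological replicates per group, background windows at 10 RPKM,
#' negative-binomial overdispersion phi = 0.1, and library sizes of
#' 15-30 million mapped fragments per replicate (at most 2-fold apart,
#' so RPKM normalisation is exercised).
#'
#' @param n_rep_a,n_rep_b replicates in group A (control) and group B
#'   (case)
#' @param mean_rpkm background mean methylation signal in RPKM
#' @param dispersion negative-binomial dispersion phi >= 0; the count
#'   variance is `m + phi * m^2`, so `phi = 0` degenerates to Poisson
#' @param planted_fraction fraction of windows planted as true DMRs,
#'   in `[0, 1)`
#' @param fold_changes positive fold changes sampled (with replacement)
#'   for planted windows; values < 1 plant hypomethylation
#' @param lib_sizes per-replicate library sizes (recycled to
#'   `n_rep_a + n_rep_b`); `NULL` draws them uniformly in
#'   `[1.5e7, 3e7]` from the simulation seed
#' @param seed integer seed
#' @return a list of class `simulation_params`
#' @export
simulation_params <- function(n_rep_a = 8L, n_rep_b = 8L, mean_rpkm = 10,
                              dispersion = 0.1, planted_fraction = 0,
                              fold_changes = 3, lib_sizes = NULL,
                              seed = 1L) {
  stopifnot(n_rep_a >= 1, n_rep_b >= 1, mean_rpkm >= 0)
  if (dispersion < 0) stop("dispersion must be >= 0")
  if (any(fold_changes <= 0)) stop("fold_changes must all be > 0")
  if (planted_fraction < 0 || planted_fraction >= 1)
    stop("planted_fraction must lie in [0, 1)")
  structure(list(n_rep_a = as.integer(n_rep_a), n_rep_b = as.integer(n_rep_b),
                 mean_rpkm = mean_rpkm, dispersion = dispersion,
                 planted_fraction = planted_fraction,
                 fold_changes = fold_changes, lib_sizes = lib_sizes,
                 seed = as.integer(seed)),
            class = "simulation_params")
}

## NB draw with variance m + phi m^2; phi = 0 is Poisson.
rnbinom_phi <- function(n, mu, phi) {
  if (phi == 0) rpois(n, mu) else rnbinom(n, mu = mu, size = 1 / phi)
}

#' Simulate a replicate window-count matrix with planted DMRs
#'
#' Tiles the genome at `ws` bp, then draws per-window fragment counts
#' for each replicate from a negative-binomial with mean
#' `mean_rpkm * width/1000 * lib_size/1e6` (i.e. constant RPKM).
#' A fraction of windows is planted as true DMRs: their group-B mean is
#' multiplied by a fold change sampled from `params$fold_changes`
#' (direction `hyper` for fold > 1, `hypo` for fold < 1).  The planted
#' truth is returned alongside the counts.
#'
#' @param genome a `synthetic_genome`
#' @param params a `simulation_params`
#' @param ws window size in bp
#' @return list with elements
#'   * `se`: [SummarizedExperiment::SummarizedExperiment] with assay
#'     `counts` (windows x replicates), `rowRanges` the window tiling,
#'     and `colData` columns `group` ("A"/"B") and `lib_size`;
#'   * `truth`: data.frame with columns `window` (row index),
#'     `direction` ("hyper"/"hypo") and `fold`.
#' @export
simulate_window_counts <- function(genome, params = simulation_params(),
                                   ws = 500L) {
  stopifnot(inherits(params, "simulation_params"))
  if (params$dispersion < 0) stop("dispersion must be >= 0")
  windows <- genome_windows(genome, ws)
  nw <- length(windows)
  nrep <- params$n_rep_a + params$n_rep_b
  groups <- rep(c("A", "B"), c(params$n_rep_a, params$n_rep_b))

  withr::with_seed(params$seed, {
    lib_sizes <- params$lib_sizes
    if (is.null(lib_sizes))
      lib_sizes <- round(runif(nrep, 1.5e7, 3e7))
    lib_sizes <- rep_len(lib_sizes, nrep)

    n_truth <- round(params$planted_fraction * nw)
    truth_idx <- if (n_truth > 0) sort(sample.int(nw, n_truth)) else integer()
    folds <- if (n_truth > 0)
      params$fold_changes[sample.int(length(params$fold_changes), n_truth,
                                     replace = TRUE)] else numeric()

    ## expected count for window i, replicate r:
    ##   rpkm * (width_i / 1000) * (lib_r / 1e6), times fold in group B
    base_rate <- params$mean_rpkm * width(windows) / 1000
    fold_vec <- rep(1, nw)
    fold_vec[truth_idx] <- folds
    counts <- matrix(0L, nrow = nw, ncol = nrep)
    for (r in seq_len(nrep)) {
      mu <- base_rate * lib_sizes[r] / 1e6
      if (groups[r] == "B") mu <- mu * fold_vec
      counts[, r] <- rnbinom_phi(nw, mu, params$dispersion)
    }
  })

  colnames(counts) <- paste0(tolower(groups), "_rep",
                             c(seq_len(params$n_rep_a),
                               seq_len(params$n_rep_b)))
  se <- SummarizedExperiment(
    assays = list(counts = counts),
    rowRanges = windows,
    colData = S4Vectors::DataFrame(group = groups, lib_size = lib_sizes,
                                   row.names = colnames(counts))
  )
  truth <- data.frame(
    window = truth_idx,
    direction = ifelse(folds > 1, "hyper", "hypo"),
    fold = folds
  )
  list(se = se, truth = truth)
}
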