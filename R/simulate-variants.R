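#' Simulate a variant table with known truth
#'
#' Generates SNV sites across the genome with per-sample ref/alt read
#' depths (~30x coverage), mapping qualities and repeat-context
#' features, mirroring a case/control whole-genome-sequencing design
#' (default 6 cases vs 2 controls).  Planted structure, all recorded
#' in the returned truth:
#'
#'  * `n_shared` variants heterozygous (alt fraction 0.5) in every
#'    case and reference in every control;
#'  * background variants private to random single samples;
#'  * a fraction of sites violating each hard-filter rule (simple
#'    repeat period < 9, homopolymer > 8, dinucleotide > 14, MQ < 40,
#'    annotated-repeat overlap);
#'  * one 4-het cluster within 10 kb in the first case sample,
#'    to be caught by the het-cluster rule.
#'
#' @param genome a `synthetic_genome`
#' @param n_cases,n_controls sample counts (>= 1)
#' @param seed integer seed
#' @param n_sites total background sites
#' @param n_shared planted case-shared variants
#' @param mean_depth mean sequencing depth per sample
#' @param fail_fraction fraction of background sites violating each of
#'   filter rules (i)-(v)
#' @param plant_het_cluster plant the rule-(vi) cluster?
#' @return list with `vt` (a [variant_table()]), `cases`, `controls`
#'   (sample names) and `truth` (data.frame per site: `planted`
#'   in `{"shared", "background", "het_cluster", "none"}`, expected
#'   reason codes `fails`, and `genotype` truth for sample 1)
#' @export
simulate_variants <- function(genome, n_cases = 6L, n_controls = 2L,
                              seed = 1L, n_sites = 300L, n_shared = 25L,
                              mean_depth = 30, fail_fraction = 0.03,
                              plant_het_cluster = TRUE) {
  stopifnot(n_cases >= 1, n_controls >= 1, n_sites >= n_shared)
  nsamp <- n_cases + n_controls
  samples <- c(paste0("case", seq_len(n_cases)),
               paste0("ctrl", seq_len(n_controls)))
  cluster_n <- if (plant_het_cluster) 4L else 0L
  n <- n_sites + cluster_n

  withr::with_seed(derive_seed(seed, 101L), {
    excl <- NULL
    if (cluster_n > 0) {
      ## reserve a window for the planted cluster so background sites
      ## cannot extend it
      chr1 <- names(genome$chrom_sizes)[1]
      base <- floor(genome$chrom_sizes[[1]] / 2)
      excl <- GRanges(chr1, IRanges(max(1L, base - 15000L),
                                    min(genome$chrom_sizes[[1]],
                                        base + 24000L)))
    }
    sites <- sort(place_disjoint_regions(rep(1L, n_sites), genome,
                                         exclusions = excl,
                                         seed = derive_seed(seed, 102L)))
    if (cluster_n > 0) {
      ## 4 extra sites spread over 9 kb on the first chromosome
      cl <- GRanges(chr1, IRanges(base + c(0L, 3000L, 6000L, 9000L),
                                  width = 1L))
      sites <- sort(c(sites, cl))
      cluster_idx <- which(overlapsAny(sites, cl))
    } else cluster_idx <- integer()

    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1L),
                  character(1))
    mcols(sites)$ref <- ref
    mcols(sites)$alt <- unname(alt)

    planted <- rep("background", n)
    bg_idx <- setdiff(seq_len(n), cluster_idx)
    ## shared sites are het in every case sample, so keep them >10 kb
    ## apart: at most one shared het can ever fall in a cluster window
    cand <- sample(bg_idx)
    shared_idx <- integer()
    for (i in cand) {
      if (length(shared_idx) == n_shared) break
      near <- shared_idx[as.character(seqnames(sites))[shared_idx] ==
                           as.character(seqnames(sites))[i]]
      if (!length(near) ||
          min(abs(start(sites)[near] - start(sites)[i])) > 10000)
        shared_idx <- c(shared_idx, i)
    }
    if (length(shared_idx) < n_shared)
      stop("genome too dense to place ", n_shared,
           " shared variants 10 kb apart")
    shared_idx <- sort(shared_idx)
    planted[shared_idx] <- "shared"
    planted[cluster_idx] <- "het_cluster"

    ## genotype truth matrix: "none", "het", "hom"
    gt <- matrix("none", n, nsamp, dimnames = list(NULL, samples))
    gt[shared_idx, seq_len(n_cases)] <- "het"
    for (i in setdiff(bg_idx, shared_idx)) {
      ## most background sites are private variants of one sample
      if (runif(1) < 0.7) {
        s <- sample.int(nsamp, 1L)
        gt[i, s] <- sample(c("het", "hom"), 1L)
      }
    }
    gt[cluster_idx, 1L] <- "het"

    ## demote accidental het clusters outside the planted one so the
    ## rule-(vi) truth is exactly the planted cluster; planted shared
    ## and cluster hets are protected (spacing above guarantees a
    ## demotable member exists)
    pos_all <- start(sites)
    chr_all <- as.character(seqnames(sites))
    protected <- c(shared_idx, cluster_idx)
    for (s in seq_len(nsamp)) {
      het_idx <- setdiff(which(gt[, s] == "het"), cluster_idx)
      for (ch in unique(chr_all[het_idx])) {
        idx <- het_idx[chr_all[het_idx] == ch]
        idx <- idx[order(pos_all[idx])]
        repeat {
          if (length(idx) < 4L) break
          spans <- pos_all[idx[-(1:3)]] -
            pos_all[idx[seq_len(length(idx) - 3L)]]
          bad <- which(spans < 10000)[1]
          if (is.na(bad)) break
          window <- idx[bad:(bad + 3L)]
          drop <- rev(setdiff(window, protected))[1]
          gt[drop, s] <- "none"
          idx <- idx[idx != drop]
        }
      }
    }

    ## read support is drawn from a binomial *conditioned on the
    ## genotype's calling band* (het: 0.30 <= f <= 0.90, hom:
    ## f > 0.90, none: f < 0.30), so planted genotypes are readable
    ## by construction and truth recovery downstream is exact
    depth <- matrix(pmax(10L, rpois(n * nsamp, mean_depth)), n, nsamp)
    frac <- matrix(0.005, n, nsamp)
    frac[gt == "het"] <- 0.5
    frac[gt == "hom"] <- 0.98
    lo <- matrix(0L, n, nsamp); hi <- depth
    lo[gt == "het"] <- ceiling(0.30 * depth[gt == "het"])
    hi[gt == "het"] <- floor(0.90 * depth[gt == "het"])
    lo[gt == "hom"] <- floor(0.90 * depth[gt == "hom"]) + 1L
    hi[gt == "none"] <- ceiling(0.30 * depth[gt == "none"]) - 1L
    plo <- stats::pbinom(lo - 1L, depth, frac)
    phi_band <- stats::pbinom(hi, depth, frac)
    u <- matrix(runif(n * nsamp), n, nsamp)
    alt_reads <- matrix(stats::qbinom(plo + u * (phi_band - plo),
                                      depth, frac), n, nsamp,
                        dimnames = list(NULL, samples))
    alt_reads <- pmax(lo, pmin(hi, alt_reads))  # guard qbinom edge cases
    dimnames(alt_reads) <- list(NULL, samples)
    ref_reads <- depth - alt_reads
    dimnames(ref_reads) <- dimnames(alt_reads)

    ## context features: clean by default, planted failures on
    ## background sites only (never on shared/cluster sites so that
    ## downstream recovery counts stay interpretable)
    ctx <- data.frame(simple_repeat_period = rep(NA_real_, n),
                      homopolymer_len = sample(1:4, n, replace = TRUE),
                      dinucleotide_len = sample(c(0, 2, 4, 6), n,
                                                replace = TRUE),
                      in_annotated_repeat = rep(FALSE, n))
    mq <- round(runif(n, 55, 60), 1)
    pool <- setdiff(bg_idx, shared_idx)
    nf <- max(1L, round(fail_fraction * n_sites))
    pick <- function(pool, k) if (length(pool)) sample(pool, min(k, length(pool))) else integer()
    idx_i <- pick(pool, nf);  pool <- setdiff(pool, idx_i)
    idx_ii <- pick(pool, nf); pool <- setdiff(pool, idx_ii)
    idx_iii <- pick(pool, nf); pool <- setdiff(pool, idx_iii)
    idx_iv <- pick(pool, nf); pool <- setdiff(pool, idx_iv)
    idx_v <- pick(pool, nf)
    ctx$simple_repeat_period[idx_i] <- sample(2:8, length(idx_i),
                                              replace = TRUE)
    ctx$homopolymer_len[idx_ii] <- sample(9:14, length(idx_ii),
                                          replace = TRUE)
    ctx$dinucleotide_len[idx_iii] <- sample(c(16, 18, 20), length(idx_iii),
                                            replace = TRUE)
    mq[idx_iv] <- round(runif(length(idx_iv), 10, 39), 1)
    ctx$in_annotated_repeat[idx_v] <- TRUE
  })

  vt <- variant_table(sites, ref_reads, alt_reads, mq, ctx)
  fails <- lapply(seq_len(n), function(i) {
    f <- character()
    if (i %in% idx_i) f <- c(f, "i")
    if (i %in% idx_ii) f <- c(f, "ii")
    if (i %in% idx_iii) f <- c(f, "iii")
    if (i %in% idx_iv) f <- c(f, "iv")
    if (i %in% idx_v) f <- c(f, "v")
    if (i %in% cluster_idx) f <- c(f, "vi")
    f
  })
  truth <- data.frame(planted = planted, genotype_sample1 = gt[, 1L])
  truth$fails <- fails
  truth$genotype <- I(split(gt, row(gt)))
  list(vt = vt, cases = samples[seq_len(n_cases)],
       controls = samples[n_cases + seq_len(n_controls)],
       truth = truth, genotype_truth = gt)
}
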