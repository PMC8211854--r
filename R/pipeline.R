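#' Read and validate a pipeline configuration
#'
#' YAML layout (paths relative to the config file's directory):
#' ```
#' seed: 1
#' output_dir: out
#' genome: genome.chrom.sizes
#' samples:
#'   - {name: ctrl_1, group: A, fragments: ctrl_1.bed}
#'   - {name: case_1, group: B, fragments: case_1.bed}
#' annotations_dir: annotations       # optional
#' signal: signal.bedgraph            # optional
#' mask: mask.bed                     # optional
#' variants: variants.vcf             # optional
#' sv: svs.bed                        # optional
#' vcf_cases: [case1, ...]            # optional
#' vcf_controls: [ctrl1, ...]
#' params:
#'   quant: {ws: 500, extend: 300, shift: 0, uniq_p: 1.0e-3}
#'   dmr: {fold_threshold: 1.5, p_threshold: 0.01}
#'   enrichment: {n_random: 10000, region_len: 500}
#'   profile: {body_bp: 3000, flank_bp: 6000, bin_bp: 200}
#' ```
#' Every referenced path must exist; parameter blocks are merged over
#' the package defaults.
#'
#' @param path YAML config path
#' @return validated config list (class `pipeline_config`)
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  rel <- function(p) if (is.null(p) || file.exists(p)) p
    else file.path(base, p)
  cfg$genome <- rel(cfg$genome)
  cfg$annotations_dir <- rel(cfg$annotations_dir)
  for (f in c("signal", "mask", "variants", "sv", "repeats_bed"))
    cfg[[f]] <- rel(cfg[[f]])
  for (i in seq_along(cfg$samples))
    cfg$samples[[i]]$fragments <- rel(cfg$samples[[i]]$fragments)
  validate_pipeline_config(cfg)
}

#' @rdname read_pipeline_config
#' @param cfg a config list built in code
#' @export
validate_pipeline_config <- function(cfg) {
  if (is.null(cfg$genome)) stop("config needs a 'genome' chrom.sizes path")
  paths <- c(genome = cfg$genome, annotations_dir = cfg$annotations_dir,
             signal = cfg$signal, mask = cfg$mask,
             variants = cfg$variants, sv = cfg$sv,
             repeats_bed = cfg$repeats_bed,
             vapply(cfg$samples, function(s) s$fragments, character(1)))
  missing <- paths[!vapply(paths, file.exists, logical(1))]
  if (length(missing))
    stop("missing input path(s): ",
         paste(names(missing), "=", missing, collapse = "; "))
  if (length(cfg$samples) < 4L)
    stop("need at least 2 samples per group (4 total)")
  groups <- vapply(cfg$samples, function(s) s$group, character(1))
  if (length(unique(groups)) != 2L)
    stop("samples must form exactly two groups")
  if (is.null(cfg$seed)) cfg$seed <- 1L
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the pipeline end-to-end
#'
#' Stages: `quant` (fragments -> window counts -> RPKM -> background
#' methylome), `dmr` (exact test, fold gate, merge, mask), `context`
#' (genomic classification + chi-squared vs background), `enrich`
#' (overlap table, Monte-Carlo expected overlap, binomial test),
#' `profile` (shuffled baseline + scaled-region matrices) and
#' `variants` (genotype calls, hard filters, shared variants,
#' DMR proximity) — the last four only when their inputs are
#' configured.  A failing stage halts the run with the stage named.
#' All randomness derives from `cfg$seed`, so re-running an identical
#' config reproduces identical outputs.
#'
#' @param cfg a `pipeline_config` (or path to one)
#' @param outdir output directory; defaults to `cfg$output_dir`
#' @param stages subset of stages to run (dependencies of later stages
#'   are always run)
#' @return the run manifest (named list), also written to
#'   `manifest.json`
#' @export
run_pipeline <- function(cfg, outdir = NULL,
                         stages = c("quant", "dmr", "context", "enrich",
                                    "profile", "variants")) {
  if (is.character(cfg)) cfg <- read_pipeline_config(cfg)
  stopifnot(inherits(cfg, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  if (is.null(outdir)) outdir <- cfg$output_dir
  if (is.null(outdir)) stop("no output directory configured")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package_version = as.character(utils::packageVersion("medipr")),
                   seed = cfg$seed, stages = list())
  note <- function(stage, ...) {
    manifest$stages[[stage]] <<- list(...)
    message("[", stage, "] ok")
  }
  run_stage <- function(stage, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  qp <- do.call(quant_params, cfg$params$quant %||% list())
  dp <- do.call(dmr_params, cfg$params$dmr %||% list())
  genome <- read_chrom_sizes(cfg$genome)

  ## ---- quant ----
  se <- NULL; background <- NULL
  run_stage("quant", function() {
    fragsets <- lapply(cfg$samples, function(s) {
      reads <- read_fragments_bed(s$fragments, genome)
      fs <- extend_fragments(reads, genome, qp)
      apply_uniq_filter(fs, qp$uniq_p, genome)
    })
    names(fragsets) <- vapply(cfg$samples, `[[`, character(1), "name")
    groups <- vapply(cfg$samples, `[[`, character(1), "group")
    se <<- to_rpkm(window_counts(fragsets, genome, qp, groups = groups))
    background <<- background_methylome(se)
    write_count_matrix(se, file.path(outdir, "windows"))
    bg <- rowRanges(se)[background]
    write_bed(bg, file.path(outdir, "background_methylome.bed"))
    note("quant", n_windows = nrow(se), n_samples = ncol(se),
         n_background = sum(background))
  })

  ## ---- dmr ----
  dmrs <- NULL
  if (any(c("dmr", "context", "enrich", "profile", "variants") %in%
          stages)) run_stage("dmr", function() {
    p <- window_test(se, dp, background = background)
    flagged <- call_windows(se, p, dp)
    merged <- filter_dmr_length(merge_adjacent(flagged), dp)
    n_masked <- 0L
    if (!is.null(cfg$mask)) {
      mask <- rtracklayer::import(cfg$mask, format = "BED")
      merged <- mask_dmrs(merged, mask)
      n_masked <- attr(merged, "removed")
    }
    dmrs <<- merged
    write_dmr_bed(merged, file.path(outdir, "dmrs.bed"))
    note("dmr", n_flagged_windows = length(flagged),
         n_dmrs = length(merged), n_masked = n_masked,
         dispersion = attr(p, "dispersion"))
  })

  ann <- if (!is.null(cfg$annotations_dir))
    read_annotation_beds(cfg$annotations_dir) else NULL

  ## ---- context ----
  if ("context" %in% stages && !is.null(ann)) run_stage("context", function() {
    bg_gr <- rowRanges(se)[background]
    rows <- list()
    for (scheme in c("genic", "repeat", "cgi")) {
      needed <- switch(scheme, genic = "genes", "repeat" = "repeats",
                       cgi = "cgis")
      if (is.null(ann[[needed]])) next
      d <- classify_intervals(dmrs, ann, scheme)
      b <- classify_intervals(bg_gr, ann, scheme)
      test <- if (length(dmrs) > 0)
        tryCatch(chisq_vs_background(d, b), error = function(e) NULL)
        else NULL
      rows[[scheme]] <- data.frame(
        scheme = scheme, category = d$categories, dmr_count = d$counts,
        dmr_fraction = d$fractions, background_fraction = b$fractions,
        chisq_p = if (is.null(test)) NA_real_ else test$p.value)
    }
    ctx <- do.call(rbind, rows)
    write.table(ctx, file.path(outdir, "context.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    if (!is.null(ann$enhancers) && length(dmrs)) {
      eo <- enhancer_overlap(dmrs, ann$enhancers)
      write.table(cbind(as.data.frame(granges(dmrs)), eo),
                  file.path(outdir, "enhancer_overlap.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    }
    note("context", n_rows = nrow(ctx))
  })

  ## ---- enrich ----
  if ("enrich" %in% stages && !is.null(ann)) run_stage("enrich", function() {
    refs <- Filter(Negate(is.null),
                   list(retention = ann$retention,
                        resist_preimpl = ann$resist_preimpl,
                        resist_germline = ann$resist_germline))
    if (length(refs) == 0L || length(dmrs) == 0L) {
      note("enrich", skipped = "no reference sets or no DMRs")
      return(invisible())
    }
    if (length(refs) >= 2L)
      refs$joint <- list(refs[[1]], refs[[2]])
    tab <- overlap_table(list(dmrs = dmrs), refs)
    ep <- do.call(enrichment_params,
                  c(cfg$params$enrichment %||% list(),
                    list(seed = derive_seed(cfg$seed, 7L))))
    if (!is.null(cfg$mask))
      ep$exclusions <- rtracklayer::import(cfg$mask, format = "BED")
    exp_ov <- expected_overlap(genome, refs[[1]], ep)
    obs <- overlap_summary(dmrs, refs[[1]])
    enr <- binomial_enrichment(obs$n_overlapping, obs$n_total,
                               max(exp_ov$expected_fraction, 1e-12))
    write.table(tab, file.path(outdir, "overlap_table.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(reference = names(refs)[1],
           observed_fraction = enr$observed_fraction,
           expected_fraction = exp_ov$expected_fraction,
           mc_se = exp_ov$se, p_value = enr$p.value,
           wilson_ci = enr$conf_int),
      file.path(outdir, "enrichment.json"), auto_unbox = TRUE,
      digits = NA)
    note("enrich", n_rows = nrow(tab),
         expected_fraction = exp_ov$expected_fraction,
         p_value = enr$p.value)
  })

  ## ---- profile ----
  if ("profile" %in% stages && !is.null(cfg$signal)) {
    run_stage("profile", function() {
      if (length(dmrs) == 0L) {
        note("profile", skipped = "no DMRs")
        return(invisible())
      }
      pp <- do.call(profile_params,
                    c(cfg$params$profile %||% list(),
                      list(seed = derive_seed(cfg$seed, 9L))))
      excl <- if (!is.null(cfg$mask))
        rtracklayer::import(cfg$mask, format = "BED") else NULL
      baseline <- shuffle_baseline(dmrs, genome, exclusions = excl,
                                   seed = pp$seed)
      signal <- read_bedgraph(cfg$signal)
      pm_d <- profile_matrix(dmrs, signal, pp, genome = genome)
      pm_b <- profile_matrix(baseline, signal, pp, genome = genome)
      prof <- rbind(cbind(set = "dmrs", mean_profile(pm_d)),
                    cbind(set = "baseline", mean_profile(pm_b)))
      write.table(prof, file.path(outdir, "profile.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
      write_bed(baseline, file.path(outdir, "baseline_regions.bed"))
      note("profile", n_regions = length(dmrs), n_bins = ncol(pm_d))
    })
  }

  ## ---- variants ----
  if ("variants" %in% stages && !is.null(cfg$variants)) {
    run_stage("variants", function() {
      vt <- read_variant_vcf(cfg$variants)
      reps <- if (!is.null(cfg$repeats_bed))
        rtracklayer::import(cfg$repeats_bed, format = "BED") else NULL
      res <- filter_variants(vt, repeats = reps)
      write_filtered_vcf(vt, res$status,
                         file.path(outdir, "variants_filtered.vcf"),
                         genome)
      n_shared <- NA_integer_
      if (!is.null(cfg$vcf_cases) && !is.null(cfg$vcf_controls)) {
        shared <- shared_variants(res$passed, cfg$vcf_cases,
                                  cfg$vcf_controls)
        n_shared <- sum(shared)
        write_bed(res$passed$sites[shared],
                  file.path(outdir, "shared_variants.bed"))
      }
      if (length(dmrs)) {
        svs <- if (!is.null(cfg$sv))
          rtracklayer::import(cfg$sv, format = "BED") else GRanges()
        prox <- variant_region_proximity(dmrs, vt$sites, svs)
        write.table(as.data.frame(prox),
                    file.path(outdir, "dmr_variant_proximity.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
      }
      note("variants", n_variants = length(vt$sites),
           n_passed = length(res$passed$sites), n_shared = n_shared)
    })
  }

  manifest$params <- list(quant = unclass(qp), dmr = unclass(dp))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
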