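#' Pipeline configuration
#'
#' One configuration object drives the whole analysis. Inputs are either
#' file paths (`paths`) or a synthetic-data configuration (`sim`); stage
#' parameters default to the published constants: classification cutoffs
#' 0.10 / 0.85, 200-bp windows stepping 100 bp, 5 differential CGs per seed
#' window, 20 percentage-point differential threshold, at least 5 gaining
#' dinucleotides, 2-kb flanks, and 10 random conservation sets.
#'
#' @param paths optional named list of input files: `wt`, `mut`, `genes`
#'   (required together), and optionally `target`, `target_genes`, `pairs`,
#'   `expr_wt`, `expr_mut`, `track`, `states`, `control_contig`.
#' @param sim optional [sim_config()]; used when `paths` is `NULL`.
#' @param low,high heterogeneity cutoffs.
#' @param min_coverage per-site coverage floor.
#' @param dmr_window_bp,dmr_step_bp,dmr_min_sites,dmr_min_delta DMR calling
#'   parameters.
#' @param min_gain,min_dinucleotides Dynamic-gene cutoffs.
#' @param flank_bp intergenic association flank.
#' @param k_random number of random conservation sets.
#' @param conversion_warn conversion-rate warning threshold.
#' @param control_contig control contig name for conversion QC.
#' @param seed seed for the stochastic stages (conservation resampling).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = NULL, sim = NULL, low = 0.10,
                            high = 0.85, min_coverage = 5,
                            dmr_window_bp = 200, dmr_step_bp = 100,
                            dmr_min_sites = 5, dmr_min_delta = 20,
                            min_gain = 0.20, min_dinucleotides = 5,
                            flank_bp = 2000, k_random = 10,
                            conversion_warn = 0.997,
                            control_contig = "ChrC", seed = 1) {
  if (is.null(paths) && is.null(sim)) sim <- sim_config(seed = seed)
  cfg <- as.list(environment())
  structure(cfg, class = "pipeline_config")
}

# internal: stable md5 of a configuration (inputs by checksum, parameters
# by value)
.config_hash <- function(config) {
  canon <- unclass(config)
  if (!is.null(canon$paths)) {
    canon$paths <- lapply(canon$paths, function(p) {
      if (is.character(p) && file.exists(p)) unname(tools::md5sum(p)) else p
    })
  }
  if (!is.null(canon$sim)) canon$sim <- unclass(canon$sim)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(canon, tmp, version = 2, compress = FALSE)
  unname(tools::md5sum(tmp))
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order: input loading (or simulation) and
#' conversion QC, CG pooling and heterogeneity profiling, DMR calling and
#' gene association, Dynamic/Stable classification, then — each when its
#' inputs are present — conservation enrichment, chromatin enrichment and
#' state overlap, and expression plasticity (CV/Fano, decile dynamic range,
#' tissue-specificity regression). Stages whose inputs are missing are
#' skipped and logged. The returned bundle echoes every applied threshold
#' and a configuration hash; all stages are deterministic given the config.
#'
#' @param config a [pipeline_config()].
#' @return A list of class `results_bundle` with `classification`, `dmrs`,
#'   `dmr_associations`, `qc`, `profiles`, `conservation`, `chromatin`,
#'   `plasticity`, `truth` (simulation only), `config`, `config_hash`,
#'   `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- character()
  note <- function(...) log <<- c(log, sprintf(...))
  note("cutoffs low=%.2f high=%.2f; min_coverage=%d", config$low,
       config$high, as.integer(config$min_coverage))
  note("dmr window=%d step=%d min_sites=%d min_delta=%g; gain>%g x%d; flank=%d",
       config$dmr_window_bp, config$dmr_step_bp, config$dmr_min_sites,
       config$dmr_min_delta, config$min_gain, config$min_dinucleotides,
       config$flank_bp)

  truth <- NULL; expr <- NULL; cons_in <- NULL; chip <- NULL
  if (is.null(config$paths)) {
    note("inputs: synthetic (seed %d)", config$sim$seed)
    meth <- simulate_methylomes(config$sim)
    wt <- meth$wt; mut <- meth$mut; genes <- meth$genes; truth <- meth$truth
    expr <- simulate_expression(config$sim, truth)
    cons_in <- simulate_conservation(config$sim, truth)
    chip <- simulate_chip(config$sim, genes, truth)
    control <- config$sim$control_contig
  } else {
    p <- config$paths
    for (key in c("wt", "mut", "genes")) {
      if (is.null(p[[key]])) stop("pipeline paths need '", key, "'")
      if (!file.exists(p[[key]])) {
        stop("stage 'input': file missing for '", key, "': ", p[[key]])
      }
    }
    note("inputs: files (%s)", paste(basename(unlist(p)), collapse = ", "))
    wt <- read_cytosine_report(p$wt, genotype = "WT")
    mut <- read_cytosine_report(p$mut, genotype = "mutant")
    genes <- read_gene_models(p$genes)
    if (!is.null(p$expr_wt) && !is.null(p$expr_mut)) {
      read_mat <- function(path) {
        dt <- fread(path)
        m <- as.matrix(dt[, -1L])
        rownames(m) <- dt[[1L]]
        m
      }
      expr <- list(wt = read_mat(p$expr_wt), mut = read_mat(p$expr_mut))
    }
    if (!is.null(p$pairs) && !is.null(p$target) &&
        !is.null(p$target_genes)) {
      cons_in <- list(
        target_methylome = read_cytosine_report(p$target),
        target_genes = read_gene_models(p$target_genes),
        pairs = fread(p$pairs)
      )
    }
    if (!is.null(p$track)) {
      chip <- list(regulatory = read_bedgraph(p$track))
      if (!is.null(p$states)) {
        st <- fread(p$states, header = FALSE,
                    col.names = c("chrom", "start", "end", "state"))
        chip$states <- st
      }
    }
    control <- config$control_contig
  }

  cutoffs <- het_cutoffs(config$low, config$high)
  qc <- tryCatch(
    list(wt = conversion_qc(wt, control, warn_below = config$conversion_warn),
         mut = conversion_qc(mut, control,
                             warn_below = config$conversion_warn)),
    error = function(e) {
      note("conversion QC skipped: %s", conditionMessage(e))
      NULL
    }
  )

  cls <- classify_gbm(
    genes, wt, mut, cutoffs = cutoffs, min_coverage = config$min_coverage,
    dmr_window_bp = config$dmr_window_bp, dmr_step_bp = config$dmr_step_bp,
    dmr_min_sites = config$dmr_min_sites,
    dmr_min_delta = config$dmr_min_delta, min_gain = config$min_gain,
    min_dinucleotides = config$min_dinucleotides
  )
  sets <- resolve_overlap(cls)
  note("classified: %d dynamic, %d stable, %d both, %d neither",
       length(sets$dynamic), length(sets$stable), length(sets$both),
       length(sets$neither))
  profiles <- list(
    wt = gene_profiles(genes, cls$wt_sites, wt, cutoffs = cutoffs,
                       min_coverage = config$min_coverage),
    mut = gene_profiles(genes, cls$mut_sites, mut, cutoffs = cutoffs,
                        min_coverage = config$min_coverage)
  )
  assoc <- associate_dmrs(cls$dmrs, genes, flank_bp = config$flank_bp)

  conservation <- NULL
  if (!is.null(cons_in)) {
    conservation <- enrichment_vs_random(
      cons_in$pairs, focal_set = sets$dynamic,
      universe = genes$gene_id,
      target_methylome = cons_in$target_methylome,
      target_genes = cons_in$target_genes, k = config$k_random,
      seed = config$seed, cutoffs = cutoffs,
      min_coverage = config$min_coverage
    )
    note("conservation: fold_count=%.2f over k=%d random sets",
         conservation$fold_count, config$k_random)
  } else note("conservation skipped: no homolog inputs")

  chromatin <- NULL
  if (!is.null(chip)) {
    g <- as.data.table(genes)
    body_sets <- list(
      dynamic = g[gene_id %in% sets$dynamic, .(chrom, start, end)],
      stable = g[gene_id %in% sets$stable, .(chrom, start, end)]
    )
    body_sets <- Filter(function(x) nrow(x) > 0L, body_sets)
    track <- normalize_track(chip$regulatory)
    chromatin <- list(track_mean = attr(track, "genomic_mean"))
    if (length(body_sets) >= 1L) {
      chromatin$enrichment <- feature_enrichment(track, body_sets)
    }
    if (!is.null(chip$states)) {
      chromatin$state_overlap <- state_overlap(body_sets, chip$states)
    }
    note("chromatin: %d feature group(s)", length(body_sets))
  } else note("chromatin skipped: no track input")

  plasticity <- NULL
  if (!is.null(expr)) {
    exclude <- sets$both
    plasticity <- list(
      stats = plasticity_stats(
        expr$wt,
        gene_sets = list(dynamic = sets$dynamic, stable = sets$stable,
                         total = rownames(expr$wt)),
        exclude = exclude
      ),
      decile_dynamic = decile_dynamic_range(expr$wt, expr$mut,
                                            sets$dynamic),
      decile_stable = decile_dynamic_range(expr$wt, expr$mut, sets$stable)
    )
    # paired mutant (shared condition profile) when the generator provides
    # it: the regression contrasts matched samples, not fresh replicates
    mut_for_reg <- expr$mut_paired %||% expr$mut
    ref_fc <- log2_reference_fc(expr$wt, focal = 1L)
    gfc <- log2_genotype_fc(expr$wt[, 1L], mut_for_reg[, 1L])
    plasticity$regression <- tryCatch(
      tissue_specificity_regression(ref_fc, gfc, gene_set = sets$dynamic),
      error = function(e) NULL
    )
    if (nrow(assoc) > 0L) {
      plasticity$intergenic <- tryCatch(
        intergenic_control(assoc, expr$wt),
        error = function(e) NULL
      )
    }
    note("plasticity: %d dynamic vs %d stable genes (%d excluded)",
         length(setdiff(sets$dynamic, exclude)),
         length(setdiff(sets$stable, exclude)), length(exclude))
  } else note("plasticity skipped: no expression input")

  structure(
    list(classification = cls$table, dmrs = cls$dmrs,
         dmr_associations = assoc, qc = qc, profiles = profiles,
         sets = sets, conservation = conservation, chromatin = chromatin,
         plasticity = plasticity, truth = truth, config = config,
         config_hash = .config_hash(config), log = log),
    class = "results_bundle"
  )
}

#' @export
print.results_bundle <- function(x, ...) {
  cat("<results_bundle>", x$config_hash, "\n")
  for (line in x$log) cat(" -", line, "\n")
  invisible(x)
}
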