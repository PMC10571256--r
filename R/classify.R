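#' Classify genes as Dynamic GbM
#'
#' A gene is Dynamic GbM when both cutoffs hold: (1) at least one
#' hypermethylated (gain-in-mutant) DMR overlaps its gene body, and (2) at
#' least `min_dinucleotides` gene-body CG dinucleotides gain more than
#' `min_gain` methylation in the mutant (strict inequality). The second
#' filter removes genes with only a handful of heterogeneous sites in an
#' otherwise uniform gene body. The classification is monotone in mutant
#' methylation gain.
#'
#' @param genes a [gene_models()] table.
#' @param wt_sites,mut_sites pooled CG sites of the wild-type and
#'   eraser-mutant methylomes.
#' @param dmrs [call_dmrs()] output for the wt-vs-mutant comparison.
#' @param min_gain minimum per-dinucleotide gain in `h` (default 0.20,
#'   strict).
#' @param min_dinucleotides minimum number of gaining dinucleotides
#'   (default 5).
#' @param min_coverage minimum pooled reads per site in both samples
#'   (default 5).
#' @return `data.table`: `gene_id`, `dynamic` (logical),
#'   `has_genebody_dmr`, `n_gaining_dinucleotides`, `n_shared_sites`,
#'   `no_data`.
#' @export
classify_dynamic <- function(genes, wt_sites, mut_sites, dmrs,
                             min_gain = 0.20, min_dinucleotides = 5,
                             min_coverage = 5) {
  stopifnot(inherits(genes, "gene_models"))
  wt <- as.data.table(wt_sites)
  mut <- as.data.table(mut_sites)
  shared <- merge(wt[, .(chrom, start, h_wt = h, cov_wt = n_total)],
                  mut[, .(chrom, start, h_mut = h, cov_mut = n_total)],
                  by = c("chrom", "start"))
  shared <- shared[cov_wt >= min_coverage & cov_mut >= min_coverage &
                     !is.na(h_wt) & !is.na(h_mut)]
  out <- data.table(gene_id = genes$gene_id)
  if (nrow(shared) > 0L) {
    setattr(shared, "class", c("cg_sites", class(shared)))
    gs <- .sites_in_genes(shared, genes)
    agg <- gs[, .(
      n_shared_sites = .N,
      n_gaining_dinucleotides = sum(h_mut - h_wt > min_gain)
    ), by = gene_id]
    out <- merge(out, agg, by = "gene_id", all.x = TRUE)
  } else {
    out[, `:=`(n_shared_sites = NA_integer_,
               n_gaining_dinucleotides = NA_integer_)]
  }
  set(out, which(is.na(out$n_shared_sites)), "n_shared_sites", 0L)
  set(out, which(is.na(out$n_gaining_dinucleotides)),
      "n_gaining_dinucleotides", 0L)
  d <- as.data.table(dmrs)
  hyper_genes <- character()
  if (nrow(d) > 0L && any(d$direction == "hyper")) {
    hyper <- d[direction == "hyper"]
    ov <- GenomicRanges::findOverlaps(.as_granges(hyper), .as_granges(genes))
    hyper_genes <- unique(genes$gene_id[subjectHits(ov)])
  }
  out[, has_genebody_dmr := gene_id %in% hyper_genes]
  out[, no_data := n_shared_sites == 0L]
  out[, dynamic := has_genebody_dmr &
        n_gaining_dinucleotides >= min_dinucleotides & !no_data]
  out[match(genes$gene_id, out$gene_id)][]
}

#' Configuration for the Stable GbM test
#'
#' Stable GbM genes carry CG-only gene-body methylation present in
#' essentially all cells. The test asks whether a gene body holds more fully
#' methylated CG sites than expected from the genome-wide background rate
#' (one-sided binomial, BH-FDR across tested genes), while excluding genes
#' with appreciable non-CG methylation (the signature of de novo / TE-like
#' methylation rather than GbM).
#'
#' @param background_rate genome-wide probability that a callable CG site is
#'   fully methylated; `NULL` (default) estimates it from the methylome.
#' @param min_sites minimum callable gene-body CG sites (default 10).
#' @param q_threshold BH-corrected significance threshold (default 0.05).
#' @param max_chg,max_chh ceilings on gene-body CHG / CHH methylation
#'   fractions (default 0.01 each).
#' @return A list of class `stable_gbm_config`.
#' @export
stable_gbm_config <- function(background_rate = NULL, min_sites = 10,
                              q_threshold = 0.05, max_chg = 0.01,
                              max_chh = 0.01) {
  if (!is.null(background_rate)) {
    stopifnot(background_rate > 0, background_rate < 1)
  }
  structure(list(background_rate = background_rate, min_sites = min_sites,
                 q_threshold = q_threshold, max_chg = max_chg,
                 max_chh = max_chh),
            class = "stable_gbm_config")
}

#' Classify genes as Stable GbM
#'
#' @param genes a [gene_models()] table.
#' @param wt_sites pooled CG sites of the wild-type methylome.
#' @param wt_methylome the wild-type [methylome()] (for CHG/CHH ceilings).
#' @param config a [stable_gbm_config()].
#' @param cutoffs a [het_cutoffs()]; a site is "methylated" for the binomial
#'   count when `h >= high`.
#' @param min_coverage minimum pooled reads per site (default 5).
#' @return `data.table`: `gene_id`, `stable` (logical), `stable_q`
#'   (BH-adjusted one-sided binomial p; `NA` when untestable), `n_sites`,
#'   `n_methylated_sites`, `chg`, `chh`, `testable`.
#' @export
classify_stable <- function(genes, wt_sites, wt_methylome,
                            config = stable_gbm_config(),
                            cutoffs = het_cutoffs(), min_coverage = 5) {
  stopifnot(inherits(genes, "gene_models"),
            inherits(config, "stable_gbm_config"))
  s <- as.data.table(wt_sites)[!is.na(h) & n_total >= min_coverage]
  bg <- config$background_rate
  if (is.null(bg)) {
    if (nrow(s) == 0L) stop("no callable CG sites to estimate background rate")
    bg <- mean(s$h >= cutoffs$high)
    bg <- min(max(bg, 1e-6), 1 - 1e-6)
  }
  gs <- .sites_in_genes(s, genes)
  agg <- if (nrow(gs) > 0L) {
    gs[, .(n_sites = .N, n_methylated_sites = sum(h >= cutoffs$high)),
       by = gene_id]
  } else {
    data.table(gene_id = character(), n_sites = integer(),
               n_methylated_sites = integer())
  }
  out <- merge(data.table(gene_id = genes$gene_id), agg, by = "gene_id",
               all.x = TRUE)
  set(out, which(is.na(out$n_sites)), "n_sites", 0L)
  set(out, which(is.na(out$n_methylated_sites)), "n_methylated_sites", 0L)
  out[, testable := n_sites >= config$min_sites]
  out[, p_raw := NA_real_]
  out[testable == TRUE,
      p_raw := pbinom(n_methylated_sites - 1L, n_sites, bg,
                      lower.tail = FALSE)]
  out[, stable_q := NA_real_]
  out[testable == TRUE, stable_q := p.adjust(p_raw, method = "BH")]
  noncg <- .gene_noncg(genes, wt_methylome)
  out <- merge(out, noncg[, .(gene_id, chg, chh)], by = "gene_id",
               all.x = TRUE)
  out[, stable := testable & !is.na(stable_q) &
        stable_q < config$q_threshold &
        (is.na(chg) | chg <= config$max_chg) &
        (is.na(chh) | chh <= config$max_chh)]
  out[, p_raw := NULL]
  out[, background_rate := bg]
  out[match(genes$gene_id, out$gene_id)][]
}

#' Joint Dynamic/Stable classification of all genes
#'
#' Runs the full two-arm classification for one wild-type / eraser-mutant
#' methylome pair: pools CG dinucleotides, finds differential sites, calls
#' DMRs, then applies the Dynamic two-cutoff rule and the Stable binomial
#' test, labelling each gene `dynamic`, `stable`, `both`, or `neither`. A
#' user-supplied stable gene list can replace the binomial test.
#'
#' @param genes a [gene_models()] table.
#' @param wt,mut wild-type and mutant [methylome()] objects.
#' @param cutoffs a [het_cutoffs()].
#' @param min_coverage minimum pooled reads per site (default 5).
#' @param dmr_window_bp,dmr_step_bp,dmr_min_sites,dmr_min_delta parameters of
#'   [call_dmrs()] / [differential_sites()].
#' @param min_gain,min_dinucleotides Dynamic-arm cutoffs
#'   (see [classify_dynamic()]).
#' @param stable_config a [stable_gbm_config()].
#' @param stable_list optional character vector of gene ids to use as the
#'   Stable set instead of running the binomial test.
#' @return A list of class `gbm_classification`: `$table` (per-gene labels
#'   and evidence), `$dmrs`, `$wt_sites`, `$mut_sites`, and the parameters
#'   applied.
#' @export
classify_gbm <- function(genes, wt, mut, cutoffs = het_cutoffs(),
                         min_coverage = 5, dmr_window_bp = 200,
                         dmr_step_bp = 100, dmr_min_sites = 5,
                         dmr_min_delta = 20, min_gain = 0.20,
                         min_dinucleotides = 5,
                         stable_config = stable_gbm_config(),
                         stable_list = NULL) {
  wt_sites <- pool_cg_dinucleotides(wt)
  mut_sites <- pool_cg_dinucleotides(mut)
  dsites <- differential_sites(wt_sites, mut_sites,
                               min_coverage = min_coverage,
                               min_delta = dmr_min_delta)
  dmrs <- call_dmrs(dsites, window_bp = dmr_window_bp, step_bp = dmr_step_bp,
                    min_sites = dmr_min_sites)
  dyn <- classify_dynamic(genes, wt_sites, mut_sites, dmrs,
                          min_gain = min_gain,
                          min_dinucleotides = min_dinucleotides,
                          min_coverage = min_coverage)
  if (is.null(stable_list)) {
    stab <- classify_stable(genes, wt_sites, wt, config = stable_config,
                            cutoffs = cutoffs, min_coverage = min_coverage)
  } else {
    stab <- data.table(gene_id = genes$gene_id,
                       stable = genes$gene_id %in% stable_list,
                       stable_q = NA_real_, n_sites = NA_integer_,
                       n_methylated_sites = NA_integer_, chg = NA_real_,
                       chh = NA_real_, testable = NA)
  }
  tab <- merge(dyn, stab, by = "gene_id")
  tab[, label := fcase(
    dynamic & stable, "both",
    dynamic, "dynamic",
    stable, "stable",
    default = "neither"
  )]
  prof_wt <- gene_profiles(genes, wt_sites, wt, cutoffs = cutoffs,
                           min_coverage = min_coverage)
  prof_mut <- gene_profiles(genes, mut_sites, mut, cutoffs = cutoffs,
                            min_coverage = min_coverage)
  tab <- merge(tab, prof_wt[, .(gene_id, mcg_wt = mcg)], by = "gene_id")
  tab <- merge(tab, prof_mut[, .(gene_id, mcg_mut = mcg)], by = "gene_id")
  tab <- tab[match(genes$gene_id, tab$gene_id)]
  structure(
    list(table = tab[], dmrs = dmrs, wt_sites = wt_sites,
         mut_sites = mut_sites,
         params = list(cutoffs = cutoffs, min_coverage = min_coverage,
                       dmr_window_bp = dmr_window_bp,
                       dmr_step_bp = dmr_step_bp,
                       dmr_min_sites = dmr_min_sites,
                       dmr_min_delta = dmr_min_delta, min_gain = min_gain,
                       min_dinucleotides = min_dinucleotides)),
    class = "gbm_classification"
  )
}

#' @export
print.gbm_classification <- function(x, ...) {
  counts <- table(x$table$label)
  cat("<gbm_classification>", nrow(x$table), "genes:",
      paste(names(counts), counts, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Partition classifications and build the exclusion list
#'
#' Genes labelled both Dynamic and Stable stay visible in the Venn summary
#' but go on an exclusion list consumed by the expression-plasticity
#' comparisons, so the two gene sets contrasted there are disjoint.
#'
#' @param classification a [classify_gbm()] result or its `$table`.
#' @return A list: `dynamic`, `stable` (gene id vectors, overlap excluded),
#'   `both` (the exclusion list), `neither`, and `venn` (named counts where
#'   `dynamic`/`stable` count all genes carrying that label, including the
#'   overlap).
#' @export
resolve_overlap <- function(classification) {
  tab <- if (inherits(classification, "gbm_classification")) {
    classification$table
  } else {
    as.data.table(classification)
  }
  both <- tab[label == "both", gene_id]
  list(
    dynamic = tab[label == "dynamic", gene_id],
    stable = tab[label == "stable", gene_id],
    both = both,
    neither = tab[label == "neither", gene_id],
    venn = c(
      dynamic = sum(tab$label %in% c("dynamic", "both")),
      stable = sum(tab$label %in% c("stable", "both")),
      overlap = length(both)
    )
  )
}
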