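#' Filter homolog pairs for conservation analysis
#'
#' Retains pairs that are one-to-one orthologs (avoiding misidentification in
#' duplicated gene families) and whose target gene body carries at most
#' `max_noncg` non-CG methylation (removing genes under de novo methylation
#' pathways, which would confound CG heterogeneity). The two filters commute.
#'
#' @param pairs data.frame with columns `source_gene`, `target_gene`,
#'   `one_to_one` (logical), `species`.
#' @param target_methylome [methylome()] of the target species.
#' @param target_genes [gene_models()] of the target species.
#' @param max_noncg ceiling on target gene-body non-CG methylation
#'   (default 0.01).
#' @return Filtered pairs `data.table`; pairs whose target gene is absent
#'   from `target_genes` are dropped with a warning.
#' @export
filter_homologs <- function(pairs, target_methylome, target_genes,
                            max_noncg = 0.01) {
  p <- as.data.table(pairs)
  required <- c("source_gene", "target_gene", "one_to_one")
  missing_cols <- setdiff(required, names(p))
  if (length(missing_cols) > 0L) {
    stop("homolog table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  absent <- setdiff(p$target_gene, target_genes$gene_id)
  if (length(absent) > 0L) {
    warning(length(absent), " homolog pair(s) dropped: target gene absent ",
            "from gene models")
    p <- p[!target_gene %in% absent]
  }
  p <- p[one_to_one == TRUE]
  noncg <- .gene_noncg(target_genes, target_methylome)
  high <- noncg[!is.na(noncg) & noncg > max_noncg, gene_id]
  p <- p[!target_gene %in% high]
  p[]
}

#' Count heterogeneously methylated CGs per gene
#'
#' For each gene body, the number of callable CG sites with heterogeneity
#' fraction strictly between the cutoffs, and the density per covered site.
#' Genes with zero covered sites get `NA` density and are flagged.
#'
#' @param genes a [gene_models()] table.
#' @param sites pooled CG sites of the corresponding methylome.
#' @param cutoffs a [het_cutoffs()].
#' @param min_coverage minimum pooled reads per site (default 5).
#' @return `data.table`: `gene_id`, `n_het`, `n_covered`, `density`.
#' @export
count_het_cgs <- function(genes, sites, cutoffs = het_cutoffs(),
                          min_coverage = 5) {
  s <- as.data.table(sites)[!is.na(h) & n_total >= min_coverage]
  setattr(s, "class", c("cg_sites", class(s)))
  gs <- .sites_in_genes(s, genes)
  agg <- if (nrow(gs) > 0L) {
    gs[, .(n_het = sum(h > cutoffs$low & h < cutoffs$high), n_covered = .N),
       by = gene_id]
  } else {
    data.table(gene_id = character(), n_het = integer(), n_covered = integer())
  }
  out <- merge(data.table(gene_id = genes$gene_id), agg, by = "gene_id",
               all.x = TRUE)
  set(out, which(is.na(out$n_het)), "n_het", 0L)
  set(out, which(is.na(out$n_covered)), "n_covered", 0L)
  out[, density := ifelse(n_covered > 0L, n_het / n_covered, NA_real_)]
  out[match(genes$gene_id, out$gene_id)][]
}

#' Conservation enrichment of heterogeneous CGs versus random gene sets
#'
#' Tests whether homologs of a focal gene set (e.g. Dynamic GbM genes) in a
#' target species carry more heterogeneously methylated gene-body CGs than
#' homologs of randomly selected genes. Draws `k` random source-gene sets of
#' the focal size, pushes each through the same one-to-one / non-CG homolog
#' filters and counting, and reports the fold change of the focal per-gene
#' mean over the average of the `k` random-set means, for both the count and
#' the per-covered-CG density, with Welch two-tailed t-tests (focal genes vs
#' pooled random genes).
#'
#' @param pairs homolog table (see [filter_homologs()]).
#' @param focal_set character vector of source gene ids.
#' @param universe character vector of source gene ids random sets are drawn
#'   from.
#' @param target_methylome,target_genes target-species methylome and gene
#'   models.
#' @param k number of random sets (default 10).
#' @param seed integer seed fixing the random draws.
#' @param cutoffs a [het_cutoffs()].
#' @param min_coverage minimum pooled reads per target site (default 5).
#' @param exclude_focal drop focal genes from the random-draw universe
#'   (default `TRUE`).
#' @return A list of class `enrichment_result`: per-gene focal stats, random
#'   set means, `fold_count`, `fold_density`, `p_count`, `p_density`,
#'   `n_focal_genes` (after filtering), `n_random_genes`, `low_confidence`
#'   flag (`k < 2`), and `species` when present in `pairs`.
#' @export
enrichment_vs_random <- function(pairs, focal_set, universe,
                                 target_methylome, target_genes, k = 10,
                                 seed = 1, cutoffs = het_cutoffs(),
                                 min_coverage = 5, exclude_focal = TRUE) {
  p <- as.data.table(pairs)
  filtered <- filter_homologs(p, target_methylome, target_genes)
  target_sites <- pool_cg_dinucleotides(target_methylome)
  het <- count_het_cgs(target_genes, target_sites, cutoffs = cutoffs,
                       min_coverage = min_coverage)
  set_stats <- function(source_set) {
    tg <- filtered[source_gene %in% source_set, target_gene]
    x <- het[gene_id %in% tg & n_covered > 0L]
    x
  }
  pool <- if (exclude_focal) setdiff(universe, focal_set) else universe
  if (length(pool) < length(focal_set)) {
    stop("universe (", length(pool), ") smaller than focal set (",
         length(focal_set), ")")
  }
  focal <- set_stats(focal_set)
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  set.seed(seed)
  random_sets <- lapply(seq_len(k), function(i) {
    set_stats(sample(pool, length(focal_set)))
  })
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  rand_count_means <- vapply(random_sets, function(x) mean(x$n_het), 0)
  rand_density_means <- vapply(random_sets, function(x) mean(x$density), 0)
  rand_pool <- rbindlist(random_sets)
  fold_count <- mean(focal$n_het) / mean(rand_count_means)
  fold_density <- mean(focal$density) / mean(rand_density_means)
  p_count <- tryCatch(
    t.test(focal$n_het, rand_pool$n_het)$p.value,
    error = function(e) NA_real_
  )
  p_density <- tryCatch(
    t.test(focal$density, rand_pool$density)$p.value,
    error = function(e) NA_real_
  )
  structure(
    list(
      species = if ("species" %in% names(p)) unique(p$species) else NA,
      focal = focal, random_count_means = rand_count_means,
      random_density_means = rand_density_means,
      fold_count = fold_count, fold_density = fold_density,
      p_count = p_count, p_density = p_density,
      n_focal_genes = nrow(focal), n_focal_input = length(focal_set),
      n_random_genes = nrow(rand_pool), k = k, seed = seed,
      low_confidence = k < 2
    ),
    class = "enrichment_result"
  )
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    paste0("<enrichment_result> %d focal homologs vs %d random sets: ",
           "fold_count %.2f (p %.3g), fold_density %.2f (p %.3g)%s\n"),
    x$n_focal_genes, x$k, x$fold_count, x$p_count, x$fold_density,
    x$p_density, if (x$low_confidence) " [low confidence: k < 2]" else ""
  ))
  invisible(x)
}
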