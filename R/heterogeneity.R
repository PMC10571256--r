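#' Heterogeneity classification cutoffs
#'
#' Genome-wide, the distribution of the per-CG heterogeneity fraction is
#' strongly bimodal: almost all CGs are methylated in essentially no cells or
#' essentially all cells. The cutoffs delimit the unusual intermediate band.
#' Sites with `h <= low` are unmethylated, `h >= high` fully methylated, and
#' strictly between heterogeneously methylated — both boundaries leave the
#' heterogeneous class.
#'
#' @param low lower cutoff (default 0.10).
#' @param high upper cutoff (default 0.85).
#' @return A list of class `het_cutoffs`.
#' @export
het_cutoffs <- function(low = 0.10, high = 0.85) {
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L)
  if (!(low > 0 && low < high && high < 1)) {
    stop("cutoffs must satisfy 0 < low < high < 1")
  }
  structure(list(low = low, high = high), class = "het_cutoffs")
}

#' Classify CG sites by methylation heterogeneity
#'
#' Total, deterministic step function of the heterogeneity fraction `h`:
#' `h <= low` is unmethylated, `h >= high` methylated, strictly inside is
#' heterogeneous. The three classes partition `[0, 1]`.
#'
#' @param h numeric vector of heterogeneity fractions in `[0, 1]` (`NA`
#'   allowed and propagated).
#' @param cutoffs a [het_cutoffs()].
#' @return Factor with levels `unmethylated`, `heterogeneous`, `methylated`.
#' @export
classify_site <- function(h, cutoffs = het_cutoffs()) {
  stopifnot(inherits(cutoffs, "het_cutoffs"))
  if (any(h < 0 | h > 1, na.rm = TRUE)) stop("h must lie in [0, 1]")
  lab <- rep(NA_character_, length(h))
  lab[h <= cutoffs$low] <- "unmethylated"
  lab[h >= cutoffs$high] <- "methylated"
  lab[h > cutoffs$low & h < cutoffs$high] <- "heterogeneous"
  factor(lab, levels = c("unmethylated", "heterogeneous", "methylated"))
}

# internal: CG sites within each gene body. A dinucleotide belongs to a gene
# iff its forward-strand C (1-based `start`, i.e. 0-based start-1) falls in
# the 0-based half-open gene interval.
.sites_in_genes <- function(sites, genes) {
  s <- as.data.table(sites)
  if (nrow(s) == 0L || nrow(genes) == 0L) {
    out <- s[0L]
    out[, gene_id := character()]
    return(out[])
  }
  site_gr <- GenomicRanges::GRanges(s$chrom, IRanges::IRanges(s$start, s$start))
  gene_gr <- .as_granges(genes)
  ov <- GenomicRanges::findOverlaps(site_gr, gene_gr)
  out <- s[queryHits(ov)]
  out[, gene_id := genes$gene_id[subjectHits(ov)]]
  out[]
}

# internal: per-gene CHG/CHH methylation fractions from raw cytosine records
.gene_noncg <- function(genes, methylome) {
  empty <- data.table(gene_id = genes$gene_id, chg = NA_real_, chh = NA_real_,
                      noncg = NA_real_)
  m <- as.data.table(methylome)[context %in% c("CHG", "CHH")]
  if (nrow(m) == 0L || nrow(genes) == 0L) return(empty)
  c_gr <- GenomicRanges::GRanges(m$chrom, IRanges::IRanges(m$pos, m$pos))
  gene_gr <- .as_granges(genes)
  ov <- GenomicRanges::findOverlaps(c_gr, gene_gr)
  if (length(ov) == 0L) return(empty)
  hits <- m[queryHits(ov)]
  hits[, gene_id := genes$gene_id[subjectHits(ov)]]
  frac <- function(meth, un) {
    tot <- sum(meth) + sum(un)
    if (tot > 0L) sum(meth) / tot else NA_real_
  }
  agg <- hits[, .(
    chg = frac(n_meth[context == "CHG"], n_unmeth[context == "CHG"]),
    chh = frac(n_meth[context == "CHH"], n_unmeth[context == "CHH"]),
    noncg = frac(n_meth, n_unmeth)
  ), by = gene_id]
  out <- merge(empty[, .(gene_id)], agg, by = "gene_id", all.x = TRUE)
  out[match(genes$gene_id, out$gene_id)]
}

#' Per-gene methylation profiles
#'
#' For each gene body, counts covered CG dinucleotide sites per heterogeneity
#' class, the read-weighted gene-body mCG fraction (sum of methylated over
#' total reads across all gene-body CG sites — "all CGs across all cells"),
#' and the gene-body non-CG (CHG/CHH) methylation fraction. Genes without any
#' callable CG site are flagged `no_data`.
#'
#' @param genes a [gene_models()] table.
#' @param sites pooled CG sites from [pool_cg_dinucleotides()].
#' @param methylome the [methylome()] the sites came from (for non-CG
#'   fractions); may be `NULL` to skip non-CG columns.
#' @param cutoffs a [het_cutoffs()].
#' @param min_coverage minimum pooled reads for a site to be callable
#'   (default 5); sites below it are counted as uncallable and excluded from
#'   class counts and mCG.
#' @param methylated_domains_only if `TRUE`, restrict the profile to sites
#'   with `h > low` (the gene's methylated domain); used for cross-tissue
#'   comparisons where unmethylated flanks would dilute the signal.
#' @return `data.table` of class `gene_profiles`: one row per gene with
#'   `n_unmethylated`, `n_heterogeneous`, `n_methylated`, `n_uncallable`,
#'   `n_sites` (callable), `mcg`, `chg`, `chh`, `noncg`, `no_data`.
#' @export
gene_profiles <- function(genes, sites, methylome = NULL,
                          cutoffs = het_cutoffs(), min_coverage = 5,
                          methylated_domains_only = FALSE) {
  stopifnot(inherits(genes, "gene_models"))
  gs <- .sites_in_genes(sites, genes)
  out <- data.table(gene_id = genes$gene_id)
  if (nrow(gs) > 0L) {
    gs[, callable := n_total >= min_coverage]
    if (methylated_domains_only) {
      gs <- gs[!callable | h > cutoffs$low]
    }
    gs[, site_class := classify_site(ifelse(callable, h, NA_real_), cutoffs)]
    agg <- gs[, .(
      n_unmethylated = sum(site_class == "unmethylated", na.rm = TRUE),
      n_heterogeneous = sum(site_class == "heterogeneous", na.rm = TRUE),
      n_methylated = sum(site_class == "methylated", na.rm = TRUE),
      n_uncallable = sum(!callable),
      mcg = {
        tot <- sum(n_total[callable])
        if (tot > 0L) sum(n_meth[callable]) / tot else NA_real_
      }
    ), by = gene_id]
    out <- merge(out, agg, by = "gene_id", all.x = TRUE)
  } else {
    out[, `:=`(n_unmethylated = NA_integer_, n_heterogeneous = NA_integer_,
               n_methylated = NA_integer_, n_uncallable = NA_integer_,
               mcg = NA_real_)]
  }
  for (col in c("n_unmethylated", "n_heterogeneous", "n_methylated",
                "n_uncallable")) {
    set(out, which(is.na(out[[col]])), col, 0L)
  }
  out[, n_sites := n_unmethylated + n_heterogeneous + n_methylated]
  out[, no_data := n_sites == 0L]
  if (!is.null(methylome)) {
    out <- merge(out, .gene_noncg(genes, methylome), by = "gene_id",
                 all.x = TRUE)
  }
  out <- out[match(genes$gene_id, out$gene_id)]
  setattr(out, "class", c("gene_profiles", class(out)))
  out[]
}

#' Genome-wide heterogeneity distribution
#'
#' Binned counts of the heterogeneity fraction over all callable CG sites —
#' the histogram behind the genome-wide violin showing the bimodality that
#' motivates the classification cutoffs.
#'
#' @param sites pooled CG sites.
#' @param bins number of equal-width bins over `[0, 1]` (default 100).
#' @param min_coverage minimum pooled reads per site (default 5).
#' @return `data.table` with `bin_low`, `bin_high`, `count`; zero rows for an
#'   empty methylome.
#' @export
heterogeneity_distribution <- function(sites, bins = 100, min_coverage = 5) {
  s <- as.data.table(sites)
  s <- s[!is.na(h) & n_total >= min_coverage]
  edges <- seq(0, 1, length.out = bins + 1L)
  if (nrow(s) == 0L) {
    return(data.table(bin_low = numeric(), bin_high = numeric(),
                      count = integer()))
  }
  idx <- findInterval(s$h, edges, rightmost.closed = TRUE, all.inside = TRUE)
  data.table(
    bin_low = edges[seq_len(bins)],
    bin_high = edges[-1L],
    count = tabulate(idx, nbins = bins)
  )
}
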