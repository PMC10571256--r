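#' Average replicate columns of an expression matrix per condition
#'
#' Technical/biological replicates are averaged per condition before
#' plasticity statistics, so CV and Fano measure variation across
#' conditions, not replicate noise.
#'
#' @param mat numeric matrix, genes x samples, with column names matching
#'   `metadata$sample`.
#' @param metadata data.frame with columns `sample` and `condition`.
#' @return Matrix genes x conditions.
#' @export
average_replicates <- function(mat, metadata) {
  md <- as.data.frame(metadata)
  stopifnot(all(c("sample", "condition") %in% names(md)),
            all(colnames(mat) %in% md$sample))
  md <- md[match(colnames(mat), md$sample), ]
  conds <- unique(md$condition)
  out <- vapply(conds, function(cn) {
    cols <- which(md$condition == cn)
    if (length(cols) == 1L) mat[, cols] else rowMeans(mat[, cols, drop = FALSE])
  }, numeric(nrow(mat)))
  matrix(out, nrow = nrow(mat),
         dimnames = list(rownames(mat), as.character(conds)))
}

#' Per-gene expression plasticity statistics
#'
#' For each gene, the mean, standard deviation, coefficient of variation
#' (`sd/mean`) and Fano factor (`var/mean`, the index of dispersion) across
#' conditions. CV tends to overstate the variability of lowly expressed
#' genes and Fano of highly expressed ones, so a robust plasticity contrast
#' should hold under both. Genes with zero mean get `NA` for both and are
#' counted. When gene sets are supplied, per-set summaries and pairwise
#' Welch two-tailed t-tests (on CV and on Fano) are included; genes on the
#' exclusion list (e.g. the Stable-and-Dynamic overlap) are removed from
#' every set first.
#'
#' @param mat numeric matrix genes x conditions (nonnegative; replicates
#'   already averaged, see [average_replicates()]).
#' @param gene_sets optional named list of gene id vectors.
#' @param exclude optional character vector of gene ids removed from all
#'   sets before comparison.
#' @return A list of class `plasticity_stats`: `per_gene` (`data.table`),
#'   `set_summary`, `tests`, `n_zero_mean`, `n_missing` (set genes absent
#'   from the matrix).
#' @export
plasticity_stats <- function(mat, gene_sets = NULL, exclude = NULL) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)))
  if (any(mat < 0, na.rm = TRUE)) stop("expression values must be nonnegative")
  mu <- rowMeans(mat)
  sdv <- apply(mat, 1L, sd)
  per_gene <- data.table(
    gene_id = rownames(mat), mean = mu, sd = sdv,
    cv = ifelse(mu > 0, sdv / mu, NA_real_),
    fano = ifelse(mu > 0, sdv^2 / mu, NA_real_)
  )
  n_zero <- sum(mu == 0)
  set_summary <- NULL; tests <- NULL; n_missing <- 0L
  if (!is.null(gene_sets)) {
    gene_sets <- lapply(gene_sets, setdiff, y = exclude)
    n_missing <- sum(vapply(gene_sets, function(ids) {
      sum(!ids %in% per_gene$gene_id)
    }, 0L))
    per_set <- lapply(gene_sets, function(ids) {
      per_gene[gene_id %in% ids & !is.na(cv)]
    })
    set_summary <- rbindlist(lapply(names(per_set), function(s) {
      x <- per_set[[s]]
      data.table(set = s, n = nrow(x),
                 median_cv = stats::median(x$cv),
                 median_fano = stats::median(x$fano),
                 mean_cv = mean(x$cv), mean_fano = mean(x$fano))
    }))
    if (length(per_set) >= 2L) {
      combos <- utils::combn(names(per_set), 2L)
      tests <- rbindlist(lapply(seq_len(ncol(combos)), function(i) {
        a <- per_set[[combos[1L, i]]]; b <- per_set[[combos[2L, i]]]
        safe_t <- function(x, y) {
          tryCatch(t.test(x, y)$p.value, error = function(e) NA_real_)
        }
        data.table(set_a = combos[1L, i], set_b = combos[2L, i],
                   p_cv = safe_t(a$cv, b$cv), p_fano = safe_t(a$fano, b$fano))
      }))
    }
  }
  structure(list(per_gene = per_gene, set_summary = set_summary,
                 tests = tests, n_zero_mean = n_zero, n_missing = n_missing),
            class = "plasticity_stats")
}

#' Expression-decile dynamic range between genotypes
#'
#' Bins the wild-type genome-wide expression distribution (for one focal
#' condition) into deciles and reports what proportion of a gene set falls
#' into each decile in each genotype — genes shrinking toward the mean
#' vacate the extreme deciles. The per-genotype spread is summarized as the
#' standard deviation of per-gene mean-centered cross-condition deviations
#' pooled over the set (so for a set shrunk toward each gene's own mean by a
#' factor f, the mutant/WT sd ratio estimates f directly), and equality of
#' those variances is tested with a classical two-tailed F-test. With
#' single-sample (vector) input the sd and F-test use the set's expression
#' values across genes instead.
#'
#' @param wt_expr,mut_expr numeric matrices genes x conditions with matching
#'   rownames (or named vectors for single-sample input).
#' @param gene_set character vector of gene ids.
#' @param condition column (index or name) used for the decile analysis
#'   (default 1).
#' @return A list of class `decile_report`: `deciles` (`data.table` of
#'   decile x genotype proportions for the set), `sd_wt`, `sd_mut`,
#'   `sd_ratio` (mut/wt), `f_test` (htest), `degenerate` flag for sets of
#'   fewer than 2 genes.
#' @export
decile_dynamic_range <- function(wt_expr, mut_expr, gene_set, condition = 1) {
  if (is.vector(wt_expr)) wt_expr <- matrix(wt_expr, ncol = 1,
                                            dimnames = list(names(wt_expr)))
  if (is.vector(mut_expr)) mut_expr <- matrix(mut_expr, ncol = 1,
                                              dimnames = list(names(mut_expr)))
  stopifnot(!is.null(rownames(wt_expr)), !is.null(rownames(mut_expr)))
  common <- intersect(rownames(wt_expr), rownames(mut_expr))
  if (length(common) < 10L) stop("need >= 10 genes shared between genotypes")
  wt_expr <- wt_expr[common, , drop = FALSE]
  mut_expr <- mut_expr[common, , drop = FALSE]
  set_ids <- intersect(gene_set, common)
  degenerate <- length(set_ids) < 2L
  wt_col <- wt_expr[, condition]
  mut_col <- mut_expr[, condition]
  edges <- quantile(wt_col, probs = seq(0, 1, 0.1), names = FALSE)
  edges[1L] <- -Inf; edges[11L] <- Inf
  bin <- function(x) {
    cut(x, breaks = edges, labels = FALSE, include.lowest = TRUE)
  }
  prop <- function(x) {
    if (length(x) == 0L) return(rep(NA_real_, 10L))
    tabulate(bin(x), nbins = 10L) / length(x)
  }
  deciles <- data.table(
    decile = 1:10,
    wt = prop(wt_col[set_ids]),
    mut = prop(mut_col[set_ids])
  )
  if (ncol(wt_expr) >= 2L && !degenerate) {
    center <- function(m) {
      dev <- m[set_ids, , drop = FALSE] -
        rowMeans(m[set_ids, , drop = FALSE])
      as.numeric(dev)
    }
    dev_wt <- center(wt_expr); dev_mut <- center(mut_expr)
    # centering per gene leaves G*(C-1) df per genotype, not G*C - 1
    df_wt <- length(set_ids) * (ncol(wt_expr) - 1L)
    df_mut <- length(set_ids) * (ncol(mut_expr) - 1L)
    s2_wt <- sum(dev_wt^2) / df_wt
    s2_mut <- sum(dev_mut^2) / df_mut
    sd_wt <- sqrt(s2_wt); sd_mut <- sqrt(s2_mut)
    f_test <- if (s2_wt > 0 && s2_mut > 0) {
      f_stat <- s2_mut / s2_wt
      p_lower <- pf(f_stat, df_mut, df_wt)
      structure(
        list(statistic = c(F = f_stat),
             parameter = c(`num df` = df_mut, `denom df` = df_wt),
             p.value = 2 * min(p_lower, 1 - p_lower),
             estimate = c(`ratio of variances` = f_stat),
             method = "F test to compare two variances (per-gene centered)",
             data.name = "mutant vs wild-type centered deviations"),
        class = "htest"
      )
    } else NULL
  } else {
    dev_wt <- wt_col[set_ids]; dev_mut <- mut_col[set_ids]
    sd_wt <- sd(dev_wt); sd_mut <- sd(dev_mut)
    f_test <- if (!degenerate && sd_wt > 0 && sd_mut > 0) {
      var.test(dev_mut, dev_wt)
    } else NULL
  }
  structure(
    list(deciles = deciles, sd_wt = sd_wt, sd_mut = sd_mut,
         sd_ratio = sd_mut / sd_wt, f_test = f_test,
         n_set_genes = length(set_ids), degenerate = degenerate),
    class = "decile_report"
  )
}

#' @export
print.decile_report <- function(x, ...) {
  cat(sprintf(
    "<decile_report> %d genes: sd ratio mut/wt %.3f (F-test p %s)%s\n",
    x$n_set_genes, x$sd_ratio,
    if (is.null(x$f_test)) "NA" else format.pval(x$f_test$p.value),
    if (x$degenerate) " [degenerate set]" else ""
  ))
  invisible(x)
}

#' Per-gene log2 fold change of a focal condition versus all others
#'
#' `log2((focal + pc) / (agg(others) + pc))` per gene, where `agg` is the
#' mean (default) or median over the non-focal conditions — the
#' tissue-specificity axis of the inverse-regression analysis.
#'
#' @param mat numeric matrix genes x conditions.
#' @param focal focal condition (column index or name).
#' @param aggregate `"mean"` or `"median"` over the other conditions.
#' @param pseudocount added to numerator and denominator (default 1; use 0
#'   on strictly positive data for exact identities).
#' @return Named numeric vector.
#' @export
log2_reference_fc <- function(mat, focal, aggregate = c("mean", "median"),
                              pseudocount = 1) {
  aggregate <- match.arg(aggregate)
  stopifnot(is.matrix(mat))
  if (is.character(focal)) focal <- match(focal, colnames(mat))
  others <- mat[, -focal, drop = FALSE]
  agg <- if (aggregate == "mean") rowMeans(others)
         else apply(others, 1L, stats::median)
  setNames(log2((mat[, focal] + pseudocount) / (agg + pseudocount)),
           rownames(mat))
}

#' Per-gene log2 fold change between genotypes
#'
#' Fallback when no externally computed differential-expression table is
#' available: `log2((mut + pc) / (wt + pc))` on normalized per-genotype
#' values (mutant-vs-wild-type contrast convention). Genes with zero
#' coverage in either genotype are set to `NA` and so drop out of the
#' regression.
#'
#' @param wt,mut named numeric vectors of normalized expression.
#' @param pseudocount added to both (default 1).
#' @return Named numeric vector.
#' @export
log2_genotype_fc <- function(wt, mut, pseudocount = 1) {
  common <- intersect(names(wt), names(mut))
  wt <- wt[common]; mut <- mut[common]
  out <- log2((mut + pseudocount) / (wt + pseudocount))
  out[wt == 0 | mut == 0] <- NA_real_
  out
}

#' Tissue-specificity inverse regression
#'
#' Ordinary least squares of the genotype fold change (mutant vs wild type
#' in the focal tissue) on the reference fold change (focal tissue vs all
#' other tissues in wild type). Under loss of expression plasticity the
#' mutant collapses toward the cross-tissue mean, so genes naturally high in
#' the focal tissue go down and low genes go up: slope and Pearson r are
#' negative, reaching exactly -1 under total plasticity loss on noiseless
#' input.
#'
#' @param reference_fc,genotype_fc named numeric vectors
#'   (see [log2_reference_fc()], [log2_genotype_fc()]).
#' @param gene_set optional character vector restricting the regression.
#' @return A list of class `regression_report`: `slope`, `intercept`, `r`
#'   (Pearson), `r_squared`, `p_value`, `n_genes`.
#' @export
tissue_specificity_regression <- function(reference_fc, genotype_fc,
                                          gene_set = NULL) {
  common <- intersect(names(reference_fc), names(genotype_fc))
  if (!is.null(gene_set)) common <- intersect(common, gene_set)
  x <- reference_fc[common]; y <- genotype_fc[common]
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("fewer than 3 genes after filtering")
  if (var(y) == 0) {
    # flat response: no relationship by definition
    return(structure(list(slope = 0, intercept = unname(y[1L]), r = 0,
                          r_squared = 0, p_value = NA_real_,
                          n_genes = length(x)),
                     class = "regression_report"))
  }
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
         r = unname(cor(x, y)), r_squared = sm$r.squared,
         p_value = unname(sm$coefficients[2L, 4L]), n_genes = length(x)),
    class = "regression_report"
  )
}

#' @export
print.regression_report <- function(x, ...) {
  cat(sprintf(
    "<regression_report> n=%d: slope %.3f, r %.3f, R^2 %.3f, p %s\n",
    x$n_genes, x$slope, x$r, x$r_squared, format.pval(x$p_value)
  ))
  invisible(x)
}

#' Plasticity of genes near intergenic DMRs (control analysis)
#'
#' Compares the expression plasticity (CV, Fano) of genes whose only DMR
#' association is a 2-kb flank — i.e. genes near intergenic demethylase
#' targets — against all genes, to check that any plasticity signal is
#' specific to gene-body targets rather than a byproduct of demethylase
#' activity nearby.
#'
#' @param associations [associate_dmrs()] output.
#' @param mat numeric expression matrix genes x conditions.
#' @return A list of class `plasticity_stats` (flank vs total sets) with an
#'   extra `flank_genes` element.
#' @export
intergenic_control <- function(associations, mat) {
  a <- as.data.table(associations)
  flank <- unique(a[relation %in% c("flank_2kb_upstream",
                                    "flank_2kb_downstream"), gene_id])
  body_genes <- unique(a[relation == "gene_body", gene_id])
  flank <- setdiff(flank, body_genes)
  if (length(flank) == 0L) stop("no flank-only DMR-associated genes")
  res <- plasticity_stats(mat, gene_sets = list(
    flank = flank, total = rownames(mat)
  ))
  res$flank_genes <- flank
  res
}
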