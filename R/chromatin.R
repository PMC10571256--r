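#' Read a bedGraph coverage track
#'
#' @param path path to a 4-column bedGraph (chrom, start, end, depth;
#'   0-based half-open).
#' @return `data.table` with columns `chrom`, `start`, `end`, `depth`.
#' @export
read_bedgraph <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "bedGraph")
  data.table(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,
    end = BiocGenerics::end(gr),
    depth = as.numeric(gr$score)
  )
}

#' Normalize a coverage track to log2 fold enrichment
#'
#' Each position's depth is expressed as log2 fold enrichment over the
#' genome-wide average depth (the per-bp mean over the track). A pseudocount
#' is added to both numerator and denominator so zero-depth positions stay
#' finite.
#'
#' @param track `data.table`/data.frame with `chrom`, `start`, `end`
#'   (0-based half-open), `depth`.
#' @param pseudocount added to depth and mean (default 0.5).
#' @return The track with a `value` column (log2 enrichment) and a
#'   `genomic_mean` attribute; class `normalized_track`.
#' @export
normalize_track <- function(track, pseudocount = 0.5) {
  t <- as.data.table(track)
  stopifnot(all(c("chrom", "start", "end", "depth") %in% names(t)))
  if (nrow(t) == 0L) stop("empty track")
  if (any(t$depth < 0)) stop("depths must be non-negative")
  w <- t$end - t$start
  mean_depth <- sum(t$depth * w) / sum(w)
  if (mean_depth == 0) stop("all-zero track: cannot normalize")
  t[, value := log2((depth + pseudocount) / (mean_depth + pseudocount))]
  setattr(t, "genomic_mean", mean_depth)
  setattr(t, "class", c("normalized_track", class(t)))
  t[]
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean(x) - mean(y)) / s_pooled` with the
#' pooled standard deviation
#' `sqrt(((n1-1) s1^2 + (n2-1) s2^2) / (n1 + n2 - 2))`.
#'
#' @param x,y numeric vectors.
#' @return Cohen's d (0 when both groups have zero pooled variance).
#' @export
cohens_d <- function(x, y) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 2L || n2 < 2L) stop("cohens_d needs >= 2 finite values per group")
  sp <- sqrt(((n1 - 1) * var(x) + (n2 - 1) * var(y)) / (n1 + n2 - 2))
  if (sp == 0) return(0)
  (mean(x) - mean(y)) / sp
}

# internal: per-feature mean of a piecewise-constant track value,
# bp-weighted over the overlap
.feature_means <- function(track, features) {
  f <- as.data.table(features)
  if (nrow(f) == 0L) return(numeric())
  f[, feature_idx := .I]
  t_gr <- .as_granges(track)
  f_gr <- .as_granges(f)
  ov <- GenomicRanges::findOverlaps(t_gr, f_gr)
  means <- rep(NA_real_, nrow(f))
  if (length(ov) > 0L) {
    inter <- GenomicRanges::pintersect(t_gr[queryHits(ov)],
                                       f_gr[subjectHits(ov)])
    dt <- data.table(
      feature_idx = subjectHits(ov),
      value = track$value[queryHits(ov)],
      width_bp = IRanges::width(inter)
    )
    agg <- dt[, .(mean_value = sum(value * width_bp) / sum(width_bp)),
              by = feature_idx]
    means[agg$feature_idx] <- agg$mean_value
  }
  means
}

#' Feature-set enrichment on a normalized track
#'
#' Averages the normalized (log2-enrichment) signal over each feature
#' (bp-weighted), groups features by set, and reports the per-set
#' distributions together with pairwise Cohen's d effect sizes and Welch
#' two-tailed t-tests between sets.
#'
#' @param track a [normalize_track()] result.
#' @param feature_sets named list of interval tables (`chrom`, `start`,
#'   `end`; 0-based half-open), e.g. exons overlapping Dynamic vs Stable GbM
#'   domains and total exons.
#' @return A list of class `feature_enrichment`: `per_feature`
#'   (`data.table` of `group`, `mean_value`), `group_means`, `pairs`
#'   (`data.table` of `group_a`, `group_b`, `cohens_d`, `p_value`).
#' @export
feature_enrichment <- function(track, feature_sets) {
  stopifnot(inherits(track, "normalized_track"), is.list(feature_sets),
            !is.null(names(feature_sets)))
  per_feature <- rbindlist(lapply(names(feature_sets), function(g) {
    f <- as.data.table(feature_sets[[g]])
    if (nrow(f) == 0L) stop("empty feature group: ", g)
    data.table(group = g, mean_value = .feature_means(track, f))
  }))
  per_feature <- per_feature[is.finite(mean_value)]
  groups <- names(feature_sets)
  for (g in groups) {
    if (nrow(per_feature[group == g]) == 0L) {
      stop("no features of group '", g, "' overlap the track")
    }
  }
  group_means <- vapply(groups, function(g) {
    mean(per_feature[group == g, mean_value])
  }, 0)
  combos <- if (length(groups) >= 2L) utils::combn(groups, 2L) else NULL
  pairs <- if (!is.null(combos)) {
    rbindlist(lapply(seq_len(ncol(combos)), function(i) {
      a <- per_feature[group == combos[1L, i], mean_value]
      b <- per_feature[group == combos[2L, i], mean_value]
      data.table(
        group_a = combos[1L, i], group_b = combos[2L, i],
        cohens_d = cohens_d(a, b),
        p_value = tryCatch(t.test(a, b)$p.value, error = function(e) NA_real_)
      )
    }))
  } else {
    data.table(group_a = character(), group_b = character(),
               cohens_d = numeric(), p_value = numeric())
  }
  structure(list(per_feature = per_feature, group_means = group_means,
                 pairs = pairs),
            class = "feature_enrichment")
}

#' Enrichment by gene-length bin
#'
#' Splits genes into length bins and compares per-class mean enrichment
#' within each bin (Welch two-tailed t-test for each class pair), to
#' separate class effects from gene-length effects. Empty bins are skipped
#' with a warning.
#'
#' @param track a [normalize_track()] result.
#' @param genes a [gene_models()] table.
#' @param classes named list of gene id vectors (e.g.
#'   `list(dynamic = ..., stable = ...)`).
#' @param bin_edges numeric vector of gene-length bin edges in bp.
#' @return `data.table`: one row per bin x class with `bin`, `class`, `n`,
#'   `mean_value`, plus attribute `tests` (per-bin pairwise t-tests).
#' @export
length_binned_enrichment <- function(track, genes, classes, bin_edges) {
  stopifnot(inherits(genes, "gene_models"), length(bin_edges) >= 2L)
  g <- as.data.table(genes)
  g[, mean_value := .feature_means(track, g)]
  g[, len := end - start]
  g[, bin := cut(len, breaks = bin_edges, include.lowest = TRUE)]
  rows <- list(); tests <- list()
  for (b in levels(g$bin)) {
    gb <- g[bin == b & !is.na(mean_value)]
    if (nrow(gb) == 0L) {
      warning("empty length bin skipped: ", b)
      next
    }
    vals <- lapply(classes, function(ids) gb[gene_id %in% ids, mean_value])
    for (cl in names(classes)) {
      rows[[length(rows) + 1L]] <- data.table(
        bin = b, class = cl, n = length(vals[[cl]]),
        mean_value = if (length(vals[[cl]]) > 0L) mean(vals[[cl]]) else NA_real_
      )
    }
    if (length(classes) >= 2L) {
      combos <- utils::combn(names(classes), 2L)
      for (i in seq_len(ncol(combos))) {
        a <- vals[[combos[1L, i]]]; bb <- vals[[combos[2L, i]]]
        tests[[length(tests) + 1L]] <- data.table(
          bin = b, class_a = combos[1L, i], class_b = combos[2L, i],
          p_value = if (length(a) >= 2L && length(bb) >= 2L) {
            tryCatch(t.test(a, bb)$p.value, error = function(e) NA_real_)
          } else NA_real_
        )
      }
    }
  }
  out <- rbindlist(rows)
  setattr(out, "tests", rbindlist(tests))
  out[]
}

#' Overlap of gene sets with a chromatin-state partition
#'
#' For each gene set and state, the total base-pair overlap (interval
#' intersection) and the percentage of the set's gene-body bp in that state.
#' When the states partition the annotated genome the percentages per set
#' sum to 100.
#'
#' @param gene_sets named list of interval tables (`chrom`, `start`, `end`,
#'   0-based half-open), e.g. Dynamic and Stable GbM gene bodies.
#' @param states interval table with a `state` column; states must not
#'   overlap one another (validation error otherwise).
#' @return `data.table` of class `state_overlap`: `set`, `state`, `bp`,
#'   `percent` (of the set's total bp).
#' @export
state_overlap <- function(gene_sets, states) {
  st <- as.data.table(states)
  stopifnot(all(c("chrom", "start", "end", "state") %in% names(st)))
  st_gr <- .as_granges(st)
  self_ov <- GenomicRanges::findOverlaps(st_gr, st_gr)
  if (length(self_ov) > length(st_gr)) {
    stop("chromatin states overlap one another: not a valid partition")
  }
  out <- rbindlist(lapply(names(gene_sets), function(set_name) {
    g <- as.data.table(gene_sets[[set_name]])
    if (nrow(g) == 0L) {
      return(data.table(set = set_name, state = unique(st$state), bp = 0L,
                        percent = NA_real_))
    }
    g_gr <- GenomicRanges::reduce(.as_granges(g))
    total_bp <- sum(IRanges::width(g_gr))
    ov <- GenomicRanges::findOverlaps(g_gr, st_gr)
    bp_by_state <- setNames(rep(0, length(unique(st$state))),
                            unique(st$state))
    if (length(ov) > 0L) {
      inter <- GenomicRanges::pintersect(g_gr[queryHits(ov)],
                                         st_gr[subjectHits(ov)])
      dt <- data.table(state = st$state[subjectHits(ov)],
                       bp = IRanges::width(inter))
      agg <- dt[, .(bp = sum(bp)), by = state]
      bp_by_state[agg$state] <- agg$bp
    }
    data.table(set = set_name, state = names(bp_by_state),
               bp = as.numeric(bp_by_state),
               percent = 100 * as.numeric(bp_by_state) / total_bp)
  }))
  setattr(out, "class", c("state_overlap", class(out)))
  out[]
}

#' Overlap between two gene lists
#'
#' Set-intersection utility, e.g. for intersecting a classified gene set
#' with an externally defined enriched-gene list.
#'
#' @param set_a,set_b character vectors of gene ids.
#' @return A list with `n_a`, `n_b`, `n_overlap`, `overlap` (the shared
#'   ids), and `fraction_a` (`n_overlap / n_a`).
#' @export
gene_set_overlap <- function(set_a, set_b) {
  ov <- intersect(set_a, set_b)
  list(n_a = length(set_a), n_b = length(set_b), n_overlap = length(ov),
       overlap = ov, fraction_a = length(ov) / max(1L, length(set_a)))
}
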