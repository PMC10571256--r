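#' Differential CG sites between two methylomes
#'
#' Joins the pooled CG sites of a reference and an alternative methylome and
#' retains sites covered in both whose heterogeneity fractions differ by at
#' least `min_delta` percentage points. `delta` is signed `b - a` (alternative
#' minus reference), so in a WT-vs-eraser-mutant comparison positive deltas
#' are methylation gains in the mutant.
#'
#' @param a,b pooled CG sites ([pool_cg_dinucleotides()]) of the reference
#'   (`a`) and alternative (`b`) sample.
#' @param min_coverage minimum pooled reads required in both samples
#'   (default 5).
#' @param min_delta minimum absolute difference in percentage points
#'   (default 20).
#' @return `data.table` of class `diff_sites`: `chrom`, `start` (1-based
#'   forward-strand C), `delta` (pp), `direction` (`hyper`/`hypo`),
#'   `n_total_a`, `n_total_b`, `h_a`, `h_b`.
#' @export
differential_sites <- function(a, b, min_coverage = 5, min_delta = 20) {
  a <- as.data.table(a)
  b <- as.data.table(b)
  m <- merge(a[, .(chrom, start, h_a = h, n_total_a = n_total)],
             b[, .(chrom, start, h_b = h, n_total_b = n_total)],
             by = c("chrom", "start"))
  m <- m[n_total_a >= min_coverage & n_total_b >= min_coverage &
           !is.na(h_a) & !is.na(h_b)]
  if (nrow(m) == 0L) {
    warning("no CG sites covered >= ", min_coverage, " in both samples")
  }
  m[, delta := 100 * (h_b - h_a)]
  m <- m[abs(delta) >= min_delta]
  m[, direction := ifelse(delta > 0, "hyper", "hypo")]
  setkey(m, chrom, start)
  out <- m[, .(chrom, start, delta, direction, n_total_a, n_total_b, h_a, h_b)]
  setattr(out, "class", c("diff_sites", class(out)))
  out[]
}

# internal: seed-window scan for one chromosome and one direction.
# pos0: sorted 0-based site starts. Windows of width window_bp are anchored on
# the step_bp grid; a window is a seed when it holds >= min_sites sites;
# overlapping/touching seeds are merged and the merged span trimmed to its
# outermost member sites. Returns list of integer index ranges into pos0.
.dmr_scan <- function(pos0, window_bp, step_bp, min_sites) {
  n <- length(pos0)
  if (n < min_sites) return(list())
  starts <- seq(0L, max(pos0), by = step_bp)
  # sites in window [w, w + window_bp): counts via sorted positions
  lo <- findInterval(starts - 1L, pos0) + 1L          # first site >= w
  hi <- findInterval(starts + window_bp - 1L, pos0)   # last site < w + window
  counts <- hi - lo + 1L
  seed <- which(counts >= min_sites)
  if (length(seed) == 0L) return(list())
  w_start <- starts[seed]
  w_end <- w_start + window_bp
  # merge overlapping or touching seed windows
  merged <- list()
  cur_s <- w_start[1L]; cur_e <- w_end[1L]
  for (i in seq_along(w_start)[-1L]) {
    if (w_start[i] <= cur_e) {
      cur_e <- max(cur_e, w_end[i])
    } else {
      merged[[length(merged) + 1L]] <- c(cur_s, cur_e)
      cur_s <- w_start[i]; cur_e <- w_end[i]
    }
  }
  merged[[length(merged) + 1L]] <- c(cur_s, cur_e)
  lapply(merged, function(m) {
    i1 <- findInterval(m[1L] - 1L, pos0) + 1L
    i2 <- findInterval(m[2L] - 1L, pos0)
    c(i1, i2)
  })
}

#' Call differentially methylated regions
#'
#' Aggregates same-direction differential CGs within overlapping fixed-width
#' windows (default 200 bp stepping 100 bp). A window holding at least
#' `min_sites` same-direction sites seeds a region; overlapping or touching
#' same-direction seeds merge, and each region is trimmed to its outermost
#' member sites (window-edge spans would inflate downstream overlap
#' statistics). Hyper and hypo regions are called independently.
#'
#' @param dsites differential sites from [differential_sites()].
#' @param window_bp window width in bp (default 200).
#' @param step_bp grid step between window starts (default 100, i.e. windows
#'   overlap by half).
#' @param min_sites minimum same-direction differential CGs per seed window
#'   (default 5).
#' @return `data.table` of class `dmr_table`: `chrom`, `start`, `end`
#'   (0-based half-open, covering member dinucleotides), `n_diff_sites`,
#'   `mean_delta` (pp), `direction`. Regions of one direction never overlap.
#' @export
call_dmrs <- function(dsites, window_bp = 200, step_bp = 100, min_sites = 5) {
  d <- as.data.table(dsites)
  empty <- data.table(chrom = character(), start = integer(), end = integer(),
                      n_diff_sites = integer(), mean_delta = numeric(),
                      direction = character())
  if (nrow(d) == 0L) {
    setattr(empty, "class", c("dmr_table", class(empty)))
    return(empty[])
  }
  setorder(d, chrom, start)
  res <- d[, {
    pos0 <- start - 1L  # 0-based dinucleotide start
    spans <- .dmr_scan(pos0, window_bp, step_bp, min_sites)
    if (length(spans) == 0L) {
      data.table(start = integer(), end = integer(),
                 n_diff_sites = integer(), mean_delta = numeric())
    } else {
      rbindlist(lapply(spans, function(ix) {
        sel <- ix[1L]:ix[2L]
        data.table(start = pos0[ix[1L]],
                   end = pos0[ix[2L]] + 2L,  # dinucleotide is 2 bp
                   n_diff_sites = length(sel),
                   mean_delta = mean(delta[sel]))
      }))
    }
  }, by = .(chrom, direction)]
  setcolorder(res, c("chrom", "start", "end", "n_diff_sites", "mean_delta",
                     "direction"))
  setorder(res, chrom, start, direction)
  setattr(res, "class", c("dmr_table", class(res)))
  res[]
}

#' Associate DMRs with gene bodies and 2-kb flanks
#'
#' Each DMR overlapping a gene body yields a `gene_body` association for that
#' gene; a DMR not touching a given gene's body but overlapping its
#' strand-aware 2-kb flank yields a `flank_2kb_upstream` or
#' `flank_2kb_downstream` association. One DMR may associate with several
#' genes.
#'
#' @param dmrs a [call_dmrs()] table.
#' @param genes a [gene_models()] table.
#' @param flank_bp flank width in bp (default 2000).
#' @return `data.table` with `gene_id`, `relation`, `dmr_chrom`, `dmr_start`,
#'   `dmr_end`, `direction`, `mean_delta`.
#' @export
associate_dmrs <- function(dmrs, genes, flank_bp = 2000) {
  stopifnot(inherits(genes, "gene_models"))
  d <- as.data.table(dmrs)
  empty <- data.table(gene_id = character(), relation = character(),
                      dmr_chrom = character(), dmr_start = integer(),
                      dmr_end = integer(), direction = character(),
                      mean_delta = numeric())
  if (nrow(d) == 0L || nrow(genes) == 0L) return(empty)
  dmr_gr <- .as_granges(d)
  hit_tab <- function(region_dt, relation) {
    keep <- region_dt$start < region_dt$end
    region_dt <- region_dt[keep]
    if (nrow(region_dt) == 0L) return(empty)
    ov <- GenomicRanges::findOverlaps(dmr_gr, .as_granges(region_dt))
    if (length(ov) == 0L) return(empty)
    data.table(
      gene_id = region_dt$gene_id[subjectHits(ov)],
      relation = relation,
      dmr_chrom = d$chrom[queryHits(ov)],
      dmr_start = d$start[queryHits(ov)],
      dmr_end = d$end[queryHits(ov)],
      direction = d$direction[queryHits(ov)],
      mean_delta = d$mean_delta[queryHits(ov)]
    )
  }
  g <- as.data.table(genes)
  body <- hit_tab(g, "gene_body")
  up <- g[, .(gene_id, chrom,
              start = ifelse(strand == "+", pmax(0L, start - flank_bp), end),
              end = ifelse(strand == "+", start, end + flank_bp))]
  down <- g[, .(gene_id, chrom,
                start = ifelse(strand == "+", end, pmax(0L, start - flank_bp)),
                end = ifelse(strand == "+", end + flank_bp, start))]
  upstream <- hit_tab(up, "flank_2kb_upstream")
  downstream <- hit_tab(down, "flank_2kb_downstream")
  # a gene's flank association is suppressed when the same DMR already
  # touches that gene's body
  key_of <- function(x) paste(x$gene_id, x$dmr_chrom, x$dmr_start, x$dmr_end)
  flanks <- rbind(upstream, downstream)
  flanks <- flanks[!key_of(flanks) %in% key_of(body)]
  out <- rbind(body, flanks)
  setorder(out, gene_id, dmr_chrom, dmr_start)
  out[]
}

#' Write DMRs as BED6+
#'
#' Columns: chrom, start, end, name, score (`n_diff_sites`), strand (`.`),
#' then `direction` and `mean_delta`.
#'
#' @param dmrs a [call_dmrs()] table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_dmr_bed <- function(dmrs, path) {
  d <- as.data.table(dmrs)
  out <- d[, .(chrom, start, end,
               name = sprintf("DMR_%04d", .I),
               score = n_diff_sites, strand = ".",
               direction, mean_delta = signif(mean_delta, 6))]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
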