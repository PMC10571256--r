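# independent brute-force oracle for DMR calling: enumerates every window on
# the step grid with naive per-window counting, merges seed windows by span
# arithmetic, and trims to member sites. Shares no code with call_dmrs.
oracle_dmrs <- function(dsites, window_bp = 200, step_bp = 100,
                        min_sites = 5) {
  d <- as.data.frame(dsites)
  out <- list()
  for (cn in unique(d$chrom)) {
    for (dir in unique(d$direction[d$chrom == cn])) {
      pos0 <- sort(d$start[d$chrom == cn & d$direction == dir] - 1L)
      deltas <- d$delta[d$chrom == cn & d$direction == dir][
        order(d$start[d$chrom == cn & d$direction == dir])]
      if (length(pos0) == 0L) next
      seeds <- list()
      for (w in seq(0L, max(pos0), by = step_bp)) {
        n_in <- 0L
        for (p in pos0) if (p >= w && p < w + window_bp) n_in <- n_in + 1L
        if (n_in >= min_sites) seeds[[length(seeds) + 1L]] <- c(w, w + window_bp)
      }
      if (length(seeds) == 0L) next
      # merge overlapping/touching seed windows
      merged <- list(seeds[[1L]])
      for (s in seeds[-1L]) {
        last <- merged[[length(merged)]]
        if (s[1L] <= last[2L]) {
          merged[[length(merged)]] <- c(last[1L], max(last[2L], s[2L]))
        } else {
          merged[[length(merged) + 1L]] <- s
        }
      }
      for (m in merged) {
        inside <- pos0 >= m[1L] & pos0 < m[2L]
        out[[length(out) + 1L]] <- data.frame(
          chrom = cn, start = min(pos0[inside]),
          end = max(pos0[inside]) + 2L,
          n_diff_sites = sum(inside),
          mean_delta = mean(deltas[inside]),
          direction = dir
        )
      }
    }
  }
  if (length(out) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), n_diff_sites = integer(),
                      mean_delta = numeric(), direction = character()))
  }
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start, res$direction), , drop = FALSE]
}

# random differential-site instance for oracle comparisons
random_diff_instance <- function(n_max = 50) {
  n <- sample(1:n_max, 1L)
  starts <- sort(sample(1:3000, n))
  starts <- starts[c(TRUE, diff(starts) >= 2L)]  # dinucleotides cannot abut
  n <- length(starts)
  d <- data.table::data.table(
    chrom = sample(c("ChrA", "ChrB"), n, replace = TRUE),
    start = starts,
    delta = sample(c(-1, 1), n, replace = TRUE) * runif(n, 20, 100)
  )
  d[, direction := ifelse(delta > 0, "hyper", "hypo")]
  d
}

# canonical comparison form
dmr_key <- function(x) {
  df <- as.data.frame(x)[, c("chrom", "start", "end", "n_diff_sites",
                             "direction", "mean_delta")]
  df <- df[order(df$chrom, df$start, df$direction), , drop = FALSE]
  rownames(df) <- NULL
  df$mean_delta <- round(df$mean_delta, 9)
  df
}

# recursively strip data.table self-reference pointers so deterministic
# results can be compared with identical()
strip_ptrs <- function(x) {
  if (data.table::is.data.table(x)) {
    return(as.data.frame(x))
  }
  if (is.list(x) && !is.object(x)) {
    return(lapply(x, strip_ptrs))
  }
  if (is.list(x)) {
    attrs <- attributes(x)
    out <- lapply(unclass(x), strip_ptrs)
    for (a in setdiff(names(attrs), "names")) attr(out, a) <- attrs[[a]]
    return(out)
  }
  x
}
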