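uniform_track <- function(depth = 40, n = 50, bin = 100L) {
  data.table::data.table(
    chrom = "Chr1", start = bin * (seq_len(n) - 1L),
    end = bin * seq_len(n), depth = depth
  )
}

test_that("track normalization is log2 relative to the genomic average", {
  t <- normalize_track(uniform_track(), pseudocount = 0)
  expect_equal(t$value, rep(0, nrow(t)))

  # one bin at 4x balanced by three empty bins keeps the genomic mean at 100
  tr <- uniform_track(depth = 100)
  tr$depth[3] <- 400
  tr$depth[c(10, 11, 12)] <- 0
  expect_equal(mean(tr$depth), 100)
  nt <- normalize_track(tr, pseudocount = 0)
  expect_equal(nt$value[3], 2)

  # a half-mean bin balanced by a 1.5x bin sits at exactly -1
  t2 <- uniform_track(depth = 100)
  t2$depth[1] <- 50; t2$depth[2] <- 150
  n2 <- normalize_track(t2, pseudocount = 0)
  expect_equal(n2$value[1], -1)

  expect_error(normalize_track(uniform_track(depth = 0)), "all-zero")
})

test_that("pseudocount keeps zero-depth positions finite", {
  tr <- uniform_track(depth = 100)
  tr$depth[5] <- 0
  nt <- normalize_track(tr)  # default pseudocount 0.5
  expect_true(all(is.finite(nt$value)))
  expect_lt(nt$value[5], -7)
})

test_that("Cohen's d matches its analytic construction", {
  x <- c(0, 1, 2)
  y <- c(1, 2, 3)  # var 1 each, pooled sd 1, mean difference 1
  expect_equal(cohens_d(y, x), 1)
  expect_equal(cohens_d(x, y), -1)
  expect_equal(cohens_d(x, x), 0)
  # zero-variance groups
  expect_equal(cohens_d(c(2, 2, 2), c(2, 2)), 0)
})

test_that("feature enrichment recovers painted class differences", {
  cfg <- small_sim(seed = 19)
  meth <- simulate_methylomes(cfg)
  chip <- simulate_chip(cfg, meth$genes, meth$truth)
  nt <- normalize_track(chip$regulatory)
  g <- data.table::as.data.table(meth$genes)
  dyn <- meth$truth$genes[class == "dynamic", gene_id]
  stab <- meth$truth$genes[class == "stable", gene_id]
  fs <- list(dynamic = g[gene_id %in% dyn, .(chrom, start, end)],
             stable = g[gene_id %in% stab, .(chrom, start, end)])
  fe <- feature_enrichment(nt, fs)
  # multiplier 4 painted on dynamic bodies: ~2 log2 units above stable
  diff <- fe$group_means["dynamic"] - fe$group_means["stable"]
  expect_equal(unname(diff), 2, tolerance = 0.15)
  expect_gt(abs(fe$pairs$cohens_d), 2)

  # identical groups: d = 0 by definition
  same <- feature_enrichment(nt, list(a = fs$dynamic, b = fs$dynamic))
  expect_equal(same$pairs$cohens_d, 0)
  expect_error(feature_enrichment(nt, list(a = fs$dynamic[0])), "empty")
})

test_that("a uniform track gives zero means and zero effect size", {
  nt <- normalize_track(uniform_track(), pseudocount = 0)
  fs <- list(
    a = data.frame(chrom = "Chr1", start = c(0, 600), end = c(400, 900)),
    b = data.frame(chrom = "Chr1", start = c(1000, 2000), end = c(1500, 2400))
  )
  fe <- feature_enrichment(nt, fs)
  expect_equal(unname(fe$group_means), c(0, 0))
  expect_equal(fe$pairs$cohens_d, 0)
})

test_that("length-binned enrichment reduces to plain enrichment in one bin", {
  cfg <- small_sim(seed = 23)
  meth <- simulate_methylomes(cfg)
  chip <- simulate_chip(cfg, meth$genes, meth$truth)
  nt <- normalize_track(chip$regulatory)
  dyn <- meth$truth$genes[class == "dynamic", gene_id]
  stab <- meth$truth$genes[class == "stable", gene_id]
  g <- data.table::as.data.table(meth$genes)
  lbe <- length_binned_enrichment(nt, meth$genes,
                                  classes = list(dynamic = dyn,
                                                 stable = stab),
                                  bin_edges = c(0, Inf))
  fe <- feature_enrichment(nt, list(
    dynamic = g[gene_id %in% dyn, .(chrom, start, end)],
    stable = g[gene_id %in% stab, .(chrom, start, end)]
  ))
  expect_equal(lbe[lbe$class == "dynamic", ]$mean_value,
               unname(fe$group_means["dynamic"]))
  expect_equal(lbe[lbe$class == "stable", ]$mean_value,
               unname(fe$group_means["stable"]))
})

test_that("identically painted classes show no per-bin difference", {
  # null: enrichment independent of class
  set.seed(5)
  n <- 60
  starts <- (0:(n - 1)) * 2000L
  lens <- sample(c(500L, 1000L, 1500L), n, replace = TRUE)
  genes <- gene_models(data.frame(
    gene_id = paste0("g", 1:n), chrom = "Chr1", start = starts,
    end = starts + lens, strand = "+"
  ))
  tr <- data.table::data.table(
    chrom = "Chr1", start = seq(0L, max(starts + lens), by = 100L)
  )
  tr[, end := start + 100L]
  tr[, depth := rpois(.N, 50)]
  nt <- normalize_track(tr)
  classes <- list(a = paste0("g", 1:30), b = paste0("g", 31:60))
  lbe <- length_binned_enrichment(nt, genes, classes,
                                  bin_edges = c(0, 750, 1250, Inf))
  tests <- attr(lbe, "tests")
  expect_gt(min(tests$p_value), 0.01)
})

test_that("state overlap percentages behave as interval arithmetic", {
  states <- data.frame(
    chrom = "Chr1", start = c(0, 1000, 2000), end = c(1000, 2000, 3000),
    state = c("s1", "s2", "s3")
  )
  sets <- list(
    inside = data.frame(chrom = "Chr1", start = 100, end = 900),
    split = data.frame(chrom = "Chr1", start = 1500, end = 2500),
    empty = data.frame(chrom = character(), start = numeric(),
                       end = numeric())
  )
  so <- state_overlap(sets, states)
  expect_equal(so[so$set == "inside" & so$state == "s1", ]$percent, 100)
  expect_equal(so[so$set == "split" & so$state == "s2", ]$percent, 50)
  expect_equal(so[so$set == "split" & so$state == "s3", ]$percent, 50)
  expect_true(all(is.na(so[so$set == "empty", ]$percent)))
  # per-set totals are 100 when the states cover the sets
  tot <- tapply(so$percent, so$set, sum)
  expect_equal(as.numeric(tot[c("inside", "split")]), c(100, 100))

  bad <- rbind(states,
               data.frame(chrom = "Chr1", start = 500, end = 1500,
                          state = "s4"))
  expect_error(state_overlap(sets, bad), "partition")
})

test_that("simulated chromatin states partition the annotated genome", {
  cfg <- small_sim(seed = 29)
  meth <- simulate_methylomes(cfg)
  chip <- simulate_chip(cfg, meth$genes, meth$truth)
  g <- data.table::as.data.table(meth$genes)
  sets <- list(all_genes = g[, .(chrom, start, end)])
  so <- state_overlap(sets, chip$states)
  expect_equal(sum(so$percent), 100, tolerance = 1e-9)
})

test_that("gene list intersection reports counts both ways", {
  r <- gene_set_overlap(c("a", "b", "c"), c("b", "c", "d", "e"))
  expect_equal(r$n_overlap, 2L)
  expect_equal(r$fraction_a, 2 / 3)
  expect_setequal(r$overlap, c("b", "c"))
})
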