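test_that("CV and Fano follow their definitions and scaling laws", {
  mat <- rbind(
    flat = rep(7, 10),
    var1 = c(2, 4, 6, 8, 10, 2, 4, 6, 8, 10)
  )
  ps <- plasticity_stats(mat)
  flat <- ps$per_gene[ps$per_gene$gene_id == "flat", ]
  expect_equal(flat$cv, 0)
  expect_equal(flat$fano, 0)

  # doubling: CV invariant, Fano doubles (exactly)
  ps2 <- plasticity_stats(2 * mat)
  v1 <- ps$per_gene[ps$per_gene$gene_id == "var1", ]
  v2 <- ps2$per_gene[ps2$per_gene$gene_id == "var1", ]
  expect_equal(v2$cv, v1$cv)
  expect_equal(v2$fano, 2 * v1$fano)

  # random-matrix property version
  set.seed(33)
  m <- matrix(rexp(200, 1 / 50), 20, 10,
              dimnames = list(paste0("g", 1:20), NULL))
  a <- plasticity_stats(m)$per_gene
  b <- plasticity_stats(3.7 * m)$per_gene
  expect_equal(b$cv, a$cv)
  expect_equal(b$fano, 3.7 * a$fano)
})

test_that("the Fano factor of Poisson counts is 1", {
  set.seed(101)
  mat <- matrix(rpois(10000, 10), nrow = 1,
                dimnames = list("g", NULL))
  f <- plasticity_stats(mat)$per_gene$fano
  expect_equal(f, 1, tolerance = 0.05)
})

test_that("zero-mean genes are flagged, not divided by", {
  mat <- rbind(zero = rep(0, 5), ok = 1:5)
  ps <- plasticity_stats(mat)
  expect_equal(ps$n_zero_mean, 1L)
  expect_true(is.na(ps$per_gene[ps$per_gene$gene_id == "zero", ]$cv))
})

test_that("set comparisons respect the exclusion list", {
  set.seed(55)
  mat <- matrix(rexp(300, 1 / 20), 30, 10,
                dimnames = list(paste0("g", 1:30), NULL))
  sets <- list(a = paste0("g", 1:10), b = paste0("g", 11:20))
  ps <- plasticity_stats(mat, gene_sets = sets, exclude = paste0("g", 1:5))
  expect_equal(ps$set_summary[ps$set_summary$set == "a", ]$n, 5L)
  expect_equal(nrow(ps$tests), 1L)
})

test_that("replicate averaging collapses to condition columns", {
  mat <- matrix(c(1, 3, 10, 20), nrow = 1,
                dimnames = list("g", c("s1", "s2", "s3", "s4")))
  md <- data.frame(sample = paste0("s", 1:4),
                   condition = c("c1", "c1", "c2", "c2"))
  avg <- average_replicates(mat, md)
  expect_equal(unname(avg["g", ]), c(2, 15))
})

test_that("identical genotypes give identical deciles and F-test p = 1", {
  set.seed(77)
  wt <- matrix(rnorm(600, 100, 10), 60, 10,
               dimnames = list(paste0("g", 1:60), NULL))
  r <- decile_dynamic_range(wt, wt, paste0("g", 1:20))
  expect_equal(r$deciles$wt, r$deciles$mut)
  expect_equal(r$sd_ratio, 1)
  expect_equal(r$f_test$p.value, 1)
})

test_that("noiseless affine shrinkage recovers the factor exactly", {
  set.seed(78)
  wt <- matrix(rnorm(600, 100, 10), 60, 10,
               dimnames = list(paste0("g", 1:60), NULL))
  mut <- rowMeans(wt) + 0.7 * (wt - rowMeans(wt))
  r <- decile_dynamic_range(wt, mut, paste0("g", 1:30))
  expect_equal(r$sd_ratio, 0.7)
  expect_lt(r$f_test$p.value, 1e-6)
  # shrinkage empties the extreme deciles
  extremes <- r$deciles$decile %in% c(1, 10)
  expect_lte(sum(r$deciles$mut[extremes]), sum(r$deciles$wt[extremes]))
})

test_that("genome-wide WT deciles are uniform by construction", {
  set.seed(79)
  wt <- matrix(rnorm(1000, 100, 10), 100, 10,
               dimnames = list(paste0("g", 1:100), NULL))
  r <- decile_dynamic_range(wt, wt, paste0("g", 1:100))
  expect_equal(r$deciles$wt, rep(0.1, 10))
})

test_that("degenerate sets and tiny universes are handled explicitly", {
  wt <- matrix(rnorm(120, 100, 10), 12, 10,
               dimnames = list(paste0("g", 1:12), NULL))
  r <- decile_dynamic_range(wt, wt, "g1")
  expect_true(r$degenerate)
  expect_null(r$f_test)
  expect_error(decile_dynamic_range(wt[1:5, ], wt[1:5, ], "g1"), ">= 10")
})

test_that("total plasticity loss gives the exact inverse identity", {
  set.seed(91)
  wt <- matrix(rexp(540, 1 / 100) + 1, 54, 10,
               dimnames = list(paste0("g", 1:54), NULL))
  # focal condition 1; mutant sits at the mean of the other conditions
  ref <- log2_reference_fc(wt, focal = 1, pseudocount = 0)
  mut_focal <- rowMeans(wt[, -1])
  gfc <- log2(mut_focal / wt[, 1])
  r <- tissue_specificity_regression(ref, gfc)
  expect_equal(r$slope, -1)
  expect_equal(r$r, -1)
  expect_equal(r$r_squared, 1)
})

test_that("a mutant identical to WT has no relationship", {
  set.seed(92)
  wt <- matrix(rexp(300, 1 / 100) + 1, 30, 10,
               dimnames = list(paste0("g", 1:30), NULL))
  ref <- log2_reference_fc(wt, focal = 1)
  gfc <- log2_genotype_fc(wt[, 1], wt[, 1])
  r <- tissue_specificity_regression(ref, gfc)
  expect_equal(r$slope, 0)
  expect_equal(r$r_squared, 0)
})

test_that("partial canalization yields a recoverably negative slope", {
  set.seed(93)
  n <- 200
  wt <- matrix(rexp(n * 12, 1 / 100) + 1, n, 12,
               dimnames = list(paste0("g", 1:n), NULL))
  mu <- rowMeans(wt)
  mut_focal <- mu + 0.6 * (wt[, 1] - mu) + rnorm(n, 0, 5)
  ref <- log2_reference_fc(wt, focal = 1, pseudocount = 0)
  gfc <- log2(pmax(mut_focal, 1) / wt[, 1])
  r <- tissue_specificity_regression(ref, gfc)
  expect_lt(r$slope, 0)
  expect_lt(r$r, 0)
  expect_lt(r$p_value, 0.01)
})

test_that("regression filtering drops zero-coverage genes and tiny inputs", {
  ref <- c(g1 = 1, g2 = -1, g3 = 0.5, g4 = 2)
  gfc <- log2_genotype_fc(c(g1 = 10, g2 = 0, g3 = 5, g4 = 8),
                          c(g1 = 5, g2 = 3, g3 = 5, g4 = 0))
  expect_true(is.na(gfc["g2"]) && is.na(gfc["g4"]))
  expect_error(tissue_specificity_regression(ref, gfc), "fewer than 3")
})

test_that("intergenic flank genes behave as a null control", {
  set.seed(95)
  n <- 120
  mat <- matrix(rexp(n * 10, 1 / 50), n, 10,
                dimnames = list(paste0("g", 1:n), NULL))
  assoc <- data.table::data.table(
    gene_id = paste0("g", 1:30),
    relation = "flank_2kb_upstream",
    dmr_chrom = "Chr1", dmr_start = 1L, dmr_end = 2L,
    direction = "hyper", mean_delta = 30
  )
  r <- intergenic_control(assoc, mat)
  expect_gt(r$tests$p_cv, 0.05)

  # genes with doubled spread are detected
  mat2 <- mat
  mat2[1:30, ] <- rowMeans(mat[1:30, , drop = FALSE]) +
    3 * (mat[1:30, ] - rowMeans(mat[1:30, , drop = FALSE]))
  mat2 <- pmax(mat2, 0)
  r2 <- intergenic_control(assoc, mat2)
  expect_lt(r2$tests$p_cv, 0.05)

  expect_error(intergenic_control(assoc[0L], mat), "no flank")
})
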