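test_that("the generator is fully deterministic under a fixed seed", {
  cfg <- small_sim(seed = 47)
  a <- simulate_methylomes(cfg)
  b <- simulate_methylomes(cfg)
  expect_identical(as.data.frame(a$wt), as.data.frame(b$wt))
  expect_identical(as.data.frame(a$mut), as.data.frame(b$mut))
  expect_identical(as.data.frame(a$genes), as.data.frame(b$genes))

  ea <- simulate_expression(cfg, a$truth)
  eb <- simulate_expression(cfg, b$truth)
  expect_identical(ea$wt, eb$wt)
  expect_identical(ea$mut, eb$mut)

  # written files are byte-identical across runs
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(cfg, d1)
  write_simulation(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
  }

  # a different seed changes the data
  c2 <- simulate_methylomes(small_sim(seed = 48))
  expect_false(identical(as.data.frame(a$wt), as.data.frame(c2$wt)))
})

test_that("per-class site heterogeneity lands in the intended bands", {
  sim <- simulate_methylomes(small_sim(seed = 53))
  sites <- pool_cg_dinucleotides(sim$wt)
  truth_sites <- sim$truth$sites
  merged <- merge(sites, truth_sites, by = c("chrom", "start"))

  dyn <- merged[merged$p_wt == 0.50, ]
  expect_equal(mean(dyn$h), 0.5, tolerance = 0.03)
  expect_gt(mean(classify_site(dyn$h) == "heterogeneous"), 0.90)

  unm <- merged[merged$p_wt == 0.01, ]
  expect_gt(mean(unm$h <= 0.10), 0.99)

  stab <- merged[merged$p_wt == 0.95, ]
  expect_gt(mean(classify_site(stab$h) == "methylated"), 0.85)
})

test_that("the eraser mutant homogenizes dynamic-gene sites", {
  sim <- simulate_methylomes(small_sim(seed = 59))
  mut_sites <- pool_cg_dinucleotides(sim$mut)
  dyn_ids <- sim$truth$genes[class == "dynamic", gene_id]
  g <- sim$genes[sim$genes$gene_id %in% dyn_ids]
  prof <- gene_profiles(g, mut_sites, sim$mut)
  expect_gt(sum(prof$n_methylated) / sum(prof$n_sites), 0.85)
})

test_that("generated reports pass the dialect validators", {
  cfg <- small_sim(seed = 61)
  dir <- withr::local_tempdir()
  paths <- write_simulation(cfg, dir)
  objs <- attr(paths, "objects")
  back <- read_cytosine_report(paths$wt)
  expect_equal(as.data.frame(back), as.data.frame(objs$methylomes$wt),
               ignore_attr = TRUE)
  genes <- read_gene_models(paths$genes)
  expect_equal(as.data.frame(genes)[, c("gene_id", "chrom", "start", "end")],
               as.data.frame(objs$methylomes$genes)[, c("gene_id", "chrom",
                                                        "start", "end")])
  track <- read_bedgraph(paths$regulatory)
  expect_equal(track$depth, objs$chip$regulatory$depth)
})

test_that("expression canalization scales the dynamic-set spread", {
  for (f in c(1.0, 0.7)) {
    cfg <- small_sim(seed = 67, canalization_factor = f)
    e <- simulate_expression(cfg)
    dyn <- names(e$classes)[e$classes == "dynamic"]
    stab <- names(e$classes)[e$classes == "stable"]
    rd <- decile_dynamic_range(e$wt, e$mut, dyn)
    rs <- decile_dynamic_range(e$wt, e$mut, stab)
    expect_equal(rd$sd_ratio, f, tolerance = 0.08)
    expect_equal(rs$sd_ratio, 1, tolerance = 0.08)
  }
  expect_error(simulate_expression(small_sim(n_conditions = 1)), ">= 2")
})

test_that("dynamic genes have the widest cross-condition variability", {
  cfg <- small_sim(seed = 71)
  e <- simulate_expression(cfg)
  ps <- plasticity_stats(e$wt, gene_sets = list(
    dynamic = names(e$classes)[e$classes == "dynamic"],
    stable = names(e$classes)[e$classes == "stable"],
    total = names(e$classes)
  ))
  s <- ps$set_summary
  cv <- setNames(s$median_cv, s$set)
  fano <- setNames(s$median_fano, s$set)
  expect_gt(cv["dynamic"], cv["total"])
  expect_gt(cv["total"], cv["stable"])
  expect_gt(fano["dynamic"], fano["total"])
  expect_gt(fano["total"], fano["stable"])
})

test_that("conservation filter fractions act exactly on flagged pairs", {
  cfg0 <- small_sim(seed = 73, cons_frac_non_one_to_one = 0,
                    cons_frac_high_noncg = 0)
  cons0 <- simulate_conservation(cfg0)
  f0 <- filter_homologs(cons0$pairs, cons0$target_methylome,
                        cons0$target_genes)
  expect_equal(nrow(f0), nrow(cons0$pairs))

  cfg2 <- small_sim(seed = 73, cons_frac_non_one_to_one = 0.2,
                    cons_frac_high_noncg = 0)
  cons2 <- simulate_conservation(cfg2)
  f2 <- filter_homologs(cons2$pairs, cons2$target_methylome,
                        cons2$target_genes)
  expect_setequal(f2$source_gene,
                  cons2$pairs[cons2$pairs$one_to_one == TRUE, ]$source_gene)
})

test_that("an unenriched ChIP track shows no class effect", {
  cfg <- small_sim(seed = 79, chip_enrich = 1)
  meth <- simulate_methylomes(cfg)
  chip <- simulate_chip(cfg, meth$genes, meth$truth)
  nt <- normalize_track(chip$regulatory)
  g <- data.table::as.data.table(meth$genes)
  fs <- list(
    dynamic = g[gene_id %in% meth$truth$genes[class == "dynamic", gene_id],
                .(chrom, start, end)],
    stable = g[gene_id %in% meth$truth$genes[class == "stable", gene_id],
               .(chrom, start, end)]
  )
  fe <- feature_enrichment(nt, fs)
  expect_lt(abs(fe$pairs$cohens_d), 0.5)
})

test_that("invalid configurations are rejected", {
  expect_error(small_sim(non_conversion_rate = 2), "non_conversion")
  expect_error(small_sim(coverage = 0), "coverage")
  expect_error(
    small_sim(p_cell = list(stable = c(wt = 1.5, mut = 1),
                            dynamic = c(wt = 0.5, mut = 0.9),
                            unmethylated = c(wt = 0, mut = 0))),
    "probabilities"
  )
})
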