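test_that("cytosine report parsing handles the mapper dialect", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Chr1\t100\t+\t8\t2\tCG\tCGA",
               "Chr1\t200\t-\t0\t5\tCHH\tCAA"), path)
  m <- read_cytosine_report(path)
  expect_s3_class(m, "methylome")
  expect_equal(nrow(m), 2L)
  rec <- as.data.frame(m)[1L, ]
  expect_equal(rec$n_meth, 8L)
  expect_equal(rec$n_unmeth, 2L)
  expect_equal(rec$context, "CG")
  expect_equal(sum(m$context == "CG"), 1L)
})

test_that("empty and malformed reports are surfaced, not crashed on", {
  empty <- withr::local_tempfile(fileext = ".tsv")
  file.create(empty)
  expect_warning(m <- read_cytosine_report(empty), "empty")
  expect_equal(nrow(m), 0L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("Chr1\t100\t+\t8\t2\tCG\tCGA",
               "Chr1\t101\t?\t1\t1\tCG\tCGA",      # bad strand
               "Chr1\t102\t+\t-3\t1\tCG\tCGA",     # negative count
               "Chr1\t103\t+\t1\t1\tCXX\tCGA"),    # bad context
             bad)
  expect_warning(m2 <- read_cytosine_report(bad), "lines 2, 3, 4")
  expect_equal(nrow(m2), 1L)
})

test_that("report round-trip reproduces identical counts", {
  sim <- simulate_methylomes(small_sim())
  path <- withr::local_tempfile(fileext = ".tsv")
  write_cytosine_report(sim$wt, path)
  back <- read_cytosine_report(path)
  expect_equal(as.data.frame(back), as.data.frame(sim$wt),
               ignore_attr = TRUE)
})

test_that("methylome constructor rejects invalid records", {
  rec <- data.frame(chrom = "Chr1", pos = 10, strand = "+", context = "CG",
                    n_meth = 1, n_unmeth = 1)
  expect_error(methylome(rbind(rec, rec)), "duplicate")
  expect_error(methylome(transform(rec, n_meth = -1)), "negative")
  expect_error(methylome(transform(rec, pos = 0)), "1-based")
  expect_error(methylome(transform(rec, context = "CpG")), "context")
})

test_that("symmetric CG cytosines pool into dinucleotide sites", {
  m <- make_methylome(
    chrom = c("Chr1", "Chr1"), pos = c(100, 101), strand = c("+", "-"),
    context = "CG", n_meth = c(3, 2), n_unmeth = c(2, 3)
  )
  s <- pool_cg_dinucleotides(m)
  expect_equal(nrow(s), 1L)
  expect_equal(s$start, 100L)
  expect_equal(s$n_meth, 5L)
  expect_equal(s$n_total, 10L)
  expect_equal(s$h, 0.5)
})

test_that("unpaired CG cytosines form single-strand sites", {
  plus_only <- make_methylome("Chr1", 100, "+", "CG", 4, 0)
  s <- pool_cg_dinucleotides(plus_only)
  expect_equal(s$n_total, 4L)
  expect_equal(s$h, 1.0)

  minus_only <- make_methylome("Chr1", 101, "-", "CG", 0, 6)
  s2 <- pool_cg_dinucleotides(minus_only)
  expect_equal(s2$start, 100L)  # site keyed by the forward-strand C
  expect_equal(s2$h, 0)

  no_cg <- make_methylome("Chr1", 50, "+", "CHH", 1, 9)
  expect_equal(nrow(pool_cg_dinucleotides(no_cg)), 0L)
})

test_that("pooling conserves reads", {
  sim <- simulate_methylomes(small_sim(seed = 3))
  s <- pool_cg_dinucleotides(sim$wt)
  cg <- as.data.frame(sim$wt)
  cg <- cg[cg$context == "CG", ]
  expect_equal(sum(s$n_total), sum(cg$n_meth) + sum(cg$n_unmeth))
  expect_equal(sum(s$n_meth), sum(cg$n_meth))
})

test_that("conversion QC measures the control contig", {
  m <- make_methylome(
    chrom = rep("ChrC", 2), pos = c(10, 20), strand = "+",
    context = c("CG", "CHH"), n_meth = c(1, 0), n_unmeth = c(499, 500)
  )
  qc <- conversion_qc(m, "ChrC")
  expect_equal(qc$apparent_methylation, 0.001)
  expect_equal(qc$conversion_rate, 0.999)
  expect_true(qc$pass)

  all_un <- make_methylome("ChrC", 10, "+", "CG", 0, 100)
  expect_equal(conversion_qc(all_un, "ChrC")$apparent_methylation, 0)

  expect_error(conversion_qc(m, "ChrM"), "ChrC")
  leaky <- make_methylome("ChrC", 10, "+", "CG", 10, 990)
  expect_warning(conversion_qc(leaky, "ChrC"), "below threshold")
})

test_that("BED and GFF3 gene models unify to 0-based half-open", {
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines("Chr1\t999\t2000\tgeneA\t0\t+", bed)
  g1 <- read_gene_models(bed)
  expect_equal(g1$start, 999L)
  expect_equal(g1$end, 2000L)
  expect_equal(g1$gene_id, "geneA")

  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "Chr1\tsrc\tgene\t1000\t2000\t.\t+\t.\tID=geneA"), gff)
  g2 <- read_gene_models(gff)
  expect_equal(g2$start, 999L)
  expect_equal(g2$end, 2000L)

  # same interval from either dialect
  expect_equal(g1[, c("chrom", "start", "end")],
               g2[, c("chrom", "start", "end")])
})

test_that("dialect conversion is a bijection on random intervals", {
  set.seed(42)
  n <- 25
  starts <- sample(0:10000, n)
  lens <- sample(100:5000, n)
  g <- gene_models(data.frame(
    gene_id = paste0("g", seq_len(n)), chrom = "Chr1",
    start = starts, end = starts + lens,
    strand = sample(c("+", "-"), n, replace = TRUE)
  ))
  bed <- withr::local_tempfile(fileext = ".bed")
  write.table(data.frame(g$chrom, g$start, g$end, g$gene_id, 0, g$strand),
              bed, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               sprintf("Chr1\tsrc\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$start + 1L, g$end, g$strand, g$gene_id)), gff)
  from_bed <- as.data.frame(read_gene_models(bed))
  from_gff <- as.data.frame(read_gene_models(gff))
  ord <- function(x) x[order(x$gene_id), c("gene_id", "chrom", "start",
                                           "end", "strand")]
  expect_equal(ord(from_bed), ord(from_gff), ignore_attr = TRUE)
  expect_equal(ord(from_bed), ord(as.data.frame(g)), ignore_attr = TRUE)
})

test_that("overlapping genes on both strands are retained", {
  g <- gene_models(data.frame(
    gene_id = c("a", "b"), chrom = "Chr1", start = c(100, 150),
    end = c(300, 400), strand = c("+", "-")
  ))
  expect_equal(nrow(g), 2L)
})
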