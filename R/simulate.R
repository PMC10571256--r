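#' Synthetic-data generator configuration
#'
#' Parameterizes the generator that emulates the study design: a small
#' multi-gene genome with three gene epigenotypes (Stable GbM: near-100%
#' per-cell CG methylation; Dynamic GbM: per-cell probability inside the
#' 10-85% heterogeneity band in wild type and near-100% in the eraser
#' mutant; unmethylated), per-read sampling where each deduplicated read is
#' an independent cell, a non-conversion error rate, an unmethylated control
#' contig, ChIP tracks and chromatin states, a homolog table for a target
#' species, and expression matrices where Dynamic-class genes have elevated
#' cross-condition variance and the mutant shrinks Dynamic-gene expression
#' toward each gene's cross-condition mean.
#'
#' @param seed integer seed fixing all randomness.
#' @param n_genes named integer vector: genes per epigenotype.
#' @param cgs_per_gene integer range (min, max) of CG dinucleotides per gene.
#' @param p_cell named list per epigenotype of per-cell methylation
#'   probabilities `c(wt = , mut = )`.
#' @param coverage mean of the per-strand-pair Poisson read coverage per CG
#'   site.
#' @param non_conversion_rate probability an unmethylated cytosine reads as
#'   methylated (default 0.003).
#' @param contig_length,n_contigs main genome geometry.
#' @param control_contig,control_length,control_cytosines unmethylated
#'   control contig (conversion QC).
#' @param intergenic_cgs CG sites placed between genes per contig;
#'   `intergenic_meth_fraction` of them are fully methylated
#'   (epigenotype-independent background).
#' @param noncg_per_gene CHG/CHH cytosines per gene body; `p_noncg` their
#'   per-cell methylation probability.
#' @param n_conditions number of expression conditions.
#' @param expr_base_mean,expr_mean_sd per-gene baseline expression mean and
#'   its across-gene spread.
#' @param expr_condition_sd named vector of across-condition sd per
#'   epigenotype (dynamic > unmethylated > stable).
#' @param expr_noise_sd measurement noise sd.
#' @param canalization_factor multiplier (< 1 shrinks) applied to
#'   Dynamic-gene condition deviations in the mutant (default 0.7).
#' @param cons_frac_non_one_to_one,cons_frac_high_noncg fractions of homolog
#'   pairs flagged non-one-to-one / given > 1% non-CG methylation, to
#'   exercise the conservation filters.
#' @param chip_bin_bp,chip_base_depth,chip_enrich ChIP track geometry: bin
#'   size, baseline Poisson depth, multiplicative enrichment painted over
#'   dynamic ("regulatory" mark) or stable ("gene body" mark) gene bodies.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_genes = c(stable = 100, dynamic = 100,
                                   unmethylated = 100),
                       cgs_per_gene = c(10, 30),
                       p_cell = list(stable = c(wt = 0.95, mut = 0.95),
                                     dynamic = c(wt = 0.50, mut = 0.95),
                                     unmethylated = c(wt = 0.01, mut = 0.01)),
                       coverage = 30,
                       non_conversion_rate = 0.003,
                       contig_length = 500000, n_contigs = 2,
                       control_contig = "ChrC", control_length = 10000,
                       control_cytosines = 3000,
                       intergenic_cgs = 400,
                       intergenic_meth_fraction = 0.25,
                       noncg_per_gene = 100, p_noncg = 0.001,
                       n_conditions = 12,
                       expr_base_mean = 200, expr_mean_sd = 5,
                       expr_condition_sd = c(dynamic = 30, stable = 8,
                                             unmethylated = 15),
                       expr_noise_sd = 3,
                       canalization_factor = 0.7,
                       cons_frac_non_one_to_one = 0.1,
                       cons_frac_high_noncg = 0.1,
                       chip_bin_bp = 50, chip_base_depth = 30,
                       chip_enrich = 4) {
  cfg <- as.list(environment())
  probs <- unlist(p_cell)
  if (any(probs < 0 | probs > 1)) stop("per-cell probabilities must be in [0, 1]")
  if (non_conversion_rate < 0 || non_conversion_rate > 1) {
    stop("non_conversion_rate must be in [0, 1]")
  }
  if (coverage <= 0) stop("coverage mean must be > 0")
  if (canalization_factor < 0) stop("canalization_factor must be >= 0")
  stopifnot(setequal(names(n_genes), names(p_cell)),
            length(cgs_per_gene) == 2L, cgs_per_gene[1L] <= cgs_per_gene[2L])
  structure(cfg, class = "sim_config")
}

# internal: draw observed counts for one strand of a cytosine population.
# p is the per-cell methylation probability; non-conversion flips
# unmethylated cells to apparent-methylated.
.sample_counts <- function(n_sites, p, coverage, non_conversion) {
  n <- rpois(n_sites, coverage)
  p_eff <- p + (1 - p) * non_conversion
  meth <- rbinom(n_sites, n, p_eff)
  list(n = n, meth = meth)
}

# internal: emit both strands of CG dinucleotides as cytosine records
.cg_records <- function(chrom, dstart, p, coverage, non_conversion) {
  recs <- lapply(c("+", "-"), function(st) {
    cnt <- .sample_counts(length(dstart), p, coverage / 2, non_conversion)
    data.table(
      chrom = chrom,
      pos = if (st == "+") dstart else dstart + 1L,
      strand = st, context = "CG",
      n_meth = cnt$meth, n_unmeth = cnt$n - cnt$meth
    )
  })
  rbindlist(recs)
}

#' Simulate paired wild-type and eraser-mutant methylomes
#'
#' Lays out genes of the three epigenotypes along the contigs, places CG
#' dinucleotides in each gene body (plus intergenic background CGs and
#' near-zero-methylation CHG/CHH cytosines), and samples reads per site:
#' each read is an independent cell, methylated with the epigenotype's
#' per-cell probability for the genotype, with unmethylated cells flipped to
#' apparent-methylated at the non-conversion rate. A fully unmethylated
#' control contig is included for conversion QC. Fully deterministic under
#' the config seed.
#'
#' @param cfg a [sim_config()].
#' @return A list of class `sim_methylomes`: `wt` and `mut`
#'   ([methylome()]s), `genes` ([gene_models()]), `truth` (list with
#'   per-gene `genes` table — `gene_id`, `class`, `p_wt`, `p_mut` — and
#'   per-site `sites` table).
#' @export
simulate_methylomes <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  classes <- rep(names(cfg$n_genes), times = cfg$n_genes)
  n_total_genes <- length(classes)
  classes <- sample(classes)  # shuffle epigenotypes along the genome
  gene_rows <- list(); site_rows <- list()
  wt_recs <- list(); mut_recs <- list()
  contigs <- paste0("Chr", seq_len(cfg$n_contigs))
  per_contig <- ceiling(n_total_genes / cfg$n_contigs)
  gi <- 0L
  for (ci in seq_along(contigs)) {
    cursor <- 1000L
    n_here <- min(per_contig, n_total_genes - gi)
    if (n_here <= 0L) break
    for (k in seq_len(n_here)) {
      gi <- gi + 1L
      cls <- classes[gi]
      gene_id <- sprintf("g%04d", gi)
      n_cg <- sample(cfg$cgs_per_gene[1L]:cfg$cgs_per_gene[2L], 1L)
      gaps <- sample(10:60, n_cg, replace = TRUE)
      dstart <- cursor + 100L + cumsum(gaps)  # 1-based forward-strand C
      body_start0 <- cursor + 50L             # 0-based half-open gene body
      body_end0 <- max(dstart) + 100L
      p_wt <- cfg$p_cell[[cls]]["wt"]; p_mut <- cfg$p_cell[[cls]]["mut"]
      wt_recs[[length(wt_recs) + 1L]] <-
        .cg_records(contigs[ci], dstart, p_wt, cfg$coverage,
                    cfg$non_conversion_rate)
      mut_recs[[length(mut_recs) + 1L]] <-
        .cg_records(contigs[ci], dstart, p_mut, cfg$coverage,
                    cfg$non_conversion_rate)
      if (cfg$noncg_per_gene > 0L) {
        used <- sort(c(dstart, dstart + 1L))
        candidates <- setdiff(seq(body_start0 + 1L, body_end0), used)
        npos <- sort(sample(candidates,
                            min(cfg$noncg_per_gene, length(candidates))))
        ctx <- sample(c("CHG", "CHH"), length(npos), replace = TRUE)
        strand <- sample(c("+", "-"), length(npos), replace = TRUE)
        for (m in c("wt", "mut")) {
          cnt <- .sample_counts(length(npos), cfg$p_noncg, cfg$coverage,
                                cfg$non_conversion_rate)
          rec <- data.table(chrom = contigs[ci], pos = npos, strand = strand,
                            context = ctx, n_meth = cnt$meth,
                            n_unmeth = cnt$n - cnt$meth)
          if (m == "wt") wt_recs[[length(wt_recs) + 1L]] <- rec
          else mut_recs[[length(mut_recs) + 1L]] <- rec
        }
      }
      gene_rows[[gi]] <- data.table(
        gene_id = gene_id, chrom = contigs[ci],
        start = body_start0, end = body_end0, strand = "+",
        class = cls, p_wt = unname(p_wt), p_mut = unname(p_mut)
      )
      site_rows[[gi]] <- data.table(
        gene_id = gene_id, chrom = contigs[ci], start = dstart,
        p_wt = unname(p_wt), p_mut = unname(p_mut)
      )
      cursor <- body_end0 + sample(500:2000, 1L)
    }
    # intergenic background CGs after the genes
    if (cfg$intergenic_cgs > 0L) {
      ig_start <- cursor + 500L
      ig_pos <- ig_start + cumsum(sample(20:80, cfg$intergenic_cgs,
                                         replace = TRUE))
      meth_flag <- runif(cfg$intergenic_cgs) < cfg$intergenic_meth_fraction
      for (m in c("wt", "mut")) {
        rec <- rbind(
          .cg_records(contigs[ci], ig_pos[meth_flag], 0.97, cfg$coverage,
                      cfg$non_conversion_rate),
          .cg_records(contigs[ci], ig_pos[!meth_flag], 0.01, cfg$coverage,
                      cfg$non_conversion_rate)
        )
        if (m == "wt") wt_recs[[length(wt_recs) + 1L]] <- rec
        else mut_recs[[length(mut_recs) + 1L]] <- rec
      }
    }
  }
  # unmethylated control contig, mixed contexts, true p = 0
  npos <- sort(sample(seq_len(cfg$control_length - 1L),
                      cfg$control_cytosines))
  ctx <- sample(c("CG", "CHG", "CHH"), cfg$control_cytosines, replace = TRUE)
  strand <- sample(c("+", "-"), cfg$control_cytosines, replace = TRUE)
  for (m in c("wt", "mut")) {
    cnt <- .sample_counts(cfg$control_cytosines, 0, cfg$coverage,
                          cfg$non_conversion_rate)
    rec <- data.table(chrom = cfg$control_contig, pos = npos,
                      strand = strand, context = ctx, n_meth = cnt$meth,
                      n_unmeth = cnt$n - cnt$meth)
    if (m == "wt") wt_recs[[length(wt_recs) + 1L]] <- rec
    else mut_recs[[length(mut_recs) + 1L]] <- rec
  }
  genes_dt <- rbindlist(gene_rows)
  truth <- list(
    genes = genes_dt[, .(gene_id, class, p_wt, p_mut)],
    sites = rbindlist(site_rows)
  )
  structure(
    list(
      wt = methylome(rbindlist(wt_recs), sample_id = "sim_wt",
                     genotype = "WT"),
      mut = methylome(rbindlist(mut_recs), sample_id = "sim_mut",
                      genotype = "mutant"),
      genes = gene_models(genes_dt[, .(gene_id, chrom, start, end, strand)]),
      truth = truth, config = cfg
    ),
    class = "sim_methylomes"
  )
}

#' Simulate expression matrices with class-dependent plasticity
#'
#' Wild-type expression of gene g in condition c is
#' `mu_g + d_gc + noise` with per-gene baseline `mu_g` and condition
#' deviations `d_gc ~ N(0, sd_class)` where the Dynamic class has the widest
#' spread (matched means across classes). Two mutant matrices are emitted,
#' matching the two ways the analysis contrasts genotypes:
#'
#' * `mut` draws its own condition deviations, scaled by the canalization
#'   factor for Dynamic genes (`mu_g + f * d'_gc + noise`). The genotypes
#'   are independent replicates of the same generative law, so the Dynamic
#'   set's mutant/WT spread ratio estimates f and, at f = 1, a two-sample
#'   variance-equality test is exactly calibrated. Used by the decile /
#'   F-test dynamic-range analysis.
#' * `mut_paired` canalizes the *same* condition profile the wild type
#'   realized (`mu_g + f * d_gc + noise`), emulating matched tissue samples
#'   whose biological condition effect is shared between genotypes. Used by
#'   the tissue-specificity regression, where an independently redrawn
#'   profile would manufacture an inverse relation for every gene class by
#'   regression to the mean.
#'
#' Values are truncated at zero.
#'
#' @param cfg a [sim_config()].
#' @param truth the `truth` element of [simulate_methylomes()] (or any table
#'   with `gene_id` and `class`); `NULL` generates fresh labels from the
#'   config sizes.
#' @return A list of class `sim_expression`: `wt`, `mut`, `mut_paired`
#'   (matrices genes x conditions), `metadata` (condition table), `classes`
#'   (named vector).
#' @export
simulate_expression <- function(cfg = sim_config(), truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_conditions < 2L) stop("n_conditions must be >= 2")
  set.seed(cfg$seed + 1L)
  genes <- if (is.null(truth)) {
    data.table(gene_id = sprintf("g%04d", seq_len(sum(cfg$n_genes))),
               class = rep(names(cfg$n_genes), times = cfg$n_genes))
  } else {
    as.data.table(truth$genes %||% truth)[, .(gene_id, class)]
  }
  ng <- nrow(genes); nc <- cfg$n_conditions
  mu <- rnorm(ng, cfg$expr_base_mean, cfg$expr_mean_sd)
  sd_class <- cfg$expr_condition_sd[genes$class]
  f_class <- ifelse(genes$class == "dynamic", cfg$canalization_factor, 1)
  dev_draw <- function() matrix(rnorm(ng * nc, 0, 1), ng, nc) * sd_class
  noise_draw <- function() matrix(rnorm(ng * nc, 0, cfg$expr_noise_sd),
                                  ng, nc)
  assemble <- function(dev, scale = 1) {
    m <- pmax(mu + dev * scale + noise_draw(), 0)
    dimnames(m) <- list(genes$gene_id, sprintf("cond%02d", seq_len(nc)))
    m
  }
  d_wt <- dev_draw()
  wt <- assemble(d_wt)
  mut <- assemble(dev_draw(), scale = f_class)
  mut_paired <- assemble(d_wt, scale = f_class)
  structure(
    list(wt = wt, mut = mut, mut_paired = mut_paired,
         metadata = data.table(sample = colnames(wt),
                               condition = colnames(wt)),
         classes = setNames(genes$class, genes$gene_id)),
    class = "sim_expression"
  )
}

#' Simulate a target-species methylome and homolog table
#'
#' Builds a second (target-species) genome in which homologs of
#' Dynamic-class source genes carry heterogeneous per-cell methylation
#' (wild-type dynamic probability) while homologs of other genes are near 0
#' or 1 — the constructed-conservation scenario. A configurable fraction of
#' pairs is flagged non-one-to-one and another fraction is given > 1% non-CG
#' gene-body methylation, to exercise the homolog filters.
#'
#' @param cfg a [sim_config()].
#' @param truth per-gene truth (as in [simulate_expression()]); `NULL`
#'   generates fresh labels.
#' @return A list of class `sim_conservation`: `target_methylome`,
#'   `target_genes`, `pairs` (homolog table), `truth`.
#' @export
simulate_conservation <- function(cfg = sim_config(), truth = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed + 2L)
  genes <- if (is.null(truth)) {
    data.table(gene_id = sprintf("g%04d", seq_len(sum(cfg$n_genes))),
               class = rep(names(cfg$n_genes), times = cfg$n_genes))
  } else {
    as.data.table(truth$genes %||% truth)[, .(gene_id, class)]
  }
  ng <- nrow(genes)
  recs <- list(); gene_rows <- list()
  cursor <- 1000L
  high_noncg <- runif(ng) < cfg$cons_frac_high_noncg
  for (i in seq_len(ng)) {
    cls <- genes$class[i]
    p <- switch(cls, dynamic = cfg$p_cell$dynamic["wt"],
                stable = cfg$p_cell$stable["wt"],
                unmethylated = cfg$p_cell$unmethylated["wt"])
    n_cg <- sample(cfg$cgs_per_gene[1L]:cfg$cgs_per_gene[2L], 1L)
    dstart <- cursor + 100L + cumsum(sample(10:60, n_cg, replace = TRUE))
    body_start0 <- cursor + 50L
    body_end0 <- max(dstart) + 100L
    recs[[length(recs) + 1L]] <-
      .cg_records("tChr1", dstart, p, cfg$coverage, cfg$non_conversion_rate)
    if (cfg$noncg_per_gene > 0L) {
      used <- sort(c(dstart, dstart + 1L))
      candidates <- setdiff(seq(body_start0 + 1L, body_end0), used)
      npos <- sort(sample(candidates,
                          min(cfg$noncg_per_gene, length(candidates))))
      p_n <- if (high_noncg[i]) 0.5 else cfg$p_noncg
      cnt <- .sample_counts(length(npos), p_n, cfg$coverage,
                            cfg$non_conversion_rate)
      recs[[length(recs) + 1L]] <- data.table(
        chrom = "tChr1", pos = npos,
        strand = sample(c("+", "-"), length(npos), replace = TRUE),
        context = sample(c("CHG", "CHH"), length(npos), replace = TRUE),
        n_meth = cnt$meth, n_unmeth = cnt$n - cnt$meth
      )
    }
    gene_rows[[i]] <- data.table(
      gene_id = paste0("t_", genes$gene_id[i]), chrom = "tChr1",
      start = body_start0, end = body_end0, strand = "+"
    )
    cursor <- body_end0 + sample(500:2000, 1L)
  }
  pairs <- data.table(
    source_gene = genes$gene_id,
    target_gene = paste0("t_", genes$gene_id),
    one_to_one = runif(ng) >= cfg$cons_frac_non_one_to_one,
    species = "target_species"
  )
  structure(
    list(
      target_methylome = methylome(rbindlist(recs),
                                   sample_id = "sim_target",
                                   genotype = "WT"),
      target_genes = gene_models(rbindlist(gene_rows)),
      pairs = pairs,
      truth = data.table(genes, high_noncg = high_noncg)
    ),
    class = "sim_conservation"
  )
}

#' Simulate ChIP coverage tracks and a chromatin-state partition
#'
#' Baseline Poisson coverage in fixed-width bins across the main contigs,
#' with multiplicative enrichment painted over Dynamic gene bodies for the
#' "regulatory" mark and over Stable gene bodies for the "gene body" mark.
#' Also emits a four-state chromatin partition (promoter_tss,
#' promoter_distal, gene_body, other_intergenic) in which half of each
#' Dynamic gene body is annotated as distal-promoter chromatin, mirroring
#' the regulatory-state intrusion that distinguishes the two GbM classes.
#'
#' @param cfg a [sim_config()].
#' @param genes [gene_models()] from [simulate_methylomes()].
#' @param truth per-gene truth table with `gene_id` and `class`.
#' @return A list of class `sim_chip`: `regulatory` and `genebody` tracks
#'   (bedGraph-style `data.table`s), `states` (interval table with `state`).
#' @export
simulate_chip <- function(cfg = sim_config(), genes, truth) {
  stopifnot(inherits(cfg, "sim_config"), inherits(genes, "gene_models"))
  set.seed(cfg$seed + 3L)
  g <- merge(as.data.table(genes),
             as.data.table(truth$genes %||% truth)[, .(gene_id, class)],
             by = "gene_id")
  contigs <- unique(as.data.table(genes)$chrom)
  make_track <- function(enriched_class) {
    rbindlist(lapply(contigs, function(cn) {
      len <- max(g[chrom == cn, end]) + 1000L
      starts <- seq(0L, len - 1L, by = cfg$chip_bin_bp)
      bins <- data.table(chrom = cn, start = starts,
                         end = pmin(starts + cfg$chip_bin_bp, len))
      mult <- rep(1, nrow(bins))
      enr <- g[chrom == cn & class == enriched_class]
      if (nrow(enr) > 0L) {
        ov <- GenomicRanges::findOverlaps(.as_granges(bins),
                                          .as_granges(enr))
        mult[unique(queryHits(ov))] <- cfg$chip_enrich
      }
      bins[, depth := rpois(.N, cfg$chip_base_depth * mult)]
      bins
    }))
  }
  regulatory <- make_track("dynamic")
  genebody <- make_track("stable")
  states <- rbindlist(lapply(contigs, function(cn) {
    len <- max(g[chrom == cn, end]) + 1000L
    gc <- g[chrom == cn][order(start)]
    rows <- list()
    prev_end <- 0L
    for (i in seq_len(nrow(gc))) {
      s <- gc$start[i]; e <- gc$end[i]
      # promoter intervals are clipped at the previous gene so the state
      # table stays a valid (non-overlapping) partition
      rows[[length(rows) + 1L]] <- data.table(
        chrom = cn,
        start = c(max(prev_end, s - 1000L), max(prev_end, s - 200L)),
        end = c(max(prev_end, s - 200L), s),
        state = c("promoter_distal", "promoter_tss")
      )
      prev_end <- e
      if (gc$class[i] == "dynamic") {
        mid <- s + (e - s) %/% 2L
        rows[[length(rows) + 1L]] <- data.table(
          chrom = cn, start = c(s, mid), end = c(mid, e),
          state = c("gene_body", "promoter_distal")
        )
      } else {
        rows[[length(rows) + 1L]] <- data.table(
          chrom = cn, start = s, end = e, state = "gene_body"
        )
      }
    }
    annotated <- rbindlist(rows)[start < end]
    # fill the remainder of the contig with the intergenic state
    ann_gr <- GenomicRanges::reduce(.as_granges(annotated))
    gaps <- BiocGenerics::setdiff(
      GenomicRanges::GRanges(cn, IRanges::IRanges(1L, len)), ann_gr
    )
    inter <- data.table(
      chrom = cn, start = BiocGenerics::start(gaps) - 1L,
      end = BiocGenerics::end(gaps), state = "other_intergenic"
    )
    rbind(annotated, inter)[order(start)]
  }))
  structure(list(regulatory = regulatory, genebody = genebody,
                 states = states),
            class = "sim_chip")
}

#' Write a full synthetic dataset to disk
#'
#' Emits the same plain-text formats the analysis consumes: per-cytosine
#' reports (wild type, mutant, target species), gene BED files, homolog TSV,
#' bedGraph ChIP tracks, chromatin-state BED, expression TSVs with a sample
#' metadata sidecar, a ground-truth TSV, and the resolved configuration as
#' YAML.
#'
#' @param cfg a [sim_config()].
#' @param dir output directory (created if needed).
#' @return Named list of written paths, invisibly; the generated objects as
#'   attribute `"objects"`.
#' @export
write_simulation <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  meth <- simulate_methylomes(cfg)
  expr <- simulate_expression(cfg, meth$truth)
  cons <- simulate_conservation(cfg, meth$truth)
  chip <- simulate_chip(cfg, meth$genes, meth$truth)
  p <- function(...) file.path(dir, ...)
  paths <- list(
    wt = p("wt.cx.tsv"), mut = p("mut.cx.tsv"),
    genes = p("genes.bed"), target = p("target.cx.tsv"),
    target_genes = p("target_genes.bed"), pairs = p("homologs.tsv"),
    regulatory = p("chip_regulatory.bedgraph"),
    genebody = p("chip_genebody.bedgraph"), states = p("states.bed"),
    expr_wt = p("expr_wt.tsv"), expr_mut = p("expr_mut.tsv"),
    expr_mut_paired = p("expr_mut_paired.tsv"),
    metadata = p("expr_metadata.tsv"), truth = p("ground_truth.tsv"),
    config = p("config.yaml")
  )
  write_cytosine_report(meth$wt, paths$wt)
  write_cytosine_report(meth$mut, paths$mut)
  write_bed6 <- function(g, path) {
    fwrite(as.data.table(g)[, .(chrom, start, end, gene_id, 0L, strand)],
           path, sep = "\t", col.names = FALSE)
  }
  write_bed6(meth$genes, paths$genes)
  write_cytosine_report(cons$target_methylome, paths$target)
  write_bed6(cons$target_genes, paths$target_genes)
  fwrite(cons$pairs, paths$pairs, sep = "\t")
  fwrite(chip$regulatory, paths$regulatory, sep = "\t", col.names = FALSE)
  fwrite(chip$genebody, paths$genebody, sep = "\t", col.names = FALSE)
  fwrite(chip$states[, .(chrom, start, end, state)], paths$states,
         sep = "\t", col.names = FALSE)
  write_matrix <- function(m, path) {
    dt <- data.table(gene_id = rownames(m))
    dt <- cbind(dt, as.data.table(m))
    fwrite(dt, path, sep = "\t")
  }
  write_matrix(expr$wt, paths$expr_wt)
  write_matrix(expr$mut, paths$expr_mut)
  write_matrix(expr$mut_paired, paths$expr_mut_paired)
  fwrite(expr$metadata, paths$metadata, sep = "\t")
  fwrite(meth$truth$genes, paths$truth, sep = "\t")
  yaml::write_yaml(unclass(cfg), paths$config)
  objects <- list(methylomes = meth, expression = expr,
                  conservation = cons, chip = chip)
  invisible(structure(paths, objects = objects))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
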