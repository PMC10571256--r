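# fixtures built in code: tiny methylomes, CG site tables, gene models

# methylome from a compact per-cytosine spec
make_methylome <- function(chrom, pos, strand, context, n_meth, n_unmeth,
                           sample_id = "fix", genotype = "WT") {
  methylome(data.frame(chrom = chrom, pos = pos, strand = strand,
                       context = context, n_meth = n_meth,
                       n_unmeth = n_unmeth),
            sample_id = sample_id, genotype = genotype)
}

# pooled CG site table directly from h values (fixed coverage)
make_sites <- function(start, h, chrom = "Chr1", coverage = 20) {
  n_meth <- as.integer(round(h * coverage))
  s <- data.table::data.table(chrom = chrom, start = as.integer(start),
                              n_meth = n_meth,
                              n_total = as.integer(coverage),
                              h = n_meth / coverage)
  data.table::setattr(s, "class", c("cg_sites", class(s)))
  s
}

# one-gene model helper
make_gene <- function(gene_id = "g1", chrom = "Chr1", start = 0,
                      end = 10000, strand = "+") {
  gene_models(data.frame(gene_id = gene_id, chrom = chrom, start = start,
                         end = end, strand = strand))
}

# paired methylomes in which one gene gains methylation in the mutant:
# n_gain CG dinucleotides move from h_wt to h_mut at fixed coverage
make_gaining_pair <- function(n_gain, h_wt = 0.3, h_mut = 0.8,
                              coverage = 20, spacing = 25, chrom = "Chr1",
                              offset = 1001L) {
  dstart <- offset + spacing * (seq_len(n_gain) - 1L)
  rec <- function(h) {
    cov2 <- coverage / 2
    data.frame(
      chrom = chrom, pos = c(dstart, dstart + 1L),
      strand = rep(c("+", "-"), each = n_gain), context = "CG",
      n_meth = as.integer(round(h * cov2)),
      n_unmeth = as.integer(cov2 - round(h * cov2))
    )
  }
  list(wt = methylome(rec(h_wt), "wt", "WT"),
       mut = methylome(rec(h_mut), "mut", "mutant"),
       dstart = dstart)
}

small_sim <- function(seed = 7, ...) {
  sim_config(seed = seed,
             n_genes = c(stable = 25, dynamic = 25, unmethylated = 25),
             intergenic_cgs = 150, control_cytosines = 800, ...)
}
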