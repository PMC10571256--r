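#' Construct a methylome from per-cytosine records
#'
#' A methylome is the in-memory form of a per-cytosine methylation call table:
#' one row per cytosine with deduplicated methylated and unmethylated read
#' counts in one of the three plant sequence contexts (CG, CHG, CHH). Each
#' deduplicated read is treated as an independent cell, so the per-cytosine
#' methylation fraction is a read-level (cellular) heterogeneity measure.
#'
#' @param records data.frame with columns `chrom`, `pos` (1-based), `strand`
#'   (`+`/`-`), `context` (`CG`/`CHG`/`CHH`), `n_meth`, `n_unmeth`.
#' @param sample_id character scalar naming the library.
#' @param genotype character scalar, e.g. `"WT"` or `"drdd"`.
#' @return An object of class `methylome`: a `data.table` of records with
#'   `sample_id` and `genotype` attributes.
#' @export
methylome <- function(records, sample_id = "sample", genotype = "unknown") {
  dt <- as.data.table(records)
  required <- c("chrom", "pos", "strand", "context", "n_meth", "n_unmeth")
  missing_cols <- setdiff(required, names(dt))
  if (length(missing_cols) > 0L) {
    stop("methylome records lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  dt <- dt[, required, with = FALSE]
  dt[, chrom := as.character(chrom)]
  dt[, strand := as.character(strand)]
  dt[, context := as.character(context)]
  dt[, pos := as.integer(pos)]
  dt[, n_meth := as.integer(n_meth)]
  dt[, n_unmeth := as.integer(n_unmeth)]
  if (nrow(dt) > 0L) {
    if (any(dt$n_meth < 0L) || any(dt$n_unmeth < 0L)) {
      stop("negative read counts are not valid")
    }
    if (any(dt$pos < 1L)) stop("positions must be 1-based (>= 1)")
    bad_ctx <- setdiff(unique(dt$context), c("CG", "CHG", "CHH"))
    if (length(bad_ctx) > 0L) {
      stop("unknown cytosine context(s): ", paste(bad_ctx, collapse = ", "))
    }
    bad_strand <- setdiff(unique(dt$strand), c("+", "-"))
    if (length(bad_strand) > 0L) {
      stop("strand must be '+' or '-', found: ", paste(bad_strand, collapse = ", "))
    }
    if (anyDuplicated(dt, by = c("chrom", "pos", "strand")) > 0L) {
      stop("duplicate (chrom, pos, strand) records")
    }
  }
  setkey(dt, chrom, pos, strand)
  setattr(dt, "sample_id", sample_id)
  setattr(dt, "genotype", genotype)
  setattr(dt, "class", c("methylome", class(dt)))
  dt[]
}

#' @export
print.methylome <- function(x, ...) {
  cat(sprintf(
    "<methylome> sample '%s' (genotype %s): %d cytosines on %d contig(s)\n",
    attr(x, "sample_id"), attr(x, "genotype"), nrow(x),
    length(unique(x$chrom))
  ))
  if (nrow(x) > 0L) print(as.data.table(x), topn = 3)
  invisible(x)
}

#' Read a per-cytosine methylation report
#'
#' Parses the tab-delimited per-cytosine dialect emitted by standard bisulfite
#' mappers (the Bismark cytosine/CX report): columns chrom, 1-based position,
#' strand, methylated read count, unmethylated read count, context, and
#' trinucleotide. Gzip-compressed files are accepted. Malformed lines (bad
#' strand or context, negative or non-numeric counts) are dropped with a
#' warning listing their line numbers.
#'
#' @param path path to the report (optionally `.gz`).
#' @inheritParams methylome
#' @return A [methylome()] object.
#' @export
read_cytosine_report <- function(path, sample_id = basename(path),
                                 genotype = "unknown") {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- fread(path, header = FALSE, sep = "\t", fill = TRUE,
              colClasses = "character", showProgress = FALSE)
  if (nrow(dt) == 0L) {
    warning("empty cytosine report: ", path)
    return(methylome(
      data.table(chrom = character(), pos = integer(), strand = character(),
                 context = character(), n_meth = integer(), n_unmeth = integer()),
      sample_id = sample_id, genotype = genotype
    ))
  }
  if (ncol(dt) < 6L) {
    stop("cytosine report needs >= 6 tab-separated columns ",
         "(chrom, pos, strand, n_meth, n_unmeth, context[, trinucleotide]); got ",
         ncol(dt))
  }
  setnames(dt, 1:6, c("chrom", "pos", "strand", "n_meth", "n_unmeth", "context"))
  pos <- suppressWarnings(as.integer(dt$pos))
  n_meth <- suppressWarnings(as.integer(dt$n_meth))
  n_unmeth <- suppressWarnings(as.integer(dt$n_unmeth))
  ok <- !is.na(pos) & pos >= 1L &
    !is.na(n_meth) & n_meth >= 0L &
    !is.na(n_unmeth) & n_unmeth >= 0L &
    dt$strand %in% c("+", "-") &
    dt$context %in% c("CG", "CHG", "CHH")
  if (any(!ok)) {
    bad <- which(!ok)
    shown <- paste(head(bad, 10L), collapse = ", ")
    if (length(bad) > 10L) shown <- paste0(shown, ", ...")
    warning(sprintf("%d malformed line(s) dropped from %s (lines %s)",
                    length(bad), path, shown))
  }
  methylome(
    data.table(chrom = dt$chrom[ok], pos = pos[ok], strand = dt$strand[ok],
               context = dt$context[ok], n_meth = n_meth[ok],
               n_unmeth = n_unmeth[ok]),
    sample_id = sample_id, genotype = genotype
  )
}

#' Write a methylome back to the per-cytosine report dialect
#'
#' Inverse of [read_cytosine_report()]: the trinucleotide column is filled
#' with the context (its first two bases are what the analysis uses).
#'
#' @param x a [methylome()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cytosine_report <- function(x, path) {
  stopifnot(inherits(x, "methylome"))
  out <- as.data.table(x)[, .(chrom, pos, strand, n_meth, n_unmeth, context,
                              trinucleotide = context)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Pool symmetric CG cytosines into dinucleotide sites
#'
#' A CG dinucleotide has two cytosines: the forward-strand C at position p and
#' the reverse-strand C at p+1. Their deduplicated read counts are summed into
#' one site, and the heterogeneity fraction `h = n_meth / n_total` is the
#' proportion of reads (cells) in which the site is methylated. Cytosines
#' whose partner strand is uncovered still form a (single-strand) site:
#' dropping them would bias `h` at low depth.
#'
#' @param x a [methylome()].
#' @return A `data.table` of class `cg_sites` with columns `chrom`, `start`
#'   (1-based position of the forward-strand C), `n_meth`, `n_total`, `h`
#'   (`NA` when `n_total` is 0).
#' @export
pool_cg_dinucleotides <- function(x) {
  stopifnot(inherits(x, "methylome"))
  cg <- as.data.table(x)[context == "CG"]
  if (nrow(cg) == 0L) {
    sites <- data.table(chrom = character(), start = integer(),
                        n_meth = integer(), n_total = integer(), h = numeric())
  } else {
    cg[, dstart := ifelse(strand == "+", pos, pos - 1L)]
    sites <- cg[, .(n_meth = sum(n_meth), n_total = sum(n_meth) + sum(n_unmeth)),
                by = .(chrom, start = dstart)]
    sites[, h := ifelse(n_total > 0L, n_meth / n_total, NA_real_)]
    setkey(sites, chrom, start)
  }
  setattr(sites, "class", c("cg_sites", class(sites)))
  sites[]
}

#' Conversion-efficiency QC from an unmethylated control contig
#'
#' Enzymatic or bisulfite conversion chemistry leaves a small fraction of
#' unmethylated cytosines reading as methylated. An endogenous unmethylated
#' genome (the chloroplast, in plants) measures this directly: the apparent
#' methylation fraction over all contexts on the control contig estimates the
#' non-conversion rate, and `1 - apparent` is the conversion rate.
#'
#' @param x a [methylome()].
#' @param control_contig name of the control contig (e.g. `"ChrC"`).
#' @param warn_below warn when the conversion rate falls below this
#'   threshold (default 0.997).
#' @return A list of class `conversion_qc` with `apparent_methylation`,
#'   `conversion_rate`, `n_reads`, and `pass`.
#' @export
conversion_qc <- function(x, control_contig, warn_below = 0.997) {
  stopifnot(inherits(x, "methylome"))
  ctrl <- as.data.table(x)[chrom == control_contig]
  if (nrow(ctrl) == 0L) {
    stop("control contig '", control_contig, "' not found; available: ",
         paste(sort(unique(x$chrom)), collapse = ", "))
  }
  n_meth <- sum(ctrl$n_meth)
  n_reads <- n_meth + sum(ctrl$n_unmeth)
  apparent <- if (n_reads > 0L) n_meth / n_reads else 0
  conv <- 1 - apparent
  if (conv < warn_below) {
    warning(sprintf(
      "conversion rate %.4f on %s below threshold %.4f for sample '%s'",
      conv, control_contig, warn_below, attr(x, "sample_id")
    ))
  }
  structure(
    list(apparent_methylation = apparent, conversion_rate = conv,
         n_reads = n_reads, pass = conv >= warn_below,
         control_contig = control_contig),
    class = "conversion_qc"
  )
}

#' @export
print.conversion_qc <- function(x, ...) {
  cat(sprintf("<conversion_qc> %s: conversion %.4f (%d reads) [%s]\n",
              x$control_contig, x$conversion_rate, x$n_reads,
              if (x$pass) "PASS" else "WARN"))
  invisible(x)
}

#' Construct gene models with unified coordinates
#'
#' @param df data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`; `start`/`end` must already be 0-based half-open.
#' @return A `data.table` of class `gene_models`.
#' @export
gene_models <- function(df) {
  dt <- as.data.table(df)[, .(gene_id = as.character(gene_id),
                              chrom = as.character(chrom),
                              start = as.integer(start), end = as.integer(end),
                              strand = as.character(strand))]
  if (nrow(dt) > 0L) {
    if (any(dt$start >= dt$end)) stop("gene intervals must satisfy start < end")
    if (any(dt$start < 0L)) stop("0-based starts must be >= 0")
    if (anyDuplicated(dt$gene_id) > 0L) stop("duplicate gene ids")
  }
  setattr(dt, "class", c("gene_models", class(dt)))
  dt[]
}

#' Read gene models from BED6 or GFF3
#'
#' Internal coordinates are 0-based half-open regardless of input dialect:
#' BED is taken as-is, GFF3 (1-based inclusive) has 1 subtracted from starts.
#' GFF3 files contribute their `gene`-type features (falling back to all
#' features when none are typed `gene`), identified by the `ID` or `Name`
#' attribute.
#'
#' @param path path to a `.bed`, `.gff`/`.gff3` (optionally `.gz`) file.
#' @param dialect `"auto"` (by extension), `"bed"`, or `"gff3"`.
#' @return A [gene_models()] table.
#' @export
read_gene_models <- function(path, dialect = c("auto", "bed", "gff3")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (dialect == "auto") {
    base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
    ext <- tolower(tools::file_ext(base))
    dialect <- switch(ext,
      bed = "bed",
      gff = "gff3", gff3 = "gff3",
      stop("cannot infer gene-model dialect from extension '.", ext,
           "'; pass dialect = 'bed' or 'gff3'")
    )
  }
  gr <- if (dialect == "bed") {
    rtracklayer::import(path, format = "BED")
  } else {
    rtracklayer::import(path, format = "GFF3")
  }
  meta <- as.data.frame(S4Vectors::mcols(gr))
  if (dialect == "gff3" && "type" %in% names(meta) &&
      any(meta$type == "gene")) {
    keep <- meta$type == "gene"
    gr <- gr[keep]
    meta <- meta[keep, , drop = FALSE]
  }
  ids <- if ("name" %in% names(meta)) as.character(meta$name)
         else if ("ID" %in% names(meta)) as.character(meta$ID)
         else if ("Name" %in% names(meta)) as.character(meta$Name)
         else paste0("feature_", seq_along(gr))
  ids[is.na(ids)] <- paste0("feature_", which(is.na(ids)))
  str <- as.character(BiocGenerics::strand(gr))
  str[!str %in% c("+", "-")] <- "+"
  gene_models(data.table(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = BiocGenerics::start(gr) - 1L,  # GRanges is 1-based inclusive
    end = BiocGenerics::end(gr),
    strand = str
  ))
}

# GRanges view of gene models / generic 0-based interval tables (internal)
.as_granges <- function(dt, ...) {
  GenomicRanges::GRanges(
    seqnames = dt$chrom,
    ranges = IRanges::IRanges(start = dt$start + 1L, end = dt$end),
    ...
  )
}
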