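#' Generate a synthetic promoter annotation
#'
#' Lays `n_promoters` one-transcript genes on `n_chrom` synthetic
#' chromosomes, TSSs `spacing` bp apart with alternating strand, and
#' returns the strand-aware 2 kb promoter windows plus chromosome sizes.
#' Windows are pairwise disjoint by construction whenever
#' `spacing >= 2000`, and chromosomes are sized so no window is clipped.
#'
#' @param config A [sim_config()] object (uses `n_promoters`, `spacing`,
#'   `n_chrom`).
#' @param gene_symbols Optional character vector of gene symbols to assign to
#'   the first promoters (used to alias planted promoters to profile genes);
#'   remaining genes are named `G0001`, `G0002`, ...
#' @return A list with `promoters` (a [GenomicRanges::GRanges] of 2 kb
#'   windows with `transcript_id`, `gene_symbol`, `tss0` metadata; `tss0` is
#'   the 0-based TSS position), and `seqlengths` (named chromosome sizes).
#' @export
generate_annotation <- function(config, gene_symbols = NULL) {
  n <- config$n_promoters
  if (n == 0L) {
    gr <- GenomicRanges::GRanges()
    return(list(promoters = gr, seqlengths = integer(0)))
  }
  per_chrom <- ceiling(n / config$n_chrom)
  chrom_len <- 20000L + per_chrom * config$spacing
  chroms <- paste0("chr", seq_len(config$n_chrom))
  idx <- seq_len(n) - 1L
  chrom <- chroms[idx %/% per_chrom + 1L]
  slot <- idx %% per_chrom
  tss0 <- 10000L + slot * config$spacing   # 0-based TSS position
  if (any(tss0 + 1000L > chrom_len)) {
    stop("sizing error: promoters do not fit on declared chromosomes")
  }
  strand <- ifelse(idx %% 2L == 0L, "+", "-")
  ids <- sprintf("T%04d", seq_len(n))
  genes <- sprintf("G%04d", seq_len(n))
  if (!is.null(gene_symbols)) {
    k <- length(gene_symbols)
    if (k > n) stop("more gene_symbols than promoters")
    genes[seq_len(k)] <- gene_symbols
  }
  seqlen <- stats::setNames(rep(chrom_len, config$n_chrom), chroms)
  # 0-based half-open [tss0 - 1000, tss0 + 1000) -> 1-based closed
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = tss0 - 999L, end = tss0 + 1000L),
    strand = strand,
    transcript_id = ids,
    gene_symbol = genes,
    tss0 = tss0,
    seqlengths = seqlen
  )
  names(gr) <- ids
  list(promoters = gr, seqlengths = seqlen)
}

#' Write a promoter set as BED6
#'
#' 0-based half-open windows; the name field is `transcript_id|gene_symbol`.
#'
#' @param promoters GRanges from [generate_annotation()] or
#'   [parse_promoters()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_promoter_bed <- function(promoters, path) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(promoters)),
    start = GenomicRanges::start(promoters) - 1L,
    end = GenomicRanges::end(promoters),
    name = paste(promoters$transcript_id, promoters$gene_symbol, sep = "|"),
    score = 0L,
    strand = as.character(GenomicRanges::strand(promoters))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write a promoter set as a GENCODE-style GTF of transcript records
#'
#' Each promoter's source transcript is written as a 1-based closed
#' `transcript` feature whose TSS (start on +, end on -) reproduces the
#' promoter window center. Transcript bodies extend 2 kb downstream.
#'
#' @inheritParams write_promoter_bed
#' @return `path`, invisibly.
#' @export
write_promoter_gtf <- function(promoters, path) {
  tss0 <- promoters$tss0
  strand <- as.character(GenomicRanges::strand(promoters))
  start1 <- ifelse(strand == "+", tss0 + 1L, tss0 + 1L - 2000L)
  end1 <- ifelse(strand == "+", tss0 + 1L + 2000L, tss0 + 1L)
  attr_field <- sprintf(
    'gene_id "%s"; transcript_id "%s"; gene_name "%s";',
    promoters$gene_symbol, promoters$transcript_id, promoters$gene_symbol)
  lines <- sprintf("%s\tcfpe_sim\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                   as.character(GenomicRanges::seqnames(promoters)),
                   start1, end1, strand, attr_field)
  writeLines(lines, path)
  invisible(path)
}
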