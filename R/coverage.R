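# Promoter windows, read counting, RPKM and MoM normalization.
#
# Coordinate conventions: promoter windows are 2 kb intervals centered on
# the transcription start site, stored internally as GRanges (1-based
# closed) but defined on the 0-based half-open interval
# [tss - 1000, tss + 1000). A single-end read is assigned to a window by
# its leftmost aligned base by default (`count_mode = "start"`); windows
# dwarf the read length so this differs negligibly from any-overlap
# counting, which is available as `count_mode = "overlap"`.

#' Construct promoter windows from TSS positions
#'
#' @param chrom Character chromosome per transcript.
#' @param tss0 0-based TSS position per transcript.
#' @param strand "+" or "-" per transcript.
#' @param transcript_id,gene_symbol Identifiers.
#' @param half_width Half window width in bp (default 1000, i.e. 2 kb
#'   windows).
#' @return GRanges of windows ordered by (chrom, start, transcript_id) with
#'   metadata columns transcript_id, gene_symbol, tss0.
#' @export
promoter_windows <- function(chrom, tss0, strand, transcript_id,
                             gene_symbol = transcript_id,
                             half_width = 1000L) {
  if (any(!strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = tss0 - half_width + 1L,
                              end = tss0 + half_width),
    strand = strand,
    transcript_id = transcript_id,
    gene_symbol = gene_symbol,
    tss0 = as.integer(tss0)
  )
  ord <- order(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr), gr$transcript_id)
  gr <- gr[ord]
  names(gr) <- gr$transcript_id
  gr
}

#' Parse a promoter annotation into TSS windows
#'
#' Reads a GENCODE-style GTF/GFF (transcript features) or a 6-column BED
#' and returns one 2 kb TSS-centered window per selected transcript. The
#' TSS is the transcript start on the + strand and the transcript end on
#' the - strand. In `per_gene` mode only the first-listed transcript of
#' each gene is kept and the number of dropped transcripts is reported as
#' an attribute.
#'
#' @param path Annotation file.
#' @param mode `"gtf"` or `"bed"`; default guesses from the extension.
#' @param per_gene Keep one window per gene (first-listed transcript).
#' @param half_width Half window width in bp.
#' @return GRanges of promoter windows (see [promoter_windows()]); attribute
#'   `n_dropped` counts transcripts dropped by per-gene selection.
#' @export
parse_promoters <- function(path, mode = NULL, per_gene = FALSE,
                            half_width = 1000L) {
  if (is.null(mode)) {
    mode <- if (grepl("\\.bed$", path, ignore.case = TRUE)) "bed" else "gtf"
  }
  mode <- match.arg(mode, c("gtf", "bed"))
  if (mode == "gtf") {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "#")]
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 9)
    if (length(bad)) stop("malformed GTF record at line ", bad[1])
    feat <- vapply(fields, `[[`, "", 3)
    keep <- feat == "transcript"
    fields <- fields[keep]
    if (!length(fields)) stop("no transcript features in ", path)
    chrom <- vapply(fields, `[[`, "", 1)
    start1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 4)))
    end1 <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 5)))
    strand <- vapply(fields, `[[`, "", 7)
    attrs <- vapply(fields, `[[`, "", 9)
    if (anyNA(start1) || anyNA(end1)) {
      stop("malformed coordinates at line ",
           which(keep)[which(is.na(start1) | is.na(end1))[1]])
    }
    if (any(!strand %in% c("+", "-"))) {
      stop("missing or invalid strand at line ",
           which(keep)[which(!strand %in% c("+", "-"))[1]])
    }
    get_attr <- function(a, key) {
      m <- regmatches(a, regexec(paste0(key, ' "([^"]+)"'), a))
      vapply(m, function(x) if (length(x) == 2) x[2] else NA_character_, "")
    }
    tx <- get_attr(attrs, "transcript_id")
    gene <- get_attr(attrs, "gene_name")
    gene[is.na(gene)] <- get_attr(attrs, "gene_id")[is.na(gene)]
    if (anyNA(tx)) stop("transcript_id missing in GTF attributes")
    tss0 <- ifelse(strand == "+", start1 - 1L, end1 - 1L)
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 6) stop("BED promoter annotation needs 6 columns (strand)")
    chrom <- df[[1]]
    start0 <- df[[2]]
    end0 <- df[[3]]
    strand <- df[[6]]
    if (any(!strand %in% c("+", "-"))) {
      stop("missing or invalid strand at line ",
           which(!strand %in% c("+", "-"))[1])
    }
    name <- strsplit(as.character(df[[4]]), "|", fixed = TRUE)
    tx <- vapply(name, `[[`, "", 1)
    gene <- vapply(name, function(x) if (length(x) > 1) x[2] else x[1], "")
    # a promoter BED carries precomputed windows: pass them through with
    # the TSS at the window center (symmetric windows, either strand)
    gr <- GenomicRanges::GRanges(
      seqnames = chrom,
      ranges = IRanges::IRanges(start = start0 + 1L, end = end0),
      strand = strand,
      transcript_id = tx, gene_symbol = gene,
      tss0 = as.integer(start0 + (end0 - start0) %/% 2))
    if (per_gene) {
      first <- !duplicated(gene)
      attr_drop <- sum(!first)
      gr <- gr[first]
    } else attr_drop <- 0L
    ord <- order(as.character(GenomicRanges::seqnames(gr)),
                 GenomicRanges::start(gr), gr$transcript_id)
    gr <- gr[ord]
    names(gr) <- gr$transcript_id
    attr(gr, "n_dropped") <- attr_drop
    return(gr)
  }
  n_dropped <- 0L
  if (per_gene) {
    first <- !duplicated(gene)
    n_dropped <- sum(!first)
    chrom <- chrom[first]; tss0 <- tss0[first]; strand <- strand[first]
    tx <- tx[first]; gene <- gene[first]
  }
  gr <- promoter_windows(chrom, as.integer(tss0), strand, tx, gene,
                         half_width = half_width)
  attr(gr, "n_dropped") <- n_dropped
  gr
}

#' Build a queryable window index
#'
#' Wraps a promoter GRanges so point/interval membership queries can be
#' answered; overlapping windows are supported (a position may hit several
#' windows).
#'
#' @param promoters GRanges of promoter windows.
#' @return A `window_index` object.
#' @export
build_window_index <- function(promoters) {
  structure(list(windows = promoters), class = "window_index")
}

#' Query a window index at genomic positions
#'
#' Positions are 0-based; a position hits a window `[start, end)` iff
#' `start <= pos < end`.
#'
#' @param index A `window_index`.
#' @param chrom,pos0 Parallel vectors of query positions (0-based).
#' @return List (per query) of integer indices of containing windows.
#' @export
query_windows <- function(index, chrom, pos0) {
  q <- GenomicRanges::GRanges(chrom, IRanges::IRanges(pos0 + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(q, index$windows, ignore.strand = TRUE)
  out <- vector("list", length(q))
  for (i in seq_along(out)) out[[i]] <- integer(0)
  sp <- split(S4Vectors::subjectHits(hits), S4Vectors::queryHits(hits))
  out[as.integer(names(sp))] <- lapply(sp, as.integer)
  out
}

# normalize an alignment source into (chrom, pos0, width) of retained reads
read_alignments <- function(path, read_length = 35L) {
  if (grepl("\\.bed$", path, ignore.case = TRUE)) {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            stringsAsFactors = FALSE)
    return(data.frame(chrom = df[[1]], pos0 = df[[2]],
                      width = df[[3]] - df[[2]], stringsAsFactors = FALSE))
  }
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile()
    bam <- Rsamtools::asBam(path, dest, overwrite = TRUE,
                            indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("rname", "pos", "qwidth"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isDuplicate = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE))
  r <- Rsamtools::scanBam(bam, param = param)[[1]]
  data.frame(chrom = as.character(r$rname), pos0 = r$pos - 1L,
             width = ifelse(is.na(r$qwidth), read_length, r$qwidth),
             stringsAsFactors = FALSE)
}

#' Count retained reads per promoter window
#'
#' Accepts a BAM/SAM file (standard flags honored: unmapped, secondary,
#' supplementary and duplicate records are excluded from both the window
#' counts and the total) or a fragment BED (all records counted). A read
#' is assigned by its leftmost aligned base (`count_mode = "start"`,
#' default) or by any overlap (`count_mode = "overlap"`); in overlap mode
#' a read spanning two windows is counted in both. `total_mapped` counts
#' every retained read genome-wide; reads on chromosomes absent from the
#' annotation count toward the total only, with a warning.
#'
#' @param path Alignment file (.bam, .sam, or .bed fragments).
#' @param index A `window_index` (or promoter GRanges).
#' @param count_mode `"start"` or `"overlap"`.
#' @return list(raw_counts = named integer per window, total_mapped =
#'   integer).
#' @export
count_reads <- function(path, index, count_mode = c("start", "overlap")) {
  count_mode <- match.arg(count_mode)
  if (inherits(index, "window_index")) index <- index$windows
  aln <- read_alignments(path)
  total_mapped <- nrow(aln)
  known <- unique(as.character(GenomicRanges::seqnames(index)))
  unknown <- setdiff(unique(aln$chrom), known)
  if (length(unknown) && length(index)) {
    warning("reads on chromosomes absent from the annotation (counted ",
            "toward total only): ", paste(unknown, collapse = ", "))
  }
  if (length(index) == 0) {
    return(list(raw_counts = integer(0), total_mapped = total_mapped))
  }
  keep <- aln$chrom %in% known
  if (count_mode == "start") {
    q <- GenomicRanges::GRanges(aln$chrom[keep],
                                IRanges::IRanges(aln$pos0[keep] + 1L,
                                                 width = 1L))
  } else {
    q <- GenomicRanges::GRanges(aln$chrom[keep],
                                IRanges::IRanges(aln$pos0[keep] + 1L,
                                                 width = pmax(1L, aln$width[keep])))
  }
  cnt <- GenomicRanges::countOverlaps(index, q, ignore.strand = TRUE)
  raw <- stats::setNames(as.integer(cnt), index$transcript_id)
  list(raw_counts = raw, total_mapped = total_mapped)
}

#' Count reads for many samples into a coverage matrix
#'
#' @param paths Named character vector (sample id -> alignment file).
#' @param index Window index or promoter GRanges.
#' @param count_mode See [count_reads()].
#' @return A `coverage_matrix` (RPKM-normalized; see [rpkm_normalize()]).
#' @export
coverage_matrix_from_files <- function(paths, index,
                                       count_mode = c("start", "overlap")) {
  count_mode <- match.arg(count_mode)
  if (is.null(names(paths))) names(paths) <- basename(paths)
  res <- lapply(paths, count_reads, index = index, count_mode = count_mode)
  counts <- do.call(rbind, lapply(res, `[[`, "raw_counts"))
  rownames(counts) <- names(paths)
  total <- vapply(res, `[[`, numeric(1), "total_mapped")
  rpkm_normalize(counts, total)
}

#' RPKM-normalize a raw count matrix
#'
#' pTSS coverage: `count x 1e9 / (total_mapped x 2000)` for 2 kb windows
#' (generally `count x 1e9 / (total_mapped x window_bp)`).
#'
#' @param counts Integer matrix, samples x promoters.
#' @param total_mapped Per-sample total mapped reads (named or in row order).
#' @param window_bp Window length in bp (default 2000).
#' @return A `coverage_matrix`: list(rpkm, counts, total_mapped, window_bp).
#' @export
rpkm_normalize <- function(counts, total_mapped, window_bp = 2000) {
  counts <- as.matrix(counts)
  if (length(total_mapped) != nrow(counts)) {
    stop("total_mapped must have one entry per sample")
  }
  if (any(total_mapped <= 0)) {
    stop("sample(s) with zero total mapped reads: ",
         paste(rownames(counts)[total_mapped <= 0], collapse = ", "))
  }
  if (any(counts < 0)) stop("negative counts")
  rpkm <- counts * 1e9 / (as.vector(total_mapped) * window_bp)
  structure(list(rpkm = rpkm, counts = counts,
                 total_mapped = stats::setNames(as.vector(total_mapped),
                                                rownames(counts)),
                 window_bp = window_bp),
            class = "coverage_matrix")
}

#' @export
print.coverage_matrix <- function(x, ...) {
  cat("<coverage_matrix>", nrow(x$rpkm), "samples x", ncol(x$rpkm),
      "promoters; median total mapped", stats::median(x$total_mapped), "\n")
  invisible(x)
}

#' Multiple-of-the-median normalization
#'
#' Rescales each RPKM cell by the median RPKM of the *control* samples of
#' the same dataset at that promoter. Promoters whose control median is 0
#' in a dataset are undefined (NA) for every sample of that dataset —
#' never infinite or pseudocounted. By construction the within-dataset
#' control median of defined MoM values is 1 (exact for odd control
#' counts).
#'
#' @param cov A `coverage_matrix` (or plain RPKM matrix).
#' @param labels Per-sample class labels ("control"/"EPE"/"LPE"), named or
#'   in row order.
#' @param dataset_ids Per-sample dataset ids, named or in row order.
#' @return A `mom_matrix`: list(mom, dataset_ids, labels, control_medians
#'   (dataset x promoter), undefined (dataset x promoter logical)).
#' @export
mom_normalize <- function(cov, labels, dataset_ids) {
  rpkm <- if (inherits(cov, "coverage_matrix")) cov$rpkm else as.matrix(cov)
  n <- nrow(rpkm)
  labels <- align_meta(labels, rownames(rpkm), "labels")
  dataset_ids <- align_meta(dataset_ids, rownames(rpkm), "dataset_ids")
  datasets <- unique(dataset_ids)
  med <- matrix(NA_real_, length(datasets), ncol(rpkm),
                dimnames = list(datasets, colnames(rpkm)))
  mom <- rpkm
  for (ds in datasets) {
    in_ds <- dataset_ids == ds
    ctrl <- in_ds & labels == "control"
    if (!any(ctrl)) stop("dataset with zero control samples: ", ds)
    m <- apply(rpkm[ctrl, , drop = FALSE], 2, stats::median)
    med[ds, ] <- m
    denom <- ifelse(m > 0, m, NA_real_)
    mom[in_ds, ] <- sweep(rpkm[in_ds, , drop = FALSE], 2, denom, `/`)
  }
  structure(list(mom = mom, dataset_ids = dataset_ids, labels = labels,
                 control_medians = med, undefined = med == 0),
            class = "mom_matrix")
}

#' @export
print.mom_matrix <- function(x, ...) {
  cat("<mom_matrix>", nrow(x$mom), "samples x", ncol(x$mom), "promoters;",
      sum(x$undefined), "undefined (dataset, promoter) cells\n")
  invisible(x)
}

align_meta <- function(v, ids, what) {
  if (!is.null(names(v))) {
    if (!all(ids %in% names(v))) stop(what, " missing entries for some samples")
    v <- v[ids]
  } else if (length(v) != length(ids)) {
    stop(what, " must have one entry per sample")
  }
  unname(v)
}

#' Write / read a samples-x-promoters matrix as TSV
#'
#' Header row of promoter ids, index column `sample_id`.
#'
#' @param m Numeric matrix with dimnames.
#' @param path File path.
#' @return `path` (write) or the matrix (read).
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  write_tsv(df, path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}
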