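make_gtf <- function(path, rows) {
  writeLines(vapply(rows, function(r) {
    sprintf("%s\tsrc\ttranscript\t%d\t%d\t.\t%s\t.\tgene_id \"%s\"; transcript_id \"%s\"; gene_name \"%s\";",
            r$chrom, r$start, r$end, r$strand, r$gene, r$tx, r$gene)
  }, ""), path)
  path
}

test_that("GTF TSS windows honor strand and 1-based to 0-based conversion", {
  f <- withr::local_tempfile(fileext = ".gtf")
  make_gtf(f, list(
    list(chrom = "chr1", start = 5001, end = 7000, strand = "+",
         tx = "tx_plus", gene = "GP"),
    list(chrom = "chr1", start = 5001, end = 7000, strand = "-",
         tx = "tx_minus", gene = "GM")))
  gr <- parse_promoters(f, mode = "gtf")
  plus <- gr[gr$transcript_id == "tx_plus"]
  minus <- gr[gr$transcript_id == "tx_minus"]
  expect_equal(plus$tss0, 5000L)
  expect_equal(GenomicRanges::start(plus) - 1L, 4000L)
  expect_equal(GenomicRanges::end(plus), 6000L)
  expect_equal(minus$tss0, 6999L)
  expect_equal(GenomicRanges::start(minus) - 1L, 5999L)
  expect_equal(GenomicRanges::end(minus), 7999L)
})

test_that("BED6 windows round-trip through the annotation writer", {
  cfg <- sim_config(n_promoters = 30, seed = 2)
  ann <- generate_annotation(cfg)
  f <- withr::local_tempfile(fileext = ".bed")
  write_promoter_bed(ann$promoters, f)
  gr <- parse_promoters(f, mode = "bed")
  expect_equal(sort(gr$transcript_id), sort(ann$promoters$transcript_id))
  m <- match(ann$promoters$transcript_id, gr$transcript_id)
  expect_equal(GenomicRanges::start(gr)[m],
               GenomicRanges::start(ann$promoters))
  expect_equal(gr$tss0[m], ann$promoters$tss0)
  g <- withr::local_tempfile(fileext = ".gtf")
  write_promoter_gtf(ann$promoters, g)
  gr2 <- parse_promoters(g, mode = "gtf")
  m2 <- match(ann$promoters$transcript_id, gr2$transcript_id)
  expect_equal(gr2$tss0[m2], ann$promoters$tss0)
})

test_that("per-gene mode keeps the first transcript and reports drops", {
  f <- withr::local_tempfile(fileext = ".gtf")
  make_gtf(f, list(
    list(chrom = "chr1", start = 5001, end = 7000, strand = "+",
         tx = "t1", gene = "G1"),
    list(chrom = "chr1", start = 9001, end = 11000, strand = "+",
         tx = "t2", gene = "G1"),
    list(chrom = "chr1", start = 20001, end = 21000, strand = "-",
         tx = "t3", gene = "G2")))
  all_tx <- parse_promoters(f)
  per_gene <- parse_promoters(f, per_gene = TRUE)
  expect_length(all_tx, 3)
  expect_length(per_gene, 2)
  expect_equal(attr(per_gene, "n_dropped"), 1L)
  expect_setequal(per_gene$transcript_id, c("t1", "t3"))
})

test_that("malformed annotations fail loudly", {
  f <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c("chr1\tsrc\ttranscript\t100\t200\t.\t.\t.\tgene_id \"g\"; transcript_id \"t\";"), f)
  expect_error(parse_promoters(f), "strand")
  f2 <- withr::local_tempfile(fileext = ".gtf")
  writeLines("chr1\tsrc\ttranscript\tabc\t200\t.\t+\t.\tgene_id \"g\"; transcript_id \"t\";", f2)
  expect_error(parse_promoters(f2), "coordinates")
  f3 <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t100\t2100\tt|g\t0", f3)  # five columns, no strand
  expect_error(parse_promoters(f3, mode = "bed"), "6 columns")
})

test_that("window index is half-open and matches a brute-force scan", {
  w <- promoter_windows(chrom = c("chr1", "chr1", "chr2"),
                        tss0 = c(5000L, 5600L, 5000L),
                        strand = c("+", "-", "+"),
                        transcript_id = c("a", "b", "c"))
  idx <- build_window_index(w)
  # window a spans [4000, 6000): start hits, end misses
  expect_equal(query_windows(idx, "chr1", 4000)[[1]], c(1L, 2L)[1])
  expect_equal(length(query_windows(idx, "chr1", 6000)[[1]]) == 0 ||
                 !(1L %in% query_windows(idx, "chr1", 6000)[[1]]), TRUE)
  # overlapping windows both reported
  expect_setequal(query_windows(idx, "chr1", 5500)[[1]], c(1L, 2L))
  # 1,000 random queries equal a linear scan
  set.seed(1)
  qc <- sample(c("chr1", "chr2", "chr3"), 1000, replace = TRUE)
  qp <- sample(0:8000, 1000, replace = TRUE)
  got <- query_windows(idx, qc, qp)
  wdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(w)),
                    start0 = GenomicRanges::start(w) - 1,
                    end0 = GenomicRanges::end(w))
  for (i in seq_len(1000)) {
    want <- which(wdf$chrom == qc[i] & qp[i] >= wdf$start0 & qp[i] < wdf$end0)
    expect_identical(sort(got[[i]]), as.integer(want))
  }
})

test_that("counting honors flags and matches a per-read recount", {
  w <- promoter_windows("chr1", 10000L, "+", "only")
  idx <- build_window_index(w)
  d <- withr::local_tempdir()
  sam <- file.path(d, "toy.sam")
  lines <- c("@HD\tVN:1.6\tSO:coordinate",
             "@SQ\tSN:chr1\tLN:50000",
             sprintf("in\t0\tchr1\t%d\t60\t35M\t*\t0\t0\t*\t*", 9500),
             sprintf("dup\t1024\tchr1\t%d\t60\t35M\t*\t0\t0\t*\t*", 9600),
             sprintf("sec\t256\tchr1\t%d\t60\t35M\t*\t0\t0\t*\t*", 9700),
             "unm\t4\t*\t0\t0\t*\t*\t0\t0\t*\t*",
             sprintf("out%d\t0\tchr1\t%d\t60\t35M\t*\t0\t0\t*\t*",
                     1:9, seq(20000, 28000, by = 1000)))
  writeLines(lines, sam)
  cnt <- count_reads(sam, idx)
  # 1 read starts inside the window; 9 mapped elsewhere; dup/sec/unmapped
  # excluded from both tallies
  expect_equal(unname(cnt$raw_counts), 1)
  expect_equal(cnt$total_mapped, 10)
})

test_that("random alignments match the brute-force oracle (start and overlap)", {
  cfg <- sim_config(n_promoters = 5, spacing = 4000,
                    dataset_sizes = list(d = c(n_control = 1, n_epe = 0,
                                               n_lpe = 0)),
                    mean_reads_per_sample = 200, seed = 31)
  truth <- simulate_truth(cfg)
  d <- withr::local_tempdir()
  files <- generate_reads(truth, d, as_bam = TRUE)
  idx <- build_window_index(truth$promoters)
  bed <- utils::read.table(files$bed[1], sep = "\t")
  reads <- data.frame(chrom = bed[[1]], pos0 = bed[[2]])
  wdf <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(truth$promoters)),
    start0 = GenomicRanges::start(truth$promoters) - 1,
    end0 = GenomicRanges::end(truth$promoters))
  want <- brute_count(wdf, reads)
  got <- count_reads(files$bam[1], idx)
  expect_equal(unname(got$raw_counts), want)
  expect_equal(got$total_mapped, nrow(reads))
  # overlap mode counts reads whose body enters the window
  got_ov <- count_reads(files$bam[1], idx, count_mode = "overlap")
  want_ov <- vapply(seq_len(nrow(wdf)), function(i) {
    sum(reads$chrom == wdf$chrom[i] &
          reads$pos0 + 35 > wdf$start0[i] & reads$pos0 < wdf$end0[i])
  }, numeric(1))
  expect_equal(unname(got_ov$raw_counts), want_ov)
  expect_true(all(got_ov$raw_counts >= got$raw_counts))
})

test_that("reads on unknown chromosomes count toward the total only", {
  w <- promoter_windows("chr1", 10000L, "+", "only")
  d <- withr::local_tempdir()
  sam <- file.path(d, "toy.sam")
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:chr1\tLN:50000", "@SQ\tSN:chrX\tLN:50000",
               "a\t0\tchr1\t9500\t60\t35M\t*\t0\t0\t*\t*",
               "b\t0\tchrX\t9500\t60\t35M\t*\t0\t0\t*\t*"), sam)
  expect_warning(cnt <- count_reads(sam, build_window_index(w)), "chrX")
  expect_equal(unname(cnt$raw_counts), 1)
  expect_equal(cnt$total_mapped, 2)
})

test_that("RPKM follows the coverage formula exactly", {
  counts <- matrix(c(10L, 0L), 1, 2,
                   dimnames = list("s1", c("P1", "P2")))
  cov <- rpkm_normalize(counts, 1e6)
  expect_identical(unname(cov$rpkm[1, 1]), 10 * 1e9 / (1e6 * 2000))  # = 5
  expect_identical(unname(cov$rpkm[1, 2]), 0)
  # doubling the library size halves every value
  cov2 <- rpkm_normalize(counts, 2e6)
  expect_equal(cov2$rpkm, cov$rpkm / 2)
  expect_error(rpkm_normalize(counts, 0), "zero total")
})

test_that("MoM divides by per-dataset control medians and flags zeros", {
  fx <- mom_fixture()
  cov <- rpkm_normalize(fx$counts, fx$total)
  mom <- mom_normalize(cov, fx$labels, fx$datasets)
  # dataset A controls at P1: RPKM prop to {10,12,14}, median from count 12
  expect_equal(unname(mom$mom["A_c2", "P1"]), 1)
  expect_equal(unname(mom$mom["A_x1", "P1"]), 20 / 12)
  # case with RPKM twice the control median
  expect_equal(unname(mom$mom["B_x1", "P2"]), 30 / 12)
  # P3 has control median 0 in dataset A: undefined there, defined in B
  expect_true(all(is.na(mom$mom[fx$datasets == "A", "P3"])))
  expect_false(anyNA(mom$mom[fx$datasets == "B", "P3"]))
  expect_true(mom$undefined["A", "P3"])
  expect_equal(sum(mom$undefined), 1)
  # {2,4,6} controls and a case at 8 -> case MoM 2 (median 4)
  cnt <- rbind(c1 = 2L, c2 = 4L, c3 = 6L, x = 8L)
  colnames(cnt) <- "P"
  mm <- mom_normalize(rpkm_normalize(cnt, rep(1e6, 4)),
                      labels = c("control", "control", "control", "EPE"),
                      dataset_ids = rep("d", 4))
  expect_equal(unname(mm$mom["x", "P"]), 2)
  expect_error(mom_normalize(cov, rep("EPE", 8), fx$datasets),
               "zero control")
})

test_that("per-dataset control median of MoM equals 1 for odd control counts", {
  cfg <- tiny_config()
  co <- simulate_cohort(cfg)
  lab <- stats::setNames(co$truth$samples$label, co$truth$samples$sample_id)
  ds <- stats::setNames(co$truth$samples$dataset, co$truth$samples$sample_id)
  mom <- mom_normalize(co$coverage, lab, ds)
  for (d in unique(ds)) {
    ctrl <- names(lab)[lab == "control" & ds == d]
    meds <- apply(mom$mom[ctrl, , drop = FALSE], 2, stats::median)
    defined <- !is.na(meds)
    expect_true(all(abs(meds[defined] - 1) < 1e-12))
  }
})

test_that("a pure per-dataset depth multiplier leaves MoM unchanged", {
  fx <- mom_fixture()
  cov1 <- rpkm_normalize(fx$counts, fx$total)
  scaled <- fx$counts
  scaled[fx$datasets == "B", ] <- scaled[fx$datasets == "B", ] * 7
  tot2 <- fx$total
  tot2[fx$datasets == "B"] <- tot2[fx$datasets == "B"] * 7
  cov2 <- rpkm_normalize(scaled, tot2)
  m1 <- mom_normalize(cov1, fx$labels, fx$datasets)
  m2 <- mom_normalize(cov2, fx$labels, fx$datasets)
  expect_equal(m1$mom, m2$mom, tolerance = 1e-12)
  # also when the multiplier hits counts only (expected-count fixture)
  cov3 <- rpkm_normalize(scaled, fx$total)
  m3 <- mom_normalize(cov3, fx$labels, fx$datasets)
  expect_equal(m1$mom, m3$mom, tolerance = 1e-12)
})

test_that("matrix TSV round-trips", {
  m <- matrix(c(1.5, 0, 2.25, 3), 2, 2,
              dimnames = list(c("s1", "s2"), c("P1", "P2")))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_matrix_tsv(m, f)
  expect_equal(read_matrix_tsv(f), m)
})
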