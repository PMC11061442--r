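test_that("annotation windows are 2 kb, centered, disjoint, both strands", {
  cfg <- sim_config(n_promoters = 100, spacing = 10000, seed = 1)
  ann <- generate_annotation(cfg)
  gr <- ann$promoters
  expect_length(gr, 100)
  expect_true(all(GenomicRanges::width(gr) == 2000))
  # 0-based half-open [tss - 1000, tss + 1000)
  expect_true(all(GenomicRanges::start(gr) - 1 == gr$tss0 - 1000))
  expect_true(all(GenomicRanges::end(gr) == gr$tss0 + 1000))
  expect_setequal(unique(as.character(GenomicRanges::strand(gr))),
                  c("+", "-"))
  # pairwise disjoint: no self-overlaps beyond identity
  hits <- GenomicRanges::findOverlaps(gr, gr, ignore.strand = TRUE)
  expect_equal(sum(S4Vectors::queryHits(hits) != S4Vectors::subjectHits(hits)),
               0)
  # no window clipped by contig bounds
  expect_true(all(GenomicRanges::end(gr) <=
                    ann$seqlengths[as.character(GenomicRanges::seqnames(gr))]))
})

test_that("a single promoter at TSS 10000 spans [9000, 11000)", {
  cfg <- sim_config(n_promoters = 1, seed = 1)
  gr <- generate_annotation(cfg)$promoters
  expect_equal(gr$tss0, 10000L)
  expect_equal(GenomicRanges::start(gr) - 1L, 9000L)  # 0-based start
  expect_equal(GenomicRanges::end(gr), 11000L)        # half-open end
})

test_that("empty annotation propagates to an empty count matrix", {
  cfg <- sim_config(n_promoters = 0, seed = 1)
  ann <- generate_annotation(cfg)
  expect_length(ann$promoters, 0)
  truth <- simulate_truth(cfg)
  cov <- simulate_counts(truth)
  expect_equal(ncol(cov$counts), 0)
  expect_true(all(cov$total_mapped > 0))  # background reads still counted
})

test_that("seed fully determines annotation, counts, clinical and reads", {
  cfg <- tiny_config()
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$truth$rates, b$truth$rates)
  expect_identical(a$coverage$counts, b$coverage$counts)
  expect_identical(a$coverage$total_mapped, b$coverage$total_mapped)
  expect_identical(a$clinical, b$clinical)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  ids <- a$truth$samples$sample_id[1:2]
  f1 <- generate_reads(a$truth, d1, sample_ids = ids)
  f2 <- generate_reads(b$truth, d2, sample_ids = ids)
  for (i in seq_len(nrow(f1))) {
    expect_identical(readLines(f1$sam[i]), readLines(f2$sam[i]))
    expect_identical(readLines(f1$bed[i]), readLines(f2$bed[i]))
  }
  # a different seed changes the draws
  c2 <- simulate_cohort(tiny_config(seed = 99))
  expect_false(identical(a$coverage$counts, c2$coverage$counts))
})

test_that("read-level counts follow the declared Poisson model", {
  # one promoter with rate 0.01 of 1e5 reads -> Poisson(1000) per sample
  cfg <- sim_config(
    n_promoters = 2,
    dataset_sizes = list(d = c(n_control = 500, n_epe = 0, n_lpe = 0)),
    mean_reads_per_sample = 1e5, seed = 42)
  truth <- simulate_truth(cfg)
  truth$rates <- stats::setNames(c(0.01, 0), names(truth$rates))
  cov <- simulate_counts(truth)
  x <- cov$counts[, 1]
  expect_equal(mean(x), 1000, tolerance = 3 * sqrt(1000 / 500) / 1000)
  # variance consistent with Poisson: var/mean ratio near 1
  expect_gt(var(x) / mean(x), 0.8)
  expect_lt(var(x) / mean(x), 1.25)
  # a promoter with rate 0 draws exactly zero reads
  expect_true(all(cov$counts[, 2] == 0))
})

test_that("rate-zero promoters receive no read placements either", {
  cfg <- sim_config(n_promoters = 3,
                    dataset_sizes = list(d = c(n_control = 2, n_epe = 0,
                                               n_lpe = 0)),
                    mean_reads_per_sample = 2000, seed = 5)
  truth <- simulate_truth(cfg)
  truth$rates[2] <- 0
  truth$rates <- truth$rates / sum(truth$rates) * 0.3
  d <- withr::local_tempdir()
  files <- generate_reads(truth, d)
  idx <- build_window_index(truth$promoters)
  for (f in files$bed) {
    cnt <- count_reads(f, idx)
    expect_equal(unname(cnt$raw_counts[2]), 0)
  }
})

test_that("planted fold changes converge to the case/control count ratio", {
  cfg <- sim_config(
    n_promoters = 20,
    dataset_sizes = list(d = c(n_control = 400, n_epe = 400, n_lpe = 0)),
    mean_reads_per_sample = 5e4,
    planted_epe = c(T0003 = 2.0, T0007 = 0.5),
    seed = 8)
  truth <- simulate_truth(cfg)
  cov <- simulate_counts(truth)
  lab <- truth$samples$label
  ratio <- colMeans(cov$counts[lab == "EPE", ]) /
    colMeans(cov$counts[lab == "control", ])
  expect_equal(unname(ratio["T0003"]), 2.0, tolerance = 0.05)
  expect_equal(unname(ratio["T0007"]), 0.5, tolerance = 0.05)
  expect_equal(unname(ratio["T0001"]), 1.0, tolerance = 0.05)
  # truth ledger directions follow the fold changes
  dirs <- truth_directions(truth, "EPE")
  expect_equal(dirs$direction[dirs$promoter_id == "T0003"], "+")
  expect_equal(dirs$direction[dirs$promoter_id == "T0007"], "-")
})

test_that("negative-binomial noise needs a positive dispersion and inflates variance", {
  expect_error(sim_config(noise_model = "negative_binomial", dispersion = 0),
               "dispersion")
  cfg <- sim_config(
    n_promoters = 5,
    dataset_sizes = list(d = c(n_control = 600, n_epe = 0, n_lpe = 0)),
    mean_reads_per_sample = 2e4,
    noise_model = "negative_binomial", dispersion = 0.3, seed = 3)
  cov <- simulate_counts(simulate_truth(cfg))
  mu <- colMeans(cov$counts)
  v <- apply(cov$counts, 2, var)
  expect_true(all(v > 1.5 * mu))  # clearly super-Poissonian
})

test_that("clinical tables are internally consistent and class-structured", {
  cfg <- tiny_config()
  truth <- simulate_truth(cfg)
  clin <- simulate_clinical(truth)
  expect_equal(nrow(clin), nrow(truth$samples))
  expect_equal(clin$bmi, clin$weight / clin$height^2, tolerance = 1e-9)
  expect_true(all(clin$gravidity >= 1))
  expect_true(all(clin$conception %in% c("IVF", "natural")))
  pmh <- clin$pmh_htn + clin$pmh_pe + clin$pmh_sle + clin$pmh_aps
  expect_true(all(pmh >= 0 & pmh <= 4))
  # zero IVF probability for controls -> no IVF controls in any draw
  pars <- default_clinical_params()
  pars$control$p_ivf <- 0
  cfg2 <- tiny_config(clinical_params = pars)
  clin2 <- simulate_clinical(simulate_truth(cfg2))
  expect_equal(sum(clin2$conception == "IVF" & clin2$label == "control"), 0)
})

test_that("early-onset cases deliver earlier than controls", {
  clin <- simulate_clinical(simulate_truth(tiny_config()))
  expect_lt(median(clin$ga_delivery[clin$label == "EPE"]),
            median(clin$ga_delivery[clin$label == "control"]) - 3)
})

test_that("generated SAM converts to BAM and matches its fragment BED", {
  cfg <- tiny_config(n_promoters = 10)
  truth <- simulate_truth(cfg)
  d <- withr::local_tempdir()
  ids <- truth$samples$sample_id[1:2]
  files <- generate_reads(truth, d, sample_ids = ids, as_bam = TRUE)
  idx <- build_window_index(truth$promoters)
  for (i in seq_len(nrow(files))) {
    from_bam <- count_reads(files$bam[i], idx)
    from_bed <- count_reads(files$bed[i], idx)
    expect_identical(from_bam$raw_counts, from_bed$raw_counts)
    expect_identical(from_bam$total_mapped, from_bed$total_mapped)
  }
})
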