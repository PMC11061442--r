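test_that("rank-sum p-values match known exact cases", {
  # fully separated 3-vs-3: 2 of the 20 assignments are as extreme
  expect_equal(wilcoxon_two_sided(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_two_sided(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxon_two_sided(rep(2, 5), rep(2, 7)), 1)
  expect_error(wilcoxon_two_sided(numeric(0), 1:3), "non-empty")
})

test_that("exact path equals the enumeration oracle on random instances", {
  set.seed(101)
  for (k in 1:50) {
    nx <- sample(2:6, 1); ny <- sample(2:6, 1)
    x <- round(rnorm(nx), 4); y <- round(rnorm(ny, sd = 2), 4)
    expect_equal(wilcoxon_two_sided(x, y), enum_ranksum_p(x, y),
                 tolerance = 1e-12)
  }
})

test_that("approximation path is within 0.02 of enumeration for small n", {
  set.seed(202)
  worst <- 0
  for (k in 1:50) {
    nx <- sample(5:8, 1); ny <- sample(5:8, 1)
    x <- rnorm(nx); y <- rnorm(ny, mean = runif(1, -1, 1))
    p_approx <- wilcoxon_two_sided(x, y, exact = FALSE)
    worst <- max(worst, abs(p_approx - enum_ranksum_p(x, y)))
  }
  expect_lt(worst, 0.02)
})

test_that("the vectorized rank-sum agrees with wilcox.test on tied data", {
  set.seed(33)
  mat <- matrix(rpois(40 * 25, 5), 40, 25,
                dimnames = list(sprintf("s%02d", 1:40), sprintf("P%02d", 1:25)))
  case_idx <- 1:18; ctrl_idx <- 19:40
  rs <- cfpe:::rank_sum_cols(mat, case_idx, ctrl_idx)
  for (j in seq_len(ncol(mat))) {
    want <- if (length(unique(mat[, j])) == 1) 1 else suppressWarnings(
      stats::wilcox.test(mat[case_idx, j], mat[ctrl_idx, j],
                         exact = FALSE, correct = TRUE)$p.value)
    expect_equal(rs$p[j], want, tolerance = 1e-12)
  }
})

test_that("Fisher p-values match hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(rbind(c(2, 0), c(0, 2))), 1 / 3,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(rbind(c(5, 5), c(5, 5))), 1)
  set.seed(7)
  for (k in 1:50) {
    tab <- matrix(rpois(4, sample(1:6, 1)), 2, 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_2x2(tab), enum_fisher_p(tab),
                 tolerance = 1e-9)
  }
  expect_error(fisher_exact_2x2(rbind(c(-1, 2), c(3, 4))), "non-negative")
})

make_mom <- function(mat, labels) {
  structure(list(mom = mat, labels = unname(labels),
                 dataset_ids = rep("d", nrow(mat)),
                 control_medians = NULL, undefined = NULL),
            class = "mom_matrix")
}

test_that("subsampling degenerates sensibly at n_iter = 1 and frac = 1", {
  set.seed(12)
  mat <- matrix(rpois(60 * 10, 8), 60, 10,
                dimnames = list(sprintf("s%02d", 1:60), sprintf("P%02d", 1:10)))
  labels <- rep(c("EPE", "control"), each = 30)
  mom <- make_mom(mat, labels)
  one <- subsample_wilcoxon(mom, class = "EPE", n_iter = 1, seed = 5)
  expect_equal(nrow(one$p), 1)
  # frac = 1: no resampling variability, identical p in every iteration
  full <- subsample_wilcoxon(mom, class = "EPE", n_iter = 7, frac = 1,
                             seed = 5)
  expect_true(all(apply(full$p, 2, function(v) length(unique(v)) == 1)))
  sel <- select_biomarkers(full)
  expect_equal(sel$p_upper95, unname(full$p[1, ]))
  # identical seeds give identical p-value matrices
  again <- subsample_wilcoxon(mom, class = "EPE", n_iter = 7, frac = 1,
                              seed = 5)
  expect_identical(full$p, again$p)
  expect_error(subsample_wilcoxon(mom, class = "LPE"), "absent")
})

test_that("selection applies the strict two-part criterion", {
  calls <- structure(list(
    p = cbind(A = rep(0.001, 100), B = rep(0.04, 100),
              C = c(rep(0.001, 97), rep(0.8, 3)), D = rep(0.05, 100)),
    diff = cbind(A = rep(1, 100), B = c(rep(1, 50), rep(-1, 50)),
                 C = rep(-1, 100), D = rep(1, 100)),
    promoter_ids = c("A", "B", "C", "D"), excluded_promoters = character(0),
    class = "EPE", n_iter = 100, frac = 0.7, seed = 1),
    class = "biomarker_calls")
  sel <- select_biomarkers(calls, alpha = 0.05)
  expect_true(sel$selected[sel$promoter_id == "A"])
  expect_equal(sel$direction[sel$promoter_id == "A"], "+")
  # mixed directions are never selected even when p passes
  expect_false(sel$selected[sel$promoter_id == "B"])
  expect_equal(sel$direction[sel$promoter_id == "B"], "mixed")
  # p_upper95 above alpha fails even with clean direction
  expect_false(sel$selected[sel$promoter_id == "C"])
  # boundary: p_upper95 exactly alpha is not selected (strict <)
  expect_equal(sel$p_upper95[sel$promoter_id == "D"], 0.05)
  expect_false(sel$selected[sel$promoter_id == "D"])
  # excess zero-difference iterations demote to mixed
  calls$diff[, "A"] <- c(rep(0, 20), rep(1, 80))
  sel2 <- select_biomarkers(calls)
  expect_equal(sel2$direction[sel2$promoter_id == "A"], "mixed")
})

test_that("planted promoters are recovered with their true direction", {
  cfg <- sim_config(
    n_promoters = 40,
    dataset_sizes = list(d = c(n_control = 60, n_epe = 60, n_lpe = 0)),
    mean_reads_per_sample = 1e4,
    planted_epe = c(T0005 = 2.0, T0011 = 0.5), seed = 77)
  co <- simulate_cohort(cfg)
  lab <- stats::setNames(co$truth$samples$label, co$truth$samples$sample_id)
  ds <- stats::setNames(co$truth$samples$dataset, co$truth$samples$sample_id)
  mom <- mom_normalize(co$coverage, lab, ds)
  sub <- subsample_wilcoxon(mom, class = "EPE", n_iter = 100, seed = 42)
  sel <- select_biomarkers(sub)
  expect_true(sel$selected[sel$promoter_id == "T0005"])
  expect_equal(sel$direction[sel$promoter_id == "T0005"], "+")
  expect_true(sel$selected[sel$promoter_id == "T0011"])
  expect_equal(sel$direction[sel$promoter_id == "T0011"], "-")
  # nulls stay mostly unselected
  nulls <- sel[!sel$promoter_id %in% c("T0005", "T0011"), ]
  expect_lt(mean(nulls$selected), 0.06)
})

test_that("promoters undefined in MoM are excluded from testing", {
  set.seed(3)
  mat <- matrix(rpois(40 * 5, 6), 40, 5,
                dimnames = list(sprintf("s%02d", 1:40), sprintf("P%d", 1:5)))
  mat[, 2] <- NA
  mom <- make_mom(mat, rep(c("EPE", "control"), each = 20))
  sub <- subsample_wilcoxon(mom, class = "EPE", n_iter = 5, seed = 1)
  expect_equal(sub$excluded_promoters, "P2")
  expect_false("P2" %in% sub$promoter_ids)
})

test_that("clinical screening assigns the stated tests and finds planted shifts", {
  cfg <- tiny_config()
  clin <- simulate_clinical(simulate_truth(cfg))
  res <- screen_clinical(clin, class = "EPE")
  expect_setequal(res$test[res$factor %in% c("age", "height", "weight", "bmi")],
                  "mann_whitney")
  expect_setequal(res$test[res$factor %in% c("parity>=1", "ivf", "pmh>=1",
                                             "gravidity>=2")],
                  "fisher_exact")
  # identical case/control distributions: duplicate controls as fake cases
  ctrl <- clin[clin$label == "control", ][1:20, ]
  fake <- ctrl
  fake$label <- "EPE"
  fake$sample_id <- paste0(fake$sample_id, "_dup")
  res_null <- screen_clinical(rbind(ctrl, fake), class = "EPE")
  cat_p <- res_null$p_value[res_null$test == "fisher_exact" &
                              !res_null$degenerate]
  expect_true(all(cat_p == 1))
  cont_p <- res_null$p_value[res_null$test == "mann_whitney" &
                               !res_null$degenerate]
  expect_true(all(cont_p > 0.99))
  # a planted BMI shift is overwhelmingly significant
  set.seed(11)
  base <- clin[clin$label == "control", ][1:50, ]
  base$label <- rep(c("control", "EPE"), each = 25)
  base$bmi[base$label == "EPE"] <- base$bmi[base$label == "EPE"] + 3
  res_shift <- screen_clinical(base, class = "EPE")
  expect_lt(res_shift$p_value[res_shift$factor == "bmi"], 0.001)
  expect_equal(res_shift$stars[res_shift$factor == "bmi"], "***")
  # single-level factors are flagged degenerate, not tested
  base$conception <- "natural"
  res_deg <- screen_clinical(base, class = "EPE")
  expect_true(res_deg$degenerate[res_deg$factor == "ivf"])
  expect_true(is.na(res_deg$p_value[res_deg$factor == "ivf"]))
})
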