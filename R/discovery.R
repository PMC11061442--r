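# Stably differential promoter discovery and clinical risk-factor screening.
#
# A promoter is called a candidate cfDNA biomarker only if the upper limit
# of the 95% CI of its two-sided Wilcoxon rank-sum p-value over repeated
# 70% subsamples (interpreted as the empirical 97.5th percentile of the
# per-iteration p-values) is below alpha AND the direction of the
# case-vs-control difference is the same in every informative iteration.

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact by enumeration when both groups are small (min(n, m) <= 10) and
#' tie-free; otherwise the normal approximation with tie-corrected
#' variance and 0.5 continuity correction.
#'
#' @param x,y Numeric samples for the two groups (non-empty).
#' @param exact `NULL` (auto), or force the exact/approximate path.
#' @return Two-sided p-value in [0, 1]; 1 when all values are identical.
#' @export
wilcoxon_two_sided <- function(x, y, exact = NULL) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  if (length(unique(c(x, y))) == 1L) return(1)
  ties <- any(duplicated(c(x, y)))
  if (is.null(exact)) exact <- min(length(x), length(y)) <= 10 && !ties
  p <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = exact && !ties, correct = TRUE)$p.value)
  min(1, max(0, p))
}

# Vectorized tie-corrected normal-approximation rank-sum over matrix columns.
# Returns list(p, diff) for case rows vs control rows of `mat`. Tie counts
# come from hashing (tabulate/match) and medians from partial sorts: this
# loop runs n_iter x n_promoter times at cohort scale.
rank_sum_cols <- function(mat, case_idx, ctrl_idx) {
  nx <- length(case_idx); ny <- length(ctrl_idx)
  N <- nx + ny
  sub <- mat[c(case_idx, ctrl_idx), , drop = FALSE]
  p <- numeric(ncol(sub))
  d <- numeric(ncol(sub))
  mu <- nx * ny / 2
  half_x <- (nx + 1L) %/% 2L
  half_y <- (ny + 1L) %/% 2L
  fast_median <- function(v, n, half) {
    if (n %% 2L == 1L) {
      sort.int(v, partial = half)[half]
    } else {
      s <- sort.int(v, partial = c(half, half + 1L))
      (s[half] + s[half + 1L]) / 2
    }
  }
  for (j in seq_len(ncol(sub))) {
    v <- sub[, j]
    r <- rank(v)
    W <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
    nt <- tabulate(match(v, v), nbins = N)
    tie_term <- sum(nt^3 - nt) / (N * (N - 1))
    sigma <- sqrt(nx * ny / 12 * ((N + 1) - tie_term))
    z <- W - mu
    if (sigma == 0) {
      p[j] <- 1
    } else {
      z <- (z - sign(z) * 0.5) / sigma
      p[j] <- min(1, 2 * min(stats::pnorm(z),
                             stats::pnorm(z, lower.tail = FALSE)))
    }
    d[j] <- fast_median(v[seq_len(nx)], nx, half_x) -
      fast_median(v[nx + seq_len(ny)], ny, half_y)
  }
  list(p = p, diff = d)
}

#' Subsampled Wilcoxon stability analysis
#'
#' Repeats, `n_iter` times, a two-sided Wilcoxon rank-sum test of each
#' promoter's MoM coverage between cases of one class and controls on a
#' random 70% subsample of the input samples (stratified by class by
#' default, so every iteration keeps `floor(frac * n)` samples of each
#' group), recording the per-iteration p-value and the sign of
#' (case median - control median).
#'
#' Promoters undefined in MoM for any used sample (zero control median in
#' that sample's dataset) are excluded from testing and reported.
#'
#' @param mom A `mom_matrix` (or plain matrix with `labels` supplied).
#' @param labels Per-sample labels; defaults to the `mom_matrix` labels.
#' @param class `"EPE"` or `"LPE"` — the case class tested against controls.
#' @param n_iter Number of subsample iterations (reference protocol: 1000).
#' @param frac Subsample fraction (reference protocol: 0.7).
#' @param seed Integer seed.
#' @param stratified Stratify the subsample by case/control status.
#' @param sample_ids Optional explicit subset of samples to use (e.g. the
#'   discovery datasets only).
#' @return A `biomarker_calls` object: list(p = n_iter x promoter matrix,
#'   diff = matching median-difference matrix, promoter_ids,
#'   excluded_promoters, class, n_iter, frac, seed).
#' @export
subsample_wilcoxon <- function(mom, labels = NULL, class = c("EPE", "LPE"),
                               n_iter = 1000, frac = 0.7, seed = 1L,
                               stratified = TRUE, sample_ids = NULL) {
  class <- match.arg(class)
  if (inherits(mom, "mom_matrix")) {
    labels <- labels %||% stats::setNames(mom$labels, rownames(mom$mom))
    mat <- mom$mom
  } else {
    mat <- as.matrix(mom)
    if (is.null(labels)) stop("labels required for a plain matrix")
  }
  labels <- align_meta(labels, rownames(mat), "labels")
  if (!is.null(sample_ids)) {
    keep <- rownames(mat) %in% sample_ids
    mat <- mat[keep, , drop = FALSE]
    labels <- labels[keep]
  }
  case_rows <- which(labels == class)
  ctrl_rows <- which(labels == "control")
  if (!length(case_rows)) stop("class absent from input: ", class)
  if (!length(ctrl_rows)) stop("no control samples in input")
  defined <- colSums(is.na(mat[c(case_rows, ctrl_rows), , drop = FALSE])) == 0
  excluded <- colnames(mat)[!defined]
  mat <- mat[, defined, drop = FALSE]
  n_case <- max(2L, floor(frac * length(case_rows)))
  n_ctrl <- max(2L, floor(frac * length(ctrl_rows)))
  if (length(case_rows) < 2 || length(ctrl_rows) < 2) {
    stop("need >= 2 cases and >= 2 controls")
  }
  with_seed(seed, {
    P <- matrix(NA_real_, n_iter, ncol(mat),
                dimnames = list(NULL, colnames(mat)))
    D <- P
    for (it in seq_len(n_iter)) {
      if (stratified) {
        ci <- sample(case_rows, n_case)
        ki <- sample(ctrl_rows, n_ctrl)
      } else {
        pool <- c(case_rows, ctrl_rows)
        take <- sample(pool, floor(frac * length(pool)))
        ci <- intersect(take, case_rows)
        ki <- intersect(take, ctrl_rows)
        if (length(ci) < 2 || length(ki) < 2) {
          # degenerate unstratified draw: redraw
          repeat {
            take <- sample(pool, floor(frac * length(pool)))
            ci <- intersect(take, case_rows)
            ki <- intersect(take, ctrl_rows)
            if (length(ci) >= 2 && length(ki) >= 2) break
          }
        }
      }
      rs <- rank_sum_cols(mat, ci, ki)
      P[it, ] <- rs$p
      D[it, ] <- rs$diff
    }
    structure(list(p = P, diff = D, promoter_ids = colnames(mat),
                   excluded_promoters = excluded, class = class,
                   n_iter = n_iter, frac = frac, seed = seed),
              class = "biomarker_calls")
  })
}

#' Select stable biomarkers from subsampled calls
#'
#' Applies the two-part stability criterion: the 97.5th percentile of the
#' per-iteration p-values (the upper limit of their 95% CI) must be below
#' `alpha`, and the direction of the case-control median difference must
#' be identical in every informative (nonzero-difference) iteration.
#' Promoters with more than `max_zero_frac` zero-difference iterations are
#' demoted to direction `"mixed"` and never selected.
#'
#' @param calls A `biomarker_calls` from [subsample_wilcoxon()].
#' @param alpha Significance cutoff (strict `<`); default 0.05.
#' @param max_zero_frac Tolerated fraction of zero-difference iterations.
#' @return data.frame: promoter_id, p_upper95, p_median, direction
#'   ("+", "-", "mixed"), prop_zero_diff, selected.
#' @export
select_biomarkers <- function(calls, alpha = 0.05, max_zero_frac = 0.10) {
  P <- calls$p
  D <- calls$diff
  p_upper <- apply(P, 2, stats::quantile, probs = 0.975, names = FALSE)
  p_med <- apply(P, 2, stats::median)
  n_pos <- colSums(D > 0)
  n_neg <- colSums(D < 0)
  n_zero <- colSums(D == 0)
  zero_frac <- n_zero / nrow(D)
  direction <- rep("mixed", ncol(D))
  direction[n_neg == 0 & n_pos > 0 & zero_frac <= max_zero_frac] <- "+"
  direction[n_pos == 0 & n_neg > 0 & zero_frac <= max_zero_frac] <- "-"
  selected <- p_upper < alpha & direction != "mixed"
  data.frame(promoter_id = calls$promoter_ids,
             p_upper95 = unname(p_upper),
             p_median = unname(p_med),
             direction = direction,
             prop_zero_diff = unname(zero_frac),
             selected = unname(selected),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities of all tables with
#' the observed margins whose probability does not exceed the observed
#' table's.
#'
#' @param table 2x2 matrix of non-negative integer counts.
#' @return Two-sided p-value.
#' @export
fisher_exact_2x2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2))) stop("need a 2x2 table")
  if (any(table < 0) || any(table != round(table))) {
    stop("table must contain non-negative integers")
  }
  stats::fisher.test(table, alternative = "two.sided")$p.value
}

#' Screen clinical risk factors between one PE class and controls
#'
#' Continuous covariates (age, height, weight, BMI) are compared with the
#' Mann-Whitney U-test; categorical covariates (gravidity >= 2, parity
#' >= 1, past-medical-history score >= 1, IVF conception) with Fisher's
#' exact test on the 2x2 table. Factors with a single level in both
#' groups are flagged degenerate and not tested.
#'
#' @param clinical Clinical table ([simulate_clinical()] layout).
#' @param class `"EPE"` or `"LPE"`.
#' @param alpha_stars Significance levels mapped to `*`, `**`, `***`.
#' @return data.frame: factor, test, statistic, p_value, stars,
#'   case_summary, control_summary, degenerate.
#' @export
screen_clinical <- function(clinical, class = c("EPE", "LPE"),
                            alpha_stars = c(0.05, 0.01, 0.001)) {
  class <- match.arg(class)
  cases <- clinical[clinical$label == class, ]
  ctrls <- clinical[clinical$label == "control", ]
  if (!nrow(cases) || !nrow(ctrls)) stop("class or controls absent")
  pmh_score <- function(df) df$pmh_htn + df$pmh_pe + df$pmh_sle + df$pmh_aps
  cont <- list(age = "age", height = "height", weight = "weight", bmi = "bmi")
  cat_bin <- list(
    "gravidity>=2" = function(df) df$gravidity >= 2,
    "parity>=1" = function(df) df$parity >= 1,
    "pmh>=1" = function(df) pmh_score(df) >= 1,
    ivf = function(df) df$conception == "IVF"
  )
  star <- function(p) {
    if (is.na(p)) "" else if (p < alpha_stars[3]) "***"
    else if (p < alpha_stars[2]) "**" else if (p < alpha_stars[1]) "*"
    else "NS"
  }
  rows <- list()
  iqr_txt <- function(v) sprintf("%.1f (%.1f-%.1f)", stats::median(v),
                                 stats::quantile(v, 0.25),
                                 stats::quantile(v, 0.75))
  for (f in names(cont)) {
    x <- cases[[cont[[f]]]]; y <- ctrls[[cont[[f]]]]
    degen <- length(unique(c(x, y))) == 1L
    p <- if (degen) NA_real_ else wilcoxon_two_sided(x, y)
    rows[[length(rows) + 1L]] <- data.frame(
      factor = f, test = "mann_whitney",
      statistic = if (degen) NA_real_ else
        suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$statistic),
      p_value = p, stars = star(p),
      case_summary = iqr_txt(x), control_summary = iqr_txt(y),
      degenerate = degen, stringsAsFactors = FALSE)
  }
  for (f in names(cat_bin)) {
    xc <- cat_bin[[f]](cases); yc <- cat_bin[[f]](ctrls)
    tab <- rbind(c(sum(xc), sum(!xc)), c(sum(yc), sum(!yc)))
    degen <- length(unique(c(xc, yc))) == 1L
    p <- if (degen) NA_real_ else fisher_exact_2x2(tab)
    pct <- function(v) sprintf("%d (%.1f%%)", sum(v), 100 * mean(v))
    rows[[length(rows) + 1L]] <- data.frame(
      factor = f, test = "fisher_exact", statistic = NA_real_,
      p_value = p, stars = star(p),
      case_summary = pct(xc), control_summary = pct(yc),
      degenerate = degen, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
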