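# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own code paths.

# Exact two-sided rank-sum p by full enumeration of group assignments.
# Convention: doubled smaller tail of the permutation distribution of the
# Mann-Whitney U statistic, capped at 1 (tail probabilities include the
# observed value).
enum_ranksum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  v <- c(x, y)
  idx <- utils::combn(nx + ny, nx)
  r <- rank(v)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  u_all <- apply(idx, 2, function(i) sum(r[i]) - nx * (nx + 1) / 2)
  p_le <- mean(u_all <= u_obs)
  p_ge <- mean(u_all >= u_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Exact two-sided Fisher p by enumerating all 2x2 tables with the observed
# margins and summing hypergeometric probabilities <= the observed table's
# (with the conventional 1 + 1e-7 relative tolerance).
enum_fisher_p <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  a_min <- max(0, c1 - r2); a_max <- min(r1, c1)
  a_all <- a_min:a_max
  probs <- stats::dhyper(a_all, r1, r2, c1)
  p_obs <- stats::dhyper(tab[1, 1], r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# All-pairs AUC oracle, O(n_case x n_control).
pairs_auc <- function(scores, labels) {
  cs <- scores[labels == 1]; ks <- scores[labels == 0]
  tot <- 0
  for (c in cs) tot <- tot + sum(c > ks) + 0.5 * sum(c == ks)
  tot / (length(cs) * length(ks))
}

# Per-read brute-force window recount. windows: data.frame(chrom, start0,
# end0); reads: data.frame(chrom, pos0). Start-assignment, half-open.
brute_count <- function(windows, reads) {
  vapply(seq_len(nrow(windows)), function(i) {
    sum(reads$chrom == windows$chrom[i] &
          reads$pos0 >= windows$start0[i] &
          reads$pos0 < windows$end0[i])
  }, numeric(1))
}

# Exhaustive operating-point sweep: smallest cutoff over all distinct
# scores (and +Inf) with specificity >= target.
sweep_threshold <- function(scores, labels, target = 0.90) {
  ctrl <- scores[labels == 0]
  cand <- sort(unique(c(scores, Inf)))
  for (t in cand) if (mean(ctrl < t) >= target) return(t)
  Inf
}

# Small deterministic two-dataset expected-count fixture used by the MoM
# tests: returns list(counts, total, labels, datasets) with odd control
# counts per dataset.
mom_fixture <- function() {
  counts <- rbind(
    A_c1 = c(10, 4, 0), A_c2 = c(12, 6, 0), A_c3 = c(14, 8, 0),
    A_x1 = c(20, 2, 5),
    B_c1 = c(30, 9, 3), B_c2 = c(34, 12, 6), B_c3 = c(38, 15, 9),
    B_x1 = c(10, 30, 6))
  colnames(counts) <- c("P1", "P2", "P3")
  list(counts = counts,
       total = stats::setNames(rep(1e5, 8), rownames(counts)),
       labels = stats::setNames(c("control", "control", "control", "EPE",
                                  "control", "control", "control", "EPE"),
                                rownames(counts)),
       datasets = stats::setNames(rep(c("A", "B"), each = 4),
                                  rownames(counts)))
}

# Tiny cohort config used by several module tests.
tiny_config <- function(seed = 20240417, n_promoters = 60, ...) {
  sim_config(
    n_promoters = n_promoters,
    dataset_sizes = list(train = c(n_control = 21, n_epe = 8, n_lpe = 8),
                         iv1 = c(n_control = 15, n_epe = 6, n_lpe = 6),
                         ext = c(n_control = 15, n_epe = 6, n_lpe = 6)),
    mean_reads_per_sample = 3000,
    seed = seed, ...)
}
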