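#' PCA-based sample outlier exclusion
#'
#' Runs PCA on the samples-x-promoters coverage matrix (columns
#' mean-centered, not scaled by default) and retains samples whose scores
#' on each of the first `n_components` principal components lie within
#' `sd_cut` standard deviations of the per-component mean. Filtering is
#' single-pass: the retained set is not re-filtered. Components use a
#' deterministic sign convention (the largest-magnitude loading of each
#' component is positive). Promoter columns containing undefined (NA)
#' values are dropped before the decomposition.
#'
#' @param m A `coverage_matrix`, `mom_matrix` or plain numeric matrix
#'   (samples x promoters).
#' @param n_components Number of leading components checked (default 2).
#' @param sd_cut Exclusion threshold in standard deviations (default 3;
#'   `Inf` retains everything).
#' @param scale. Unit-scale columns before PCA (default FALSE).
#' @return A `qc_report`: list(retained_ids, excluded_ids, scores
#'   (samples x components), pc_means, pc_sds, n_components, sd_cut).
#' @export
pca_filter <- function(m, n_components = 2, sd_cut = 3, scale. = FALSE) {
  x <- if (inherits(m, "coverage_matrix")) m$rpkm
       else if (inherits(m, "mom_matrix")) m$mom
       else as.matrix(m)
  keep_col <- colSums(is.na(x)) == 0
  x <- x[, keep_col, drop = FALSE]
  if (nrow(x) < 3) stop("PCA QC needs at least 3 samples")
  if (nrow(x) <= n_components) {
    stop("fewer samples than requested components")
  }
  if (scale.) {
    sds <- apply(x, 2, stats::sd)
    x <- x[, sds > 0, drop = FALSE]
  }
  pc <- stats::prcomp(x, center = TRUE, scale. = scale., rank. = n_components)
  k <- min(n_components, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|loading| coordinate of each PC is positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(pc$rotation[, j]))
    if (pc$rotation[i_max, j] < 0) scores[, j] <- -scores[, j]
  }
  mu <- colMeans(scores)
  sds <- apply(scores, 2, stats::sd)
  z <- sweep(scores, 2, mu)
  z <- sweep(z, 2, ifelse(sds > 0, sds, 1), `/`)
  z[, sds == 0] <- 0
  bad <- apply(abs(z) > sd_cut, 1, any)
  structure(list(
    retained_ids = rownames(x)[!bad],
    excluded_ids = rownames(x)[bad],
    scores = scores,
    pc_means = mu,
    pc_sds = sds,
    n_components = k,
    sd_cut = sd_cut
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat("<qc_report>", length(x$retained_ids), "retained,",
      length(x$excluded_ids), "excluded (|z| >", x$sd_cut, "on",
      x$n_components, "PCs)\n")
  invisible(x)
}

#' Tally QC exclusions by class
#'
#' @param report A `qc_report`.
#' @param labels Named per-sample class labels.
#' @return data.frame: label, n_excluded, n_retained.
#' @export
qc_tally <- function(report, labels) {
  lv <- unique(labels)
  data.frame(
    label = lv,
    n_excluded = vapply(lv, function(l)
      sum(labels[report$excluded_ids] == l), integer(1)),
    n_retained = vapply(lv, function(l)
      sum(labels[report$retained_ids] == l), integer(1)),
    row.names = NULL
  )
}

#' Serialize a QC report to JSON
#'
#' @param report A `qc_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_json <- function(report, path) {
  obj <- list(
    retained_ids = report$retained_ids,
    excluded_ids = report$excluded_ids,
    scores = data.frame(sample_id = rownames(report$scores),
                        report$scores, check.names = FALSE),
    pc_means = report$pc_means, pc_sds = report$pc_sds,
    sd_cut = report$sd_cut
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
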