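# Synthetic multi-hospital cohort generator.
#
# The generative model mirrors what the downstream analysis assumes of real
# NIPT data: each sample has a total mapped-read budget; a fixed fraction of
# reads is attracted to promoter windows in proportion to per-promoter
# weights; case samples multiply the weights of their class's planted
# promoters by a fold change; counts are Poisson (or negative binomial)
# around those expectations; per-dataset depth differences are a pure
# multiplicative batch factor.

#' Profile gene symbols of the two classifiers
#'
#' The fixed cfDNA feature genes: 8 promoters for the early-onset profile
#' and the FLT3LG/EGF ratio pair for the late-onset profile. In synthetic
#' cohorts these symbols are aliases bound to planted promoter ids via the
#' truth ledger's `gene_map`.
#'
#' @return Character vector of gene symbols.
#' @export
epe_profile_genes <- function() {
  c("FOSL2", "CAMKK2", "CCND1", "ITPR1", "PRKACB", "WNT7B", "CACNB2", "NRF1")
}

#' @rdname epe_profile_genes
#' @export
lpe_profile_genes <- function() c("FLT3LG", "EGF")

#' Simulate the cohort truth ledger
#'
#' Assigns sample ids, dataset membership and class labels, draws
#' per-promoter baseline rates, and resolves the planted differential
#' promoters for each class context. When `config$planted_epe` /
#' `planted_lpe` are `NULL`, the default plants are the 8-gene early-onset
#' profile (all at `epe_fold`, alternating direction: six up, two down for
#' CACNB2/NRF1) and the late-onset pair FLT3LG at `lpe_fold` (up) and EGF
#' at `1/lpe_fold` (down).
#'
#' @param config A [sim_config()].
#' @return A `truth_ledger` list: `samples` (data.frame: sample_id,
#'   dataset, label), `rates` (named per-promoter weights summing to
#'   `window_weight`), `planted_epe`, `planted_lpe` (named fold-change
#'   vectors), `gene_map` (gene symbol -> promoter id for profile genes),
#'   and the annotation.
#' @export
simulate_truth <- function(config) {
  with_seed(config$seed, {
    n <- config$n_promoters
    profile_genes <- c(epe_profile_genes(), lpe_profile_genes())
    ann <- generate_annotation(config)
    prom_ids <- if (n > 0) ann$promoters$transcript_id else character(0)

    # per-promoter attraction weights: gamma heterogeneity, renormalized
    g <- if (n > 0) stats::rgamma(n, shape = config$rate_shape, rate = 1) else numeric(0)
    rates <- if (n > 0) config$window_weight * g / sum(g) else numeric(0)
    names(rates) <- prom_ids

    # bind the profile gene symbols to reliably covered but *typical*
    # promoters (top-quartile rate boundary): profile genes must have a
    # nonzero control median at sparse depth, yet must not carry so much
    # absolute coverage that the planted effects dominate the cohort's
    # principal components (the PCA QC would then flag cases wholesale,
    # which real cohorts do not show)
    gene_map <- NULL
    if (n >= length(profile_genes)) {
      k <- length(profile_genes)
      ord <- order(rates, decreasing = TRUE)
      start <- max(1L, min(floor(0.25 * n), n - k + 1L))
      picked <- ord[start:(start + k - 1L)]
      gene_map <- stats::setNames(prom_ids[picked], profile_genes)
      sym <- ann$promoters$gene_symbol
      sym[picked] <- profile_genes
      ann$promoters$gene_symbol <- sym
    }
    planted_epe <- config$planted_epe
    planted_lpe <- config$planted_lpe
    if (is.null(planted_epe) && !is.null(gene_map)) {
      f <- config$epe_fold
      epe_ids <- gene_map[epe_profile_genes()]
      # six promoters gain coverage, CACNB2/NRF1 lose it
      planted_epe <- stats::setNames(c(rep(f, 6), rep(1 / f, 2)), epe_ids)
    }
    if (is.null(planted_lpe) && !is.null(gene_map)) {
      f <- config$lpe_fold
      planted_lpe <- stats::setNames(c(f, 1 / f),
                                     gene_map[lpe_profile_genes()])
    }
    planted_epe <- planted_epe %||% stats::setNames(numeric(0), character(0))
    planted_lpe <- planted_lpe %||% stats::setNames(numeric(0), character(0))
    if (any(c(planted_epe, planted_lpe) <= 0)) {
      stop("planted fold-changes must be > 0")
    }
    bad <- setdiff(c(names(planted_epe), names(planted_lpe)), prom_ids)
    if (length(bad)) {
      stop("planted promoter ids not in annotation: ",
           paste(bad, collapse = ", "))
    }

    samples <- do.call(rbind, lapply(names(config$dataset_sizes), function(ds) {
      sz <- config$dataset_sizes[[ds]]
      lab <- rep(c("control", "EPE", "LPE"), times = sz)
      data.frame(dataset = ds, label = lab, stringsAsFactors = FALSE)
    }))
    samples$sample_id <- sprintf("S%05d", seq_len(nrow(samples)))
    samples <- samples[, c("sample_id", "dataset", "label")]

    structure(list(samples = samples, rates = rates,
                   planted_epe = planted_epe, planted_lpe = planted_lpe,
                   gene_map = gene_map,
                   promoters = ann$promoters, seqlengths = ann$seqlengths,
                   config = config),
              class = "truth_ledger")
  })
}

#' Truth-ledger promoter directions
#'
#' @param truth A `truth_ledger`.
#' @param class `"EPE"` or `"LPE"`.
#' @return data.frame: promoter_id, fold, direction ("+" iff fold > 1,
#'   "-" iff fold < 1).
#' @export
truth_directions <- function(truth, class = c("EPE", "LPE")) {
  class <- match.arg(class)
  fold <- if (class == "EPE") truth$planted_epe else truth$planted_lpe
  fold <- fold[fold != 1]
  data.frame(promoter_id = names(fold), fold = unname(fold),
             direction = ifelse(fold > 1, "+", "-"),
             stringsAsFactors = FALSE)
}

# expected in-window count matrix (samples x promoters), before noise
expected_counts <- function(truth) {
  config <- truth$config
  samples <- truth$samples
  n_s <- nrow(samples)
  n_p <- length(truth$rates)
  mu <- matrix(rep(truth$rates, each = n_s), nrow = n_s,
               dimnames = list(samples$sample_id, names(truth$rates)))
  depth <- config$mean_reads_per_sample *
    unname(config$batch_scale[samples$dataset])
  mu <- mu * depth
  for (cls in c("EPE", "LPE")) {
    fold <- if (cls == "EPE") truth$planted_epe else truth$planted_lpe
    rows <- samples$label == cls
    if (any(rows) && length(fold)) {
      cols <- match(names(fold), colnames(mu))
      mu[rows, cols] <- sweep(mu[rows, cols, drop = FALSE], 2, fold, `*`)
    }
  }
  mu
}

draw_noise <- function(mu, noise_model, dispersion) {
  n <- length(mu)
  if (noise_model == "poisson") {
    matrix(stats::rpois(n, as.vector(mu)), nrow = nrow(mu),
           dimnames = dimnames(mu))
  } else {
    if (dispersion <= 0) stop("negative-binomial dispersion must be > 0")
    matrix(stats::rnbinom(n, mu = as.vector(mu), size = 1 / dispersion),
           nrow = nrow(mu), dimnames = dimnames(mu))
  }
}

#' Simulate promoter count matrices directly
#'
#' Draws the per-sample in-window promoter counts and total mapped reads
#' from the same noise model as the read-level generator
#' ([generate_reads()]), without materializing individual reads. Total
#' mapped reads = in-window counts + a Poisson background draw with mean
#' `(1 - window_weight) x depth`, matching read-level generation where
#' background reads land between windows.
#'
#' @param truth A `truth_ledger` from [simulate_truth()].
#' @return A `coverage_matrix` (see [rpkm_normalize()]) holding raw counts,
#'   total mapped reads, and RPKM values.
#' @export
simulate_counts <- function(truth) {
  config <- truth$config
  with_seed(config$seed + 1L, {
    mu <- expected_counts(truth)
    counts <- draw_noise(mu, config$noise_model, config$dispersion)
    depth <- config$mean_reads_per_sample *
      unname(config$batch_scale[truth$samples$dataset])
    bg_mu <- (1 - config$window_weight) * depth
    bg <- stats::rpois(nrow(counts), bg_mu)
    total <- rowSums(counts) + bg
    names(total) <- rownames(counts)
    rpkm_normalize(counts, total)
  })
}

#' Simulate a clinical covariate table
#'
#' One row per sample; BMI is weight / height^2 by construction. The four
#' past-medical-history indicators are emitted both as separate flags and
#' are summable to the 0-4 PMH score downstream; conception is
#' `"IVF"` or `"natural"`.
#'
#' @param truth A `truth_ledger`.
#' @return data.frame with sample_id, dataset, label, age (years), height
#'   (m), weight (kg), bmi (kg/m^2), ga_delivery (weeks), gravidity, parity,
#'   pmh_htn, pmh_pe, pmh_sle, pmh_aps, conception.
#' @export
simulate_clinical <- function(truth) {
  config <- truth$config
  with_seed(config$seed + 2L, {
    s <- truth$samples
    n <- nrow(s)
    out <- s
    pars <- config$clinical_params
    age <- height <- bmi <- ga <- numeric(n)
    parity <- grav <- integer(n)
    pmh <- matrix(0L, n, 4)
    ivf <- integer(n)
    for (cls in unique(s$label)) {
      p <- pars[[cls]]
      if (is.null(p)) stop("clinical_params missing class: ", cls)
      i <- which(s$label == cls)
      m <- length(i)
      age[i] <- stats::rlnorm(m, log(p$age_median), p$age_sdlog)
      height[i] <- stats::rnorm(m, p$height_mean, p$height_sd) / 100
      bmi[i] <- stats::rlnorm(m, log(p$bmi_median), p$bmi_sdlog)
      ga[i] <- pmax(24, stats::rnorm(m, p$ga_mean, p$ga_sd))
      parity[i] <- stats::rbinom(m, 1L, p$p_parous)
      for (k in 1:4) pmh[i, k] <- stats::rbinom(m, 1L, p$p_pmh[k])
      ivf[i] <- stats::rbinom(m, 1L, p$p_ivf)
      grav[i] <- parity[i] + 1L + stats::rpois(m, 0.4)
    }
    out$age <- round(age, 1)
    out$height <- round(height, 2)
    out$bmi <- round(bmi, 1)
    out$weight <- round(out$bmi * out$height^2, 1)
    # re-derive BMI from the rounded pair so the table is self-consistent
    out$bmi <- out$weight / out$height^2
    out$ga_delivery <- round(ga, 1)
    out$gravidity <- grav
    out$parity <- parity
    out$pmh_htn <- pmh[, 1]
    out$pmh_pe <- pmh[, 2]
    out$pmh_sle <- pmh[, 3]
    out$pmh_aps <- pmh[, 4]
    out$conception <- ifelse(ivf == 1L, "IVF", "natural")
    out
  })
}

#' Simulate read-level alignments for a set of samples
#'
#' Materializes the count model as single-end, mapped, non-duplicate
#' 35 bp alignments: in-window reads start uniformly within their
#' promoter window, background reads start uniformly in inter-window
#' gaps. Each sample is written as SAM text and as an equivalent
#' fragment BED; SAM can additionally be converted to BAM.
#'
#' @param truth A `truth_ledger`.
#' @param dir Output directory (created if needed).
#' @param sample_ids Samples to emit (default: all; keep this small —
#'   read-level output is meant for format-level tests and exemplars).
#' @param as_bam Convert each SAM to a coordinate-sorted BAM via
#'   [Rsamtools::asBam()].
#' @return data.frame: sample_id, sam, bed, bam (paths; bam NA unless
#'   requested).
#' @export
generate_reads <- function(truth, dir, sample_ids = NULL, as_bam = FALSE) {
  config <- truth$config
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  samples <- truth$samples
  if (!is.null(sample_ids)) {
    samples <- samples[samples$sample_id %in% sample_ids, , drop = FALSE]
  }
  prom <- truth$promoters
  seqlen <- truth$seqlengths
  rl <- config$read_length
  # background gaps: complement of windows, shrunk so a read start stays
  # outside every window and on the contig
  win_start0 <- GenomicRanges::start(prom) - 1L
  win_end0 <- GenomicRanges::end(prom)
  gaps <- lapply(names(seqlen), function(ch) {
    on_ch <- as.character(GenomicRanges::seqnames(prom)) == ch
    s <- sort(win_start0[on_ch]); e <- sort(win_end0[on_ch])
    bounds <- cbind(c(0L, e), c(s, seqlen[[ch]] - rl))
    bounds[bounds[, 2] > bounds[, 1], , drop = FALSE]
  })
  names(gaps) <- names(seqlen)

  with_seed(config$seed + 3L, {
    mu_all <- expected_counts(truth)
    out <- lapply(seq_len(nrow(samples)), function(i) {
      sid <- samples$sample_id[i]
      mu <- mu_all[sid, ]
      counts <- as.vector(draw_noise(matrix(mu, nrow = 1),
                                     config$noise_model, config$dispersion))
      depth <- config$mean_reads_per_sample *
        unname(config$batch_scale[samples$dataset[i]])
      n_bg <- stats::rpois(1, (1 - config$window_weight) * depth)

      # in-window reads: start uniform in [win_start, win_end - 1] (0-based)
      w_idx <- rep(seq_along(counts), counts)
      pos0 <- win_start0[w_idx] +
        floor(stats::runif(length(w_idx)) * 2000)
      chrom <- as.character(GenomicRanges::seqnames(prom))[w_idx]
      # background reads: uniform over gap intervals, per chromosome
      gap_len <- vapply(gaps, function(g) sum(g[, 2] - g[, 1]), numeric(1))
      if (sum(gap_len) > 0 && n_bg > 0) {
        ch_bg <- sample(names(gaps), n_bg, replace = TRUE,
                        prob = gap_len / sum(gap_len))
        bg_pos <- vapply(ch_bg, function(ch) {
          g <- gaps[[ch]]
          len <- g[, 2] - g[, 1]
          k <- sample.int(nrow(g), 1, prob = len)
          g[k, 1] + floor(stats::runif(1) * len[k])
        }, numeric(1))
        chrom <- c(chrom, ch_bg)
        pos0 <- c(pos0, bg_pos)
      }
      n_reads <- length(pos0)
      flag <- ifelse(stats::runif(n_reads) < 0.5, 0L, 16L)
      ord <- order(match(chrom, names(seqlen)), pos0)
      sam_path <- file.path(dir, paste0(sid, ".sam"))
      bed_path <- file.path(dir, paste0(sid, ".bed"))
      write_sam(sam_path, chrom[ord], pos0[ord], flag[ord], seqlen, rl,
                qname_prefix = sid)
      bed <- data.frame(chrom = chrom[ord], start = pos0[ord],
                        end = pos0[ord] + rl,
                        name = sprintf("%s_r%06d", sid, seq_len(n_reads)))
      utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
      bam_path <- NA_character_
      if (as_bam) {
        bam_path <- Rsamtools::asBam(sam_path, file.path(dir, sid),
                                     overwrite = TRUE,
                                     indexDestination = FALSE)
      }
      data.frame(sample_id = sid, sam = sam_path, bed = bed_path,
                 bam = bam_path, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}

# minimal single-end SAM writer (mapped, primary, non-duplicate records)
write_sam <- function(path, chrom, pos0, flag, seqlengths, read_length,
                      qname_prefix = "r") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:coordinate", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(seqlengths),
                     as.integer(seqlengths)), con)
  if (length(pos0)) {
    writeLines(sprintf("%s_r%06d\t%d\t%s\t%d\t60\t%dM\t*\t0\t0\t*\t*",
                       qname_prefix, seq_along(pos0), flag, chrom,
                       as.integer(pos0) + 1L, read_length), con)
  }
  invisible(path)
}

#' Simulate a full cohort
#'
#' Convenience wrapper: truth ledger, count matrix, clinical table.
#'
#' @param config A [sim_config()].
#' @return list(truth, coverage, clinical).
#' @export
simulate_cohort <- function(config) {
  truth <- simulate_truth(config)
  list(truth = truth,
       coverage = simulate_counts(truth),
       clinical = simulate_clinical(truth))
}

#' Write a truth ledger as JSON
#'
#' @param truth A `truth_ledger`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(truth, path) {
  obj <- list(
    samples = truth$samples,
    planted_epe = as.list(truth$planted_epe),
    planted_lpe = as.list(truth$planted_lpe),
    directions = list(EPE = truth_directions(truth, "EPE"),
                      LPE = truth_directions(truth, "LPE")),
    gene_map = as.list(truth$gene_map %||% character(0)),
    seed = truth$config$seed
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
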