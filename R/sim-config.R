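#' Default class-conditional clinical distributions
#'
#' Parameters of the clinical covariate generator, one set per class
#' (`control`, `EPE`, `LPE`). Maternal age and BMI are log-normal
#' (parameterized by the median in natural units and the log-scale sd),
#' height is normal (cm), weight is derived as BMI x height^2 so the three
#' are always mutually consistent. Parity, the four past-medical-history
#' flags (chronic hypertension, prior preeclampsia, SLE, antiphospholipid
#' syndrome) and IVF conception are Bernoulli. Gestational age at delivery
#' (weeks) is normal, truncated at 24 weeks. Defaults reflect a Chinese
#' NIPT screening population: controls deliver at term (~39.3 wk) with
#' median age 28 y and BMI 20.5; early-onset PE cases are older (33 y),
#' heavier (BMI 22.2), deliver preterm (~33 wk), and are far more often
#' IVF conceptions; late-onset shifts are milder.
#'
#' @return Named list of per-class parameter lists.
#' @export
default_clinical_params <- function() {
  list(
    control = list(age_median = 28, age_sdlog = 0.130,
                   height_mean = 160, height_sd = 5.2,
                   bmi_median = 20.5, bmi_sdlog = 0.133,
                   p_parous = 0.55, p_pmh = rep(0.003, 4), p_ivf = 0.018,
                   ga_mean = 39.3, ga_sd = 1.1),
    EPE     = list(age_median = 33, age_sdlog = 0.135,
                   height_mean = 160, height_sd = 5.2,
                   bmi_median = 22.2, bmi_sdlog = 0.121,
                   p_parous = 0.45, p_pmh = rep(0.015, 4), p_ivf = 0.26,
                   ga_mean = 33.0, ga_sd = 1.8),
    LPE     = list(age_median = 31, age_sdlog = 0.132,
                   height_mean = 160, height_sd = 5.2,
                   bmi_median = 22.8, bmi_sdlog = 0.128,
                   p_parous = 0.40, p_pmh = rep(0.006, 4), p_ivf = 0.05,
                   ga_mean = 37.3, ga_sd = 1.4)
  )
}

#' Default per-dataset sample sizes
#'
#' Four hospitals: one training set, two internal validation sets, one
#' external validation set, at the post-QC sizes of the study design this
#' generator emulates.
#'
#' @return Named list of `c(n_control, n_epe, n_lpe)` triples with a
#'   `role` attribute per dataset.
#' @export
default_dataset_sizes <- function() {
  list(
    training  = c(n_control = 276, n_epe = 54, n_lpe = 145),
    internal1 = c(n_control = 528, n_epe = 30, n_lpe = 160),
    internal2 = c(n_control = 406, n_epe = 16, n_lpe = 115),
    external  = c(n_control = 779, n_epe = 40, n_lpe = 160)
  )
}

#' Build a synthetic-cohort configuration
#'
#' Collects every knob of the synthetic cohort generator into a validated
#' config object. The defaults are the generator's reference conditions:
#' a 500-promoter synthetic genome, ~1e4 mapped reads per sample of which
#' 30% fall in promoter windows (about 6 expected reads per 2 kb window,
#' the in-window depth of ~0.1X sequencing with 35 bp reads), four
#' hospital datasets at the study-scale sizes of
#' [default_dataset_sizes()], and planted promoter effects bound to the
#' early-onset 8-gene profile and the late-onset FLT3LG/EGF ratio.
#'
#' @param n_promoters Number of synthetic promoters (one transcript per gene).
#' @param dataset_sizes Named list of `c(n_control, n_epe, n_lpe)` per dataset;
#'   the first dataset is the training set, the last the external set.
#' @param mean_reads_per_sample Expected total mapped reads per sample.
#' @param window_weight Fraction of reads expected inside promoter windows
#'   (the rest land in background regions between windows).
#' @param rate_shape Gamma shape for per-promoter relative read-attraction
#'   weights; larger is more homogeneous.
#' @param planted_epe Named numeric vector `promoter_id -> fold change` applied
#'   to EPE samples (fold 1 = null). `NULL` plants the default 8-promoter
#'   profile at fold `epe_fold`.
#' @param planted_lpe Same for LPE samples; `NULL` plants FLT3LG up / EGF down.
#' @param epe_fold,lpe_fold Default fold changes used when planting profiles.
#' @param batch_scale Named per-dataset depth multipliers (default all 1).
#' @param noise_model `"poisson"` or `"negative_binomial"`.
#' @param dispersion NB dispersion (variance = mu + dispersion * mu^2); must be
#'   > 0 when `noise_model = "negative_binomial"`.
#' @param read_length Single-end read length in bp.
#' @param spacing Distance between consecutive TSSs on a chromosome (bp);
#'   must be >= 2000 for disjoint windows.
#' @param n_chrom Number of synthetic chromosomes.
#' @param clinical_params Per-class clinical distributions, see
#'   [default_clinical_params()].
#' @param seed Integer seed; fully determines all generator output.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_promoters = 500,
                       dataset_sizes = default_dataset_sizes(),
                       mean_reads_per_sample = 1e4,
                       window_weight = 0.3,
                       rate_shape = 5,
                       planted_epe = NULL,
                       planted_lpe = NULL,
                       epe_fold = 1.5,
                       lpe_fold = 1.5,
                       batch_scale = NULL,
                       noise_model = c("poisson", "negative_binomial"),
                       dispersion = 0.05,
                       read_length = 35,
                       spacing = 10000,
                       n_chrom = 2,
                       clinical_params = default_clinical_params(),
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  if (n_promoters < 0) stop("n_promoters must be >= 0")
  if (noise_model == "negative_binomial" && dispersion <= 0) {
    stop("negative-binomial dispersion must be > 0")
  }
  if (window_weight <= 0 || window_weight > 1) {
    stop("window_weight must be in (0, 1]")
  }
  if (spacing < 2000) stop("spacing < 2000 would overlap promoter windows")
  if (is.null(names(dataset_sizes)) || any(names(dataset_sizes) == "")) {
    stop("dataset_sizes must be a named list")
  }
  for (cls in c("control", "EPE", "LPE")) {
    if (is.null(clinical_params[[cls]])) {
      stop("clinical_params missing class: ", cls)
    }
  }
  if (is.null(batch_scale)) {
    batch_scale <- stats::setNames(rep(1, length(dataset_sizes)),
                                   names(dataset_sizes))
  }
  structure(list(
    n_promoters = as.integer(n_promoters),
    dataset_sizes = dataset_sizes,
    mean_reads_per_sample = mean_reads_per_sample,
    window_weight = window_weight,
    rate_shape = rate_shape,
    planted_epe = planted_epe,
    planted_lpe = planted_lpe,
    epe_fold = epe_fold,
    lpe_fold = lpe_fold,
    batch_scale = batch_scale,
    noise_model = noise_model,
    dispersion = dispersion,
    read_length = as.integer(read_length),
    spacing = as.integer(spacing),
    n_chrom = as.integer(n_chrom),
    clinical_params = clinical_params,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  n_samp <- sum(vapply(x$dataset_sizes, sum, numeric(1)))
  cat("<sim_config>", x$n_promoters, "promoters,",
      length(x$dataset_sizes), "datasets,", n_samp, "samples,",
      x$noise_model, "noise, seed", x$seed, "\n")
  invisible(x)
}
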