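# End-to-end pipeline: simulate -> coverage -> QC -> discovery ->
# features -> train -> evaluate, with artifacts written to a run
# directory. Stage boundaries are label-disciplined: coverage and QC
# never see case/control status (except MoM's control flag), and
# discovery/training never see validation or external datasets.

#' Build a pipeline configuration
#'
#' @param sim A [sim_config()] describing the cohort (the first dataset
#'   is the training set, the last is the external validation set; the
#'   datasets in between are internal validation sets).
#' @param iters,frac Stability-selection iterations and subsample fraction.
#' @param sd_cut PCA QC threshold in standard deviations.
#' @param spec_target Operating-point specificity target.
#' @param n_boot Bootstrap resamples for AUC CIs.
#' @param alpha Stability-selection significance cutoff.
#' @param protocol Threshold policy for evaluation ("per-dataset"/"fixed").
#' @param run_evaluation Toggle the evaluation stage.
#' @param epe_model,lpe_model Model kinds for the two contexts (defaults:
#'   LR for early-onset, RF for late-onset).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(sim = sim_config(),
                            iters = 1000, frac = 0.7, sd_cut = 3,
                            spec_target = 0.90, n_boot = 1000,
                            alpha = 0.05,
                            protocol = c("per-dataset", "fixed"),
                            run_evaluation = TRUE,
                            epe_model = "lr", lpe_model = "rf") {
  protocol <- match.arg(protocol)
  if (length(sim$dataset_sizes) < 2) {
    stop("config error: need at least a training and one validation dataset")
  }
  structure(list(sim = sim, iters = iters, frac = frac, sd_cut = sd_cut,
                 spec_target = spec_target, n_boot = n_boot, alpha = alpha,
                 protocol = protocol, run_evaluation = run_evaluation,
                 epe_model = epe_model, lpe_model = lpe_model),
            class = "pipeline_config")
}

dataset_roles <- function(config) {
  ds <- names(config$sim$dataset_sizes)
  roles <- c("training", rep("internal", max(0, length(ds) - 2)), "external")
  stats::setNames(roles, ds)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on a synthetic cohort and (optionally) writes all
#' artifacts under `out_dir`: the config echo (YAML), truth ledger
#' (JSON), clinical table, RPKM/MoM matrices, QC report, biomarker calls
#' for both class contexts, clinical screens, trained models and
#' per-dataset evaluation reports for the clinical-only, cfDNA-only and
#' combined feature sets. Reruns with an identical config reproduce all
#' numeric outputs byte for byte.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @return Invisibly, a list with every stage product (truth, coverage,
#'   mom, qc, calls, screens, features, models, evaluations).
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config")) stop("config error: not a pipeline_config")
  write_out <- !is.null(out_dir)
  if (write_out && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  roles <- dataset_roles(config)
  seed0 <- config$sim$seed

  message("stage: simulate")
  cohort <- simulate_cohort(config$sim)
  truth <- cohort$truth
  cov <- cohort$coverage
  clinical <- cohort$clinical

  message("stage: qc")
  qc <- pca_filter(cov, n_components = 2, sd_cut = config$sd_cut)
  keep <- qc$retained_ids
  samples <- truth$samples[truth$samples$sample_id %in% keep, ]
  cov_q <- rpkm_normalize(cov$counts[keep, , drop = FALSE],
                          cov$total_mapped[keep])
  clinical <- clinical[clinical$sample_id %in% keep, ]

  message("stage: mom")
  labels <- stats::setNames(samples$label, samples$sample_id)
  dsets <- stats::setNames(samples$dataset, samples$sample_id)
  mom <- mom_normalize(cov_q, labels, dsets)

  message("stage: discovery")
  discovery_ids <- samples$sample_id[roles[samples$dataset] != "external"]
  class_contexts <- intersect(c("EPE", "LPE"), unique(samples$label))
  calls <- list(); screens <- list()
  for (cls in class_contexts) {
    sub <- subsample_wilcoxon(mom, class = cls, n_iter = config$iters,
                              frac = config$frac,
                              seed = seed0 + ifelse(cls == "EPE", 11L, 12L),
                              sample_ids = discovery_ids)
    calls[[cls]] <- select_biomarkers(sub, alpha = config$alpha)
    screens[[cls]] <- screen_clinical(
      clinical[clinical$sample_id %in% discovery_ids, ], class = cls)
  }

  message("stage: features/train")
  train_ds <- names(roles)[roles == "training"]
  feature_sets <- c("clinical", "cfdna", "combined")
  features <- list(); models <- list()
  for (cls in class_contexts) {
    kind <- if (cls == "EPE") config$epe_model else config$lpe_model
    features[[cls]] <- lapply(stats::setNames(feature_sets, feature_sets),
                              function(fs) {
      suppressMessages(build_features(mom, clinical, truth$gene_map,
                                      class = cls, feature_set = fs))
    })
    models[[cls]] <- lapply(features[[cls]], function(ft) {
      tr <- subset_features(ft, ft$dataset == train_ds)
      pe_train(tr, model_kind = kind, seed = seed0 + 21L,
               spec_target = config$spec_target)
    })
  }

  evaluations <- NULL
  if (config$run_evaluation) {
    message("stage: evaluate")
    evaluations <- list()
    for (cls in class_contexts) {
      evaluations[[cls]] <- list()
      for (fs in feature_sets) {
        ft <- features[[cls]][[fs]]
        reps <- lapply(names(roles), function(ds) {
          sub <- subset_features(ft, ft$dataset == ds)
          evaluate_dataset(models[[cls]][[fs]], sub,
                           dataset_id = ds, protocol = config$protocol,
                           spec_target = config$spec_target,
                           n_boot = config$n_boot, seed = seed0 + 31L)
        })
        names(reps) <- names(roles)
        evaluations[[cls]][[fs]] <- reps
      }
    }
  }

  result <- list(config = config, truth = truth, coverage = cov_q, qc = qc,
                 mom = mom, clinical = clinical, calls = calls,
                 screens = screens, features = features, models = models,
                 evaluations = evaluations, roles = roles)

  if (write_out) write_pipeline_artifacts(result, out_dir)
  invisible(result)
}

write_pipeline_artifacts <- function(result, out_dir) {
  config <- result$config
  yaml::write_yaml(list(
    seed = config$sim$seed,
    n_promoters = config$sim$n_promoters,
    datasets = lapply(config$sim$dataset_sizes, as.list),
    mean_reads_per_sample = config$sim$mean_reads_per_sample,
    noise_model = config$sim$noise_model,
    iters = config$iters, frac = config$frac, sd_cut = config$sd_cut,
    spec_target = config$spec_target, n_boot = config$n_boot,
    alpha = config$alpha, protocol = config$protocol
  ), file.path(out_dir, "config_echo.yaml"))
  write_truth_json(result$truth, file.path(out_dir, "truth.json"))
  write_tsv(result$clinical, file.path(out_dir, "clinical.tsv"))
  write_matrix_tsv(result$coverage$rpkm, file.path(out_dir, "rpkm.tsv"))
  write_matrix_tsv(result$mom$mom, file.path(out_dir, "mom.tsv"))
  write_qc_json(result$qc, file.path(out_dir, "qc_report.json"))
  for (cls in names(result$calls)) {
    write_tsv(result$calls[[cls]],
              file.path(out_dir, sprintf("calls_%s.tsv", tolower(cls))))
    write_tsv(result$screens[[cls]],
              file.path(out_dir, sprintf("clinical_screen_%s.tsv",
                                         tolower(cls))))
    write_classifier_json(
      result$models[[cls]][["combined"]],
      file.path(out_dir, sprintf("model_%s.json", tolower(cls))))
  }
  if (!is.null(result$evaluations)) {
    for (cls in names(result$evaluations)) {
      for (fs in names(result$evaluations[[cls]])) {
        tab <- eval_table(result$evaluations[[cls]][[fs]])
        write_tsv(tab, file.path(out_dir,
                                 sprintf("eval_%s_%s.tsv", tolower(cls), fs)))
      }
    }
  }
  invisible(out_dir)
}

#' Plot ROC curves for a set of evaluation reports
#'
#' @param reports Named list of `eval_report`s (one curve each).
#' @param path Optional PNG output path; plots to the active device when
#'   NULL.
#' @param main Plot title.
#' @return `path`, invisibly.
#' @export
plot_roc <- function(reports, path = NULL, main = "ROC") {
  if (!is.null(path)) {
    grDevices::png(path, width = 640, height = 640)
    on.exit(grDevices::dev.off())
  }
  graphics::plot(c(0, 1), c(0, 1), type = "l", lty = 3, col = "grey",
                 xlab = "False positive rate", ylab = "True positive rate",
                 main = main)
  cols <- grDevices::hcl.colors(max(3, length(reports)), "Dark 2")
  for (i in seq_along(reports)) {
    r <- reports[[i]]
    graphics::lines(r$roc$fpr, r$roc$tpr, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", bty = "n", lwd = 2,
                   col = cols[seq_along(reports)],
                   legend = sprintf("%s (AUC %.2f)",
                                    names(reports) %||%
                                      vapply(reports, `[[`, "", "dataset_id"),
                                    vapply(reports, `[[`, numeric(1), "auc")))
  invisible(path)
}
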