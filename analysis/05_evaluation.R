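#!/usr/bin/env Rscript
# Stage 5 — ROC evaluation of the classifiers in all four datasets.
#
# For each class context and feature set: AUC with a 1,000-resample
# percentile-bootstrap 95% CI, and the operating point at 10% false
# positive rate (accuracy, sensitivity, specificity, PPV, NPV), with the
# threshold re-anchored per dataset. DeLong's test compares the combined
# classifier against each single-source variant on every dataset, and
# ROC curves are drawn per context.
#
# Random forests do not round-trip through JSON, so this stage retrains
# each model from the stage-4 feature tables (deterministic given the
# seed) rather than deserializing it.

suppressMessages(library(cfpe))
out <- "results"
seed <- 20240417
n_boot <- 1000

samples <- read_tsv(file.path(out, "samples_retained.tsv"))
datasets <- unique(samples$dataset)
train_ds <- datasets[1]

for (cls in c("EPE", "LPE")) {
  kind <- if (cls == "EPE") "lr" else "rf"
  reports <- list(); scores <- list()
  for (fs in c("clinical", "cfdna", "combined")) {
    ft <- read_tsv(file.path(out, sprintf("features_%s_%s.tsv",
                                          tolower(cls), fs)))
    feats <- setdiff(names(ft), c("sample_id", "dataset", "label", "y"))
    attr(ft, "schema") <- feats
    attr(ft, "schema_hash") <- cfpe:::schema_hash(feats)
    attr(ft, "class_context") <- cls
    model <- pe_train(subset_features(ft, ft$dataset == train_ds),
                      model_kind = kind, seed = seed + 21L)
    reports[[fs]] <- lapply(stats::setNames(datasets, datasets), function(ds) {
      evaluate_dataset(model, subset_features(ft, ft$dataset == ds),
                       dataset_id = ds, protocol = "per-dataset",
                       spec_target = 0.90, n_boot = n_boot,
                       seed = seed + 31L)
    })
    tab <- eval_table(reports[[fs]])
    write_tsv(tab, file.path(out, sprintf("eval_%s_%s.tsv",
                                          tolower(cls), fs)))
    cat(sprintf("%s [%s]: AUC %s\n", cls, fs,
                paste(sprintf("%s %.2f", tab$dataset, tab$auc),
                      collapse = ", ")))
  }
  # DeLong: combined vs each single source, per dataset
  labs <- read_tsv(file.path(out, sprintf("features_%s_combined.tsv",
                                          tolower(cls))))
  y_of <- stats::setNames(labs$y, labs$sample_id)
  cmp <- do.call(rbind, lapply(datasets, function(ds) {
    do.call(rbind, lapply(c("clinical", "cfdna"), function(fs) {
      ra <- reports$combined[[ds]]; rb <- reports[[fs]][[ds]]
      common <- intersect(names(ra$scores), names(rb$scores))
      yv <- y_of[common]
      dl <- delong_test(ra$scores[common], rb$scores[common], yv)
      data.frame(dataset = ds, comparison = paste0("combined_vs_", fs),
                 auc_combined = dl$auc_a, auc_other = dl$auc_b,
                 p_value = dl$p_value,
                 stars = significance_stars(dl$p_value),
                 stringsAsFactors = FALSE)
    }))
  }))
  write_tsv(cmp, file.path(out, sprintf("delong_%s.tsv", tolower(cls))))
  plot_roc(reports$combined,
           path = file.path(out, sprintf("roc_%s.png", tolower(cls))),
           main = sprintf("%s combined classifier", cls))
  cat(sprintf("%s DeLong combined-vs-single: %s\n", cls,
              paste(sprintf("%s %s %s", cmp$dataset, cmp$comparison,
                            cmp$stars), collapse = "; ")))
}
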