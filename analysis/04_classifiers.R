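#!/usr/bin/env Rscript
# Stage 4 — assemble feature vectors and train the two classifiers.
#
# Early-onset (C_EPE): logistic regression on 5 clinical encodings
# (age MoM, BMI MoM, parity, 0-4 past-medical-history score, IVF) plus
# the 8-gene promoter-coverage profile. Late-onset (C_LPE): random
# forest on the same clinical encodings plus the FLT3LG/EGF coverage
# ratio. Clinical-only and cfDNA-only variants are trained alongside for
# the ablation comparison. Training uses the training hospital only.

suppressMessages(library(cfpe))
out <- "results"
seed <- 20240417

mom_mat <- read_matrix_tsv(file.path(out, "mom.tsv"))
samples <- read_tsv(file.path(out, "samples_retained.tsv"))
clinical <- read_tsv(file.path(out, "clinical.tsv"))
clinical <- clinical[clinical$sample_id %in% samples$sample_id, ]
truth <- jsonlite::read_json(file.path(out, "truth.json"),
                             simplifyVector = TRUE)
gene_map <- unlist(truth$gene_map)
train_ds <- unique(samples$dataset)[1]

mom <- structure(list(mom = mom_mat,
                      labels = stats::setNames(samples$label,
                                               samples$sample_id)[rownames(mom_mat)],
                      dataset_ids = stats::setNames(samples$dataset,
                                                    samples$sample_id)[rownames(mom_mat)]),
                 class = "mom_matrix")

for (cls in c("EPE", "LPE")) {
  kind <- if (cls == "EPE") "lr" else "rf"
  for (fs in c("clinical", "cfdna", "combined")) {
    ft <- build_features(mom, clinical, gene_map, class = cls,
                         feature_set = fs)
    write_tsv(ft, file.path(out, sprintf("features_%s_%s.tsv",
                                         tolower(cls), fs)))
    model <- pe_train(subset_features(ft, ft$dataset == train_ds),
                      model_kind = kind, seed = seed + 21L,
                      spec_target = 0.90)
    if (kind == "lr" || fs == "combined") {
      write_classifier_json(model, file.path(out, sprintf(
        "model_%s_%s.json", tolower(cls), fs)))
    }
    cat(sprintf("%s %s [%s]: %d features, training threshold %.3f\n",
                cls, toupper(kind), fs, length(model$schema),
                model$threshold))
  }
}
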