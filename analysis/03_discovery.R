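#!/usr/bin/env Rscript
# Stage 3 — biomarker discovery and clinical risk-factor screening.
#
# On the discovery samples (training + internal validation hospitals,
# never the external one), repeats a case-vs-control Wilcoxon rank-sum
# test of every promoter's MoM coverage on random stratified 70%
# subsamples; a promoter is a candidate biomarker when the upper limit of
# the 95% CI of its p-values stays below 0.05 with a consistent direction
# of change. Clinical covariates are screened with Mann-Whitney (continuous)
# and Fisher's exact (categorical) tests.

suppressMessages(library(cfpe))
out <- "results"
iters <- 1000
seed <- 20240417

mom_mat <- read_matrix_tsv(file.path(out, "mom.tsv"))
samples <- read_tsv(file.path(out, "samples_retained.tsv"))
clinical <- read_tsv(file.path(out, "clinical.tsv"))
clinical <- clinical[clinical$sample_id %in% samples$sample_id, ]
roles <- stats::setNames(
  c("training", rep("internal", length(unique(samples$dataset)) - 2),
    "external"), unique(samples$dataset))
discovery_ids <- samples$sample_id[roles[samples$dataset] != "external"]
labels <- stats::setNames(samples$label, samples$sample_id)

for (cls in c("EPE", "LPE")) {
  sub <- subsample_wilcoxon(mom_mat, labels = labels, class = cls,
                            n_iter = iters, frac = 0.7,
                            seed = seed + ifelse(cls == "EPE", 11L, 12L),
                            sample_ids = discovery_ids)
  sel <- select_biomarkers(sub, alpha = 0.05)
  write_tsv(sel, file.path(out, sprintf("calls_%s.tsv", tolower(cls))))
  cat(sprintf("%s: %d/%d promoters stably differential (%d up, %d down)\n",
              cls, sum(sel$selected), nrow(sel),
              sum(sel$selected & sel$direction == "+"),
              sum(sel$selected & sel$direction == "-")))
  scr <- screen_clinical(clinical[clinical$sample_id %in% discovery_ids, ],
                         class = cls)
  write_tsv(scr, file.path(out, sprintf("clinical_screen_%s.tsv",
                                        tolower(cls))))
  sig <- scr$factor[!is.na(scr$p_value) & scr$p_value < 0.05]
  cat(sprintf("%s clinical factors at p < 0.05: %s\n", cls,
              paste(sig, collapse = ", ")))
}
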