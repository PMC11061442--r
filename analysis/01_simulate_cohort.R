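#!/usr/bin/env Rscript
# Stage 1 — simulate the multi-hospital NIPT cohort.
#
# Generates the reference synthetic study: four hospital datasets (one
# training, two internal validation, one external validation) at
# study-scale sizes, a 500-promoter synthetic genome, promoter-level
# counts at ~0.1X-equivalent depth, Table-1-like clinical covariates, and
# a ground-truth ledger of the planted differential promoters. Also
# materializes two samples at read level (SAM/BED/BAM) to exercise the
# alignment-format path end to end.

suppressMessages(library(cfpe))

seed <- 20240417
out <- "results"
dir.create(file.path(out, "reads"), recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = seed)
print(cfg)

cohort <- simulate_cohort(cfg)
truth <- cohort$truth

write_truth_json(truth, file.path(out, "truth.json"))
write_tsv(cohort$clinical, file.path(out, "clinical.tsv"))
write_matrix_tsv(cohort$coverage$counts, file.path(out, "counts.tsv"))
write_tsv(data.frame(sample_id = names(cohort$coverage$total_mapped),
                     total_mapped = unname(cohort$coverage$total_mapped)),
          file.path(out, "total_mapped.tsv"))
write_promoter_bed(truth$promoters, file.path(out, "promoters.bed"))
write_promoter_gtf(truth$promoters, file.path(out, "promoters.gtf"))
yaml::write_yaml(list(seed = seed, n_promoters = cfg$n_promoters,
                      datasets = lapply(cfg$dataset_sizes, as.list),
                      mean_reads_per_sample = cfg$mean_reads_per_sample,
                      noise_model = cfg$noise_model),
                 file.path(out, "config_echo.yaml"))

# two read-level exemplars: the counting stage must reproduce the
# matrix-level counts' distribution from actual alignment records
exemplars <- truth$samples$sample_id[1:2]
files <- generate_reads(truth, file.path(out, "reads"),
                        sample_ids = exemplars, as_bam = TRUE)
idx <- build_window_index(truth$promoters)
for (i in seq_len(nrow(files))) {
  cnt <- count_reads(files$bam[i], idx)
  cat(sprintf("%s: %d reads, %d in windows (%.1f%%)\n",
              files$sample_id[i], cnt$total_mapped, sum(cnt$raw_counts),
              100 * sum(cnt$raw_counts) / cnt$total_mapped))
}

n <- table(truth$samples$label)
cat(sprintf("cohort: %d samples (%d controls, %d early-onset, %d late-onset) in %d datasets\n",
            nrow(truth$samples), n[["control"]], n[["EPE"]], n[["LPE"]],
            length(cfg$dataset_sizes)))
cat(sprintf("planted: %d early-onset and %d late-onset differential promoters\n",
            length(truth$planted_epe), length(truth$planted_lpe)))
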