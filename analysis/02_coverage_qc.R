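#!/usr/bin/env Rscript
# Stage 2 — pTSS coverage normalization and PCA sample QC.
#
# RPKM-normalizes the promoter counts, excludes samples beyond 3 sd on
# the first two principal components (single pass, pooled across
# hospitals), and computes the multiple-of-the-median (MoM) matrix
# against each dataset's retained control samples.

suppressMessages(library(cfpe))
out <- "results"

counts <- read_matrix_tsv(file.path(out, "counts.tsv"))
totals <- read_tsv(file.path(out, "total_mapped.tsv"))
total_mapped <- stats::setNames(totals$total_mapped, totals$sample_id)
truth <- jsonlite::read_json(file.path(out, "truth.json"),
                             simplifyVector = TRUE)
samples <- truth$samples

cov <- rpkm_normalize(counts, total_mapped[rownames(counts)])
qc <- pca_filter(cov, n_components = 2, sd_cut = 3)
print(qc)
labels_all <- stats::setNames(samples$label, samples$sample_id)
print(qc_tally(qc, labels_all))
write_qc_json(qc, file.path(out, "qc_report.json"))

keep <- qc$retained_ids
cov_q <- rpkm_normalize(counts[keep, , drop = FALSE], total_mapped[keep])
mom <- mom_normalize(cov_q, labels_all[keep],
                     stats::setNames(samples$dataset, samples$sample_id)[keep])
print(mom)
write_matrix_tsv(cov_q$rpkm, file.path(out, "rpkm.tsv"))
write_matrix_tsv(mom$mom, file.path(out, "mom.tsv"))
write_tsv(samples[samples$sample_id %in% keep, ],
          file.path(out, "samples_retained.tsv"))
cat(sprintf("retained %d/%d samples; %d (dataset, promoter) cells undefined\n",
            length(keep), nrow(samples), sum(mom$undefined)))
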