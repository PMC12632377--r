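#!/usr/bin/env Rscript
# Step 2 -- normalisation, QC and per-protein KO-vs-control contrasts.
#
# Median-centres each sample in log2 space, reports per-group protein counts
# and median RSD, then computes every KO-vs-control contrast within cell
# type (Student's t, BH correction) and the per-annotation significance
# counts at q <= 0.05.

suppressPackageStartupMessages(library(olscape))

data_dir <- "results/data"
out_dir <- "results/differential"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

design <- read_design(file.path(data_dir, "design.tsv"))
abund <- read_abundance(file.path(data_dir, "abundance.tsv"), scale = "log2")
catalog <- read_catalog(file.path(data_dir, "catalog.gmt"),
                        groups_path = file.path(data_dir, "groups.tsv"),
                        classes_path = file.path(data_dir, "classes.tsv"))

# RSD is defined on linear intensities; undo the log for QC only
qc <- qc_metrics(abundance_matrix(2^abund$values, "raw_intensity"), design)
write.table(qc$groups, file.path(out_dir, "qc_groups.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("QC: %d groups, median RSD %.1f%% (range %.1f-%.1f%%)\n",
            nrow(qc$groups), median(qc$groups$median_rsd),
            min(qc$groups$median_rsd), max(qc$groups$median_rsd)))

normed <- normalize_median(abund)
fc <- compute_all_contrasts(normed, design)
write.table(fc, file.path(out_dir, "fold_changes.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("contrasts: %d conditions x ~%d proteins, %d rows\n",
            nrow(fc_conditions(fc)), length(unique(fc$protein_id)), nrow(fc)))

counts <- do.call(rbind, lapply(seq_len(nrow(fc_conditions(fc))), function(i) {
  cond <- fc_conditions(fc)[i, ]
  sub <- fc[fc$genotype == cond$genotype & fc$cell_type == cond$cell_type, ]
  cbind(genotype = cond$genotype, cell_type = cond$cell_type,
        count_significant(sub, catalog, q_max = 0.05))
}))
write.table(counts, file.path(out_dir, "significant_counts.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
top <- counts[order(-(counts$up + counts$down)), ][1:5, ]
cat("largest per-annotation significance counts (q <= 0.05):\n")
print(top, row.names = FALSE)
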