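#!/usr/bin/env Rscript
# Step 3 -- the organelle correlation landscape.
#
# From the fold-change table: per-annotation condition-condition correlation
# matrices, the composite condition x annotation organelle correlation map,
# disease-class mean +/- SD summaries, circos-style links at the r < -0.2 /
# r > 0.7 thresholds, ranked impact scores for the vesicular and
# mitochondrial annotation groups, iN-vs-iDA per-genotype organelle
# correlations, Euler overlaps of mitochondrial proteins at log2FC > -0.75
# across sphingolipidosis mutants, and hierarchical clustering of the
# composite profiles.

suppressPackageStartupMessages(library(olscape))

data_dir <- "results/data"
out_dir <- "results/landscape"
dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

fc <- read.delim("results/differential/fold_changes.tsv",
                 stringsAsFactors = FALSE)
catalog <- read_catalog(file.path(data_dir, "catalog.gmt"),
                        groups_path = file.path(data_dir, "groups.tsv"),
                        classes_path = file.path(data_dir, "classes.tsv"))

cm <- composite_map(fc, catalog, min_proteins = 10)
write.table(data.frame(condition = rownames(cm$matrix), cm$matrix,
                       check.names = FALSE),
            file.path(out_dir, "composite_map.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
lo <- which(cm$matrix == min(cm$matrix, na.rm = TRUE), arr.ind = TRUE)[1, ]
cat(sprintf("composite map %d x %d; most negative organelle correlation: %s / %s (%.2f)\n",
            nrow(cm$matrix), ncol(cm$matrix), rownames(cm$matrix)[lo[1]],
            colnames(cm$matrix)[lo[2]], min(cm$matrix, na.rm = TRUE)))

cs <- class_variance(cm, catalog$disease_class)
write.table(cs, file.path(out_dir, "class_summary.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
var_by_class <- aggregate(sd ~ class + cell_type, cs, mean)
cat("mean within-class SD of organelle correlations:\n")
print(var_by_class[order(-var_by_class$sd), ][1:4, ], row.names = FALSE)

acms <- lapply(c("mitochondria", "OXPHOS", "SynapseSV"), function(ann) {
  annotation_correlation(fc, catalog, ann, min_proteins = 10)
})
links <- filter_links(acms, neg_max = -0.2, pos_min = 0.7)
write.table(links, file.path(out_dir, "links.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
focus <- filter_links(acms, neg_max = -0.2, pos_min = 0.7,
                      origin = c("GBA1_KO", "ASAH1_KO"))
write.table(focus, file.path(out_dir, "links_gba1_asah1.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("links (|r| beyond -0.2 / 0.7): %d total, %d touching GBA1/ASAH1 (%d negative)\n",
            nrow(links), nrow(focus), sum(focus$r < 0)))

for (grp in names(catalog$groups)) {
  for (ct in c("iN", "iDA")) {
    imp <- impact_score(fc, catalog, grp, ct)
    write.table(imp, file.path(out_dir, sprintf("impact_%s_%s.tsv", grp, ct)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    cat(sprintf("impact ranking (%s, %s): top 3 = %s\n", grp, ct,
                paste(imp$genotype[1:3], collapse = ", ")))
  }
}

genos <- setdiff(unique(fc$genotype), "Control")
cross <- do.call(rbind, lapply(c("mitochondria", "SynapseSV"), function(ann) {
  data.frame(annotation = ann, genotype = genos,
             r_iN_vs_iDA = vapply(genos, function(g) {
               cross_celltype_correlation(fc, catalog, ann, g)
             }, 0), row.names = NULL)
}))
write.table(cross, file.path(out_dir, "cross_celltype.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

sph <- c("GBA1_KO", "ASAH1_KO", "SMPD1_KO", "HEXA_KO")
mito_sets <- lapply(sph, function(g) {
  intersect(threshold_membership(fc, g, "iDA", "greater", -0.75),
            catalog$sets$mitochondria)
})
names(mito_sets) <- sph
ov <- overlap_counts(mito_sets)
write.table(ov, file.path(out_dir, "euler_mito_iDA.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
cat(sprintf("mitochondrial proteins at log2FC > -0.75 (iDA): full overlap region = %d\n",
            ov$count[ov$signature == paste(rep("1", length(sph)), collapse = "")]))

hc <- hcluster_correlations(cm$matrix, linkage = "average")
if (requireNamespace("ape", quietly = TRUE)) {
  ape::write.tree(ape::as.phylo(hc), file.path(out_dir, "dendrogram.nwk"))
}
cat("condition clustering leaf order:",
    paste(utils::head(rownames(cm$matrix)[hc$order], 6), collapse = ", "),
    "...\n")
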