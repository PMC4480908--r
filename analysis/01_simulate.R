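#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study dataset.
#
# Simulates a two-arm methylation-perturbation experiment at the scale of
# the study design this pipeline targets: 20000 genes, four overlapping
# polycomb-target (PCGT) component sets covering 10% of genes, 1600 truly
# responsive genes per direction with a planted PCGT representation factor
# of 2, sequencing libraries for five conditions (two knockdown siRNAs,
# knockdown control, overexpression, vector control) and three-replicate
# array scores per condition. Writes the dataset in the same plain-text
# formats the pipeline reads.

library(methylshift)

out_dir <- "results/data"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

cfg <- simulation_config(seed = 20260920)
ds <- simulate_experiment(cfg)

write_gene_models_bed(ds$gene_models, file.path(out_dir, "genes.bed"))
write_count_matrix(ds$seq_counts, file.path(out_dir, "seq_counts.tsv"))
write_gmt(ds$pcgt_sets[c("suz12", "eed", "phc1", "rnf2", "all", "any")],
          file.path(out_dir, "pcgt_sets.gmt"))
for (cond in names(ds$array_scores)) {
  write.table(
    data.frame(gene_id = rownames(ds$array_scores[[cond]]),
               ds$array_scores[[cond]]),
    file.path(out_dir, sprintf("array_scores_%s.tsv", cond)),
    sep = "\t", quote = FALSE, row.names = FALSE)
}
write.table(ds$truth, file.path(out_dir, "truth.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE)
for (nm in c("spike", "expression")) {
  write.table(ds$ct_tables[[nm]],
              file.path(out_dir, sprintf("ct_%s.tsv", nm)),
              sep = "\t", quote = FALSE, row.names = FALSE)
}

cat(sprintf(
  "simulated %d genes (seed %d): %d PCGTs, %d responsive per direction, planted RF %.1f (odds %.3f)\n",
  cfg$n_genes, cfg$seed, length(ds$pcgt_sets$any), cfg$n_responsive,
  cfg$target_rf, cfg$enrichment_odds))
cat("wrote annotation, counts, array scores, PCGT sets, Ct tables and truth to",
    out_dir, "\n")
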