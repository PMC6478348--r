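#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study dataset.
#
# Emulates the design of the exon-level RNA-Seq experiment the package
# targets: two conditions (alcohol-exposed vs saline control) with two pooled
# replicates each, NB-distributed exon counts over multi-exon genes, 10% of
# exons carrying a planted usage shift (signs alternating within a gene so a
# gene's total can stay flat), a few percent of exons hosting a miRNA locus,
# and a KEGG-like annotation catalog with meta-group labels.

library(exonml)

cfg <- pipeline_config(
  out_dir = "results/synthetic",
  seeds = list(simulate = 11L, ml = 12L, enrichment = 13L),
  sim = simulation_config(n_genes = 300, exons_per_gene = c(2, 8),
                          frac_deu_exons = 0.10, deu_log2_effect = 1.5,
                          frac_mirna_host = 0.05,
                          nb_mean_range = c(50, 2000), seed = 11L))

ds <- run_simulate(cfg)

message(sprintf("wrote %d exons over %d genes; %d planted DEU exons, %d miRNA hosts",
                nrow(ds$counts), length(unique(ds$counts$gene_id)),
                sum(ds$truth$is_deu), sum(ds$truth$is_mirna_host)))
message("outputs under results/synthetic/: counts.tsv, truth.tsv, ",
        "conditions.tsv, mirna_loci.tsv, catalog.gmt, meta_map.tsv")
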