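#!/usr/bin/env Rscript
# Step 1 — simulate the study-like dataset.
#
# Generates a two-condition (FXD vs healthy donor) experiment: reference
# gene sequences with group-specific CG-dinucleotide density (changed genes
# more CG-suppressed than unchanged ones), gene models and CpG islands on a
# synthetic chromosome, clonal per-sample haplotypes with a higher AT>CG
# substitution rate in the FXD condition, and n = 3 replicate libraries per
# sample at 30x coverage. Bulky per-position pileups go to scratch/sim/;
# small summary tables go to results/.

suppressMessages(library(tespectra))

cfg <- simulation_config(seed = 20240101, n_genes = 20L,
                         gene_length_range = c(2000L, 4000L),
                         samples_per_condition = 2L, replicates = 3L,
                         coverage = 30)
dir.create("scratch/sim", recursive = TRUE, showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

ref <- simulate_reference(cfg)
write_consensus_fasta(ref$gene_seqs, "scratch/sim/reference.fasta")
writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", ref$genes$chrom,
                   ref$genes$start, ref$genes$end, ref$genes$gene_id,
                   ref$genes$strand), "scratch/sim/genes.bed")
writeLines(sprintf("%s\t%d\t%d", ref$islands$chrom, ref$islands$start,
                   ref$islands$end), "scratch/sim/islands.bed")

sim <- simulate_experiment(ref)
truth_all <- list()
for (k in seq_along(sim$samples)) {
  s <- sim$samples[[k]]
  f <- sprintf("scratch/sim/pileup_%s_r%d.tsv", s$sample_id, s$replicate)
  write_pileup_tsv(s$pileups, f)
  truth_all[[k]] <- s$truth
}
write_table_tsv(do.call(rbind, truth_all), "scratch/sim/truth_counts.tsv")

tabs <- simulate_stats_tables(cfg, ref$truth)
write_table_tsv(tabs$de, "scratch/sim/de.tsv")
write_table_tsv(tabs$splicing, "scratch/sim/splicing.tsv")
dir.create("scratch/sim/te_lists", showWarnings = FALSE)
for (s in names(tabs$te_lists))
  writeLines(tabs$te_lists[[s]], sprintf("scratch/sim/te_lists/%s.txt", s))
write_table_tsv(data.frame(sample = names(tabs$condition_of),
                           condition = unname(tabs$condition_of)),
                "scratch/sim/conditions.tsv")
write_table_tsv(ref$truth, "results/01_gene_truth.tsv")

cat(sprintf("simulated %d genes (%d-%d bp), %d libraries\n",
            cfg$n_genes, min(ref$genes$length_bp), max(ref$genes$length_bp),
            length(sim$samples)))
cat(sprintf("CG density: changed genes %.1f/kb, unchanged %.1f/kb (targets %g / %g)\n",
            mean(1000 * ref$truth$cg_count[ref$truth$status != "none"] /
                   ref$truth$length_bp[ref$truth$status != "none"]),
            mean(1000 * ref$truth$cg_count[ref$truth$status == "none"] /
                   ref$truth$length_bp[ref$truth$status == "none"]),
            cfg$cg_density_targets[["changed"]],
            cfg$cg_density_targets[["unchanged"]]))
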