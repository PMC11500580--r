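#!/usr/bin/env Rscript
# Step 2 — consensus calling and the substitution spectrum.
#
# Reads the simulated pileups back through the io layer, calls a consensus
# per gene per library with the 0.51 minimum-fraction rule, counts the
# twelve reference->consensus substitution classes, normalizes the total to
# substitutions per kb, and aggregates the AT>CG / CG>AT ratio into a
# group x sample matrix (replicate means first, then gene means) with its
# row-wise z-score view. Also records CG and GC dinucleotide densities of
# each consensus.

suppressMessages(library(tespectra))

genes <- read_gene_models("scratch/sim/genes.bed")
ref_seqs <- read_fasta_seqs("scratch/sim/reference.fasta")
truth <- read_table_tsv("results/01_gene_truth.tsv")
cond_tab <- read_table_tsv("scratch/sim/conditions.tsv")

pileup_files <- list.files("scratch/sim", pattern = "^pileup_.*\\.tsv$",
                           full.names = TRUE)
all_spectra <- list()
all_dinuc <- list()
for (f in pileup_files) {
  meta <- sub("^pileup_(.*)_r(\\d+)\\.tsv$", "\\1 \\2", basename(f))
  sample_id <- strsplit(meta, " ")[[1]][1]
  replicate <- as.integer(strsplit(meta, " ")[[1]][2])
  pileups <- lapply(seq_len(nrow(genes)), function(i)
    read_pileup(f, genes[i, ]))
  names(pileups) <- genes$gene_id
  sp <- sample_spectra(ref_seqs, pileups)
  sp$sample <- sample_id
  sp$replicate <- replicate
  all_spectra[[f]] <- sp
  cons <- lapply(names(pileups), function(g)
    call_consensus(pileups[[g]], gene_id = g))
  names(cons) <- names(pileups)
  all_dinuc[[f]] <- do.call(rbind, lapply(names(cons), function(g) {
    cg <- dinucleotide_density(cons[[g]]$seq, "CG", gene_id = g)
    gc <- dinucleotide_density(cons[[g]]$seq, "GC", gene_id = g)
    data.frame(gene_id = g, sample = sample_id, replicate = replicate,
               cg_count = cg$count, cg_per_kb = cg$per_kb,
               gc_count = gc$count, gc_per_kb = gc$per_kb)
  }))
}
spectra <- do.call(rbind, all_spectra)
rownames(spectra) <- NULL
write_table_tsv(spectra, "results/02_spectra.tsv")
write_table_tsv(do.call(rbind, all_dinuc), "results/02_dinucleotide.tsv")

# group = planted change status; columns = samples
groups <- split(truth$gene_id,
                ifelse(truth$status == "none", "unchanged", "changed"))
per_gene <- data.frame(gene_id = spectra$gene_id, sample = spectra$sample,
                       replicate = spectra$replicate,
                       at_to_cg = spectra$at_to_cg,
                       cg_to_at = spectra$cg_to_at)
for (scheme in c("mean_of_gene_ratios", "ratio_of_summed_counts")) {
  m <- aggregate_group_matrix(per_gene, groups, scheme = scheme)
  write_table_tsv(data.frame(group = rownames(m$values), m$values,
                             check.names = FALSE),
                  sprintf("results/02_ratio_matrix_%s.tsv", scheme))
  write_table_tsv(data.frame(group = rownames(m$z_view), m$z_view,
                             check.names = FALSE),
                  sprintf("results/02_ratio_zscore_%s.tsv", scheme))
}

m <- aggregate_group_matrix(per_gene, groups)
cat("group-mean AT>CG / CG>AT ratio (mean_of_gene_ratios):\n")
print(round(m$values, 3))
cond_of <- setNames(cond_tab$condition, cond_tab$sample)
for (cn in unique(cond_of)) {
  cols <- names(cond_of)[cond_of == cn]
  cat(sprintf("  condition %-8s mean over samples: %.3f\n", cn,
              mean(m$values[, cols])))
}
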