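small_cfg <- function(...) {
  simulation_config(seed = 101, n_genes = 6L,
                    gene_length_range = c(900L, 1200L),
                    samples_per_condition = 1L, replicates = 2L,
                    coverage = 25, ...)
}

test_that("the same seed reproduces reference, reads and tables exactly", {
  cfg <- small_cfg()
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(r1$gene_seqs, r2$gene_seqs)
  expect_identical(r1$genes, r2$genes)
  expect_identical(r1$islands, r2$islands)
  s1 <- simulate_sample(r1, cfg, "FXD", "FXD_s1", 1)
  s2 <- simulate_sample(r2, cfg, "FXD", "FXD_s1", 1)
  expect_identical(s1$pileups, s2$pileups)
  t1 <- simulate_stats_tables(cfg, r1$truth)
  t2 <- simulate_stats_tables(cfg, r2$truth)
  expect_identical(t1, t2)
})

test_that("reference CG densities honor the group targets", {
  cfg <- simulation_config(seed = 7, n_genes = 4L,
                           gene_length_range = c(1000L, 1000L),
                           cg_density_targets = c(changed = 500,
                                                  unchanged = 500),
                           frac_de = 0.5, frac_splicing = 0)
  ref <- simulate_reference(cfg)
  dens <- vapply(ref$gene_seqs, function(s)
    dinucleotide_density(s, "CG")$per_kb, numeric(1))
  expect_true(all(dens >= 450 & dens <= 550))

  cfg0 <- simulation_config(seed = 7, n_genes = 3L,
                            gene_length_range = c(500L, 800L),
                            cg_density_targets = c(changed = 0,
                                                   unchanged = 0))
  ref0 <- simulate_reference(cfg0)
  expect_true(all(vapply(ref0$gene_seqs, function(s)
    dinucleotide_density(s, "CG")$count, numeric(1)) == 0))

  expect_error(
    simulate_reference(simulation_config(
      cg_density_targets = c(changed = 1500, unchanged = 10))),
    "unattainable")
})

test_that("emitted fixtures round-trip through the io readers", {
  cfg <- small_cfg()
  ref <- simulate_reference(cfg)
  dir <- tempfile(); dir.create(dir)
  fa <- file.path(dir, "reference.fasta")
  write_consensus_fasta(ref$gene_seqs, fa)
  expect_identical(read_fasta_seqs(fa), ref$gene_seqs)
  bed <- file.path(dir, "genes.bed")
  writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", ref$genes$chrom,
                     ref$genes$start, ref$genes$end, ref$genes$gene_id,
                     ref$genes$strand), bed)
  gm <- read_gene_models(bed)
  expect_equal(gm$gene_id, ref$genes$gene_id)
  expect_equal(gm$length_bp, ref$genes$length_bp)
  s <- simulate_sample(ref, cfg, "FXD", "FXD_s1", 1)
  tsv <- file.path(dir, "pileup.tsv")
  write_pileup_tsv(s$pileups, tsv)
  for (g in names(s$pileups)[1:2]) {
    back <- read_pileup(tsv, gm[gm$gene_id == g, ])
    expect_equal(unname(back[, ]), unname(s$pileups[[g]][, ]))
  }
})

test_that("zero substitution and error rates reconstruct the reference", {
  cfg <- simulation_config(seed = 11, n_genes = 5L,
                           gene_length_range = c(800L, 1000L),
                           samples_per_condition = 1L, replicates = 1L,
                           coverage = 30, rate_at_to_cg = 0,
                           rate_cg_to_at = 0, error_rate = 0)
  ref <- simulate_reference(cfg)
  s <- simulate_sample(ref, cfg, "FXD", "FXD_s1", 1)
  for (g in names(s$pileups)) {
    cons <- call_consensus(s$pileups[[g]], gene_id = g)
    expect_identical(cons$seq, ref$gene_seqs[[g]])
  }
  sp <- sample_spectra(ref$gene_seqs, s$pileups)
  expect_true(all(sp$total_per_kb == 0))
  expect_true(all(is.na(sp$ratio)))
})

test_that("coverage 1 leaves exactly the zero-depth positions uncalled", {
  cfg <- simulation_config(seed = 13, n_genes = 3L,
                           gene_length_range = c(600L, 800L),
                           coverage = 1, rate_at_to_cg = 0,
                           rate_cg_to_at = 0, error_rate = 0)
  ref <- simulate_reference(cfg)
  s <- simulate_sample(ref, cfg, "healthy", "healthy_s1", 1)
  for (g in names(s$pileups)) {
    depth <- rowSums(s$pileups[[g]])
    cons <- call_consensus(s$pileups[[g]])
    expect_equal(cons$n_failed, sum(depth == 0))
    expect_gt(cons$n_failed, 0)   # coverage 1 leaves gaps
  }
})

test_that("recovered group ratio responds monotonically to the planted rate", {
  ratios <- vapply(c(0.005, 0.01, 0.02), function(r) {
    cfg <- simulation_config(seed = 17, n_genes = 10L,
                             gene_length_range = c(2000L, 2500L),
                             samples_per_condition = 1L, replicates = 1L,
                             coverage = 30, rate_at_to_cg = r,
                             rate_cg_to_at = 0.01, error_rate = 0.002)
    ref <- simulate_reference(cfg)
    s <- simulate_sample(ref, cfg, "FXD", "FXD_s1", 1)
    sp <- sample_spectra(ref$gene_seqs, s$pileups)
    mean(sp$ratio, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(ratios) > 0))
})

test_that("stats tables reproduce the planted gene-set structure", {
  cfg <- simulation_config(seed = 19, n_genes = 40L,
                           gene_length_range = c(500L, 700L),
                           cg_density_targets = c(changed = 16,
                                                  unchanged = 16),
                           frac_de = 0.25, frac_splicing = 0.25,
                           te_side_probs = c(A_only = 0.5, B_only = 0.25,
                                             both = 0.25))
  ref <- simulate_reference(cfg)
  tabs <- simulate_stats_tables(cfg, ref$truth)
  de <- de_gene_set(tabs$de)
  expect_setequal(de$members, ref$truth$gene_id[ref$truth$status == "de"])
  sp <- splicing_gene_set(tabs$splicing)
  expect_setequal(sp$members,
                  ref$truth$gene_id[ref$truth$status == "splicing"])
  merged <- merge_te_lists(tabs$te_lists, tabs$condition_of)
  expect_setequal(merged$FXD$members,
                  ref$truth$gene_id[ref$truth$te_side %in%
                                      c("A_only", "both")])
  expect_setequal(merged$healthy$members,
                  ref$truth$gene_id[ref$truth$te_side %in%
                                      c("B_only", "both")])
  part <- venn_partition(merged$FXD, merged$healthy, de, sp)
  tab <- partition_table(part)
  planted <- ifelse(ref$truth$te_side == "both", "both",
                    ref$truth$te_side)
  planted_status <- ifelse(ref$truth$status == "none", "none",
                           ref$truth$status)
  want <- paste(planted, planted_status, sep = ".")
  names(want) <- ref$truth$gene_id
  got <- setNames(tab$cell, tab$gene_id)
  expect_equal(got[names(want)], want)

  # frac_de = 0 -> empty DE set
  cfg0 <- small_cfg(frac_de = 0)
  ref0 <- simulate_reference(cfg0)
  tabs0 <- simulate_stats_tables(cfg0, ref0$truth)
  expect_equal(length(de_gene_set(tabs0$de)$members), 0L)
})
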