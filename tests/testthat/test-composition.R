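test_that("count_substitutions handles identity, swaps and normalization", {
  s0 <- count_substitutions("ACGT", "ACGT")
  expect_true(all(s0$class_counts == 0L))
  expect_equal(s0$total_per_kb, 0)
  expect_true(is.na(s0$ratio))

  s1 <- count_substitutions("ATCG", "GCAT")
  expect_equal(unname(s1$class_counts[c("A>G", "T>C", "C>A", "G>T")]),
               rep(1L, 4))
  expect_equal(s1$at_to_cg, 2L)
  expect_equal(s1$cg_to_at, 2L)
  expect_equal(s1$ratio, 1)

  s2 <- count_substitutions("AAAA", "CCCC")
  expect_equal(unname(s2$class_counts["A>C"]), 4L)
  expect_equal(s2$total_per_kb, 4 / (4 / 1000))
  expect_equal(s2$total_per_kb, 1000)

  expect_error(count_substitutions("ACG", "AC"), "equal length")
  expect_error(count_substitutions("ACGX", "ACGT"), "non-ACGT")
})

test_that("consensus N counts toward the total but neither class sum", {
  s <- count_substitutions("ACGT", "NNGT")
  expect_equal(s$n_to_N, 2L)
  expect_equal(s$at_to_cg + s$cg_to_at, 0L)
  expect_equal(s$total_per_kb, 2 / (4 / 1000))
  s_ex <- count_substitutions("ACGT", "NNGT", n_policy = "exclude")
  expect_equal(s_ex$total_per_kb, 0)
})

test_that("substitution_ratio handles pseudocounts and 0/0", {
  expect_equal(substitution_ratio(list(at_to_cg = 2, cg_to_at = 1)), 2)
  expect_true(is.na(substitution_ratio(list(at_to_cg = 0, cg_to_at = 0))))
  expect_equal(substitution_ratio(list(at_to_cg = 3, cg_to_at = 0),
                                  pseudocount = 1), 4)
  expect_error(substitution_ratio(list(at_to_cg = 1, cg_to_at = 1), -1),
               ">= 0")
})

test_that("spectrum matches the positionwise oracle on all short {A,C} pairs", {
  for (L in 1:4) {
    combos <- expand.grid(rep(list(c("A", "C")), 2 * L),
                          stringsAsFactors = FALSE)
    for (r in seq_len(nrow(combos))) {
      ref <- paste(unlist(combos[r, 1:L]), collapse = "")
      cons <- paste(unlist(combos[r, (L + 1):(2 * L)]), collapse = "")
      got <- count_substitutions(ref, cons)
      want <- oracle_count_subs(ref, cons)
      expect_equal(got$at_to_cg, want$at)
      expect_equal(got$cg_to_at, want$cg)
      expect_equal(sum(got$class_counts), want$n_sub)
    }
  }
})

test_that("class sums are invariant under joint reverse complement", {
  set.seed(31)
  for (i in 1:60) {
    L <- sample(10:200, 1)
    ref <- random_dna(L)
    cons <- strsplit(ref, "")[[1]]
    mut <- sample(L, ceiling(L / 5))
    cons[mut] <- sample(c(BASES, "N"), length(mut), replace = TRUE)
    cons <- paste(cons, collapse = "")
    a <- count_substitutions(ref, cons)
    b <- count_substitutions(revcomp(ref), revcomp(cons))
    expect_equal(a$at_to_cg, b$at_to_cg)
    expect_equal(a$cg_to_at, b$cg_to_at)
    expect_equal(a$n_to_N, b$n_to_N)
    expect_equal(a$ratio, b$ratio)
    # conservation: mismatches == 12-class sum + n_to_N
    mism <- sum(strsplit(ref, "")[[1]] != strsplit(cons, "")[[1]])
    expect_equal(sum(a$class_counts) + a$n_to_N, mism)
  }
})

test_that("dinucleotide density counts overlapping windows and skips N", {
  d <- dinucleotide_density("CGCG", "CG")
  expect_equal(d$count, 2L)
  expect_equal(d$per_kb, 500)
  expect_equal(d$n_valid_windows, 3L)
  expect_equal(dinucleotide_density("GGGG", "CG")$count, 0L)
  d2 <- dinucleotide_density("CNGCG", "CG")
  expect_equal(d2$count, 1L)
  expect_equal(d2$n_valid_windows, 2L)
  expect_equal(dinucleotide_density("A", "CG")$count, 0L)
  expect_error(dinucleotide_density("ACGT", "CGA"), "2-mer")
})

test_that("CG and GC counts are palindromic under reverse complement", {
  set.seed(13)
  for (i in 1:60) {
    s <- random_dna(sample(20:300, 1))
    rc <- revcomp(s)
    expect_equal(dinucleotide_density(s, "CG")$count,
                 dinucleotide_density(rc, "CG")$count)
    expect_equal(dinucleotide_density(s, "GC")$count,
                 dinucleotide_density(rc, "GC")$count)
  }
})

test_that("dinucleotide counting agrees with Biostrings on N-free sequences", {
  set.seed(17)
  for (i in 1:20) {
    s <- random_dna(sample(50:500, 1))
    for (p in c("CG", "GC", "AA")) {
      expect_equal(dinucleotide_density(s, p)$count,
                   Biostrings::countPattern(p, Biostrings::DNAString(s)))
    }
  }
})

test_that("self-concatenation leaves per-kb density unchanged up to the junction", {
  set.seed(19)
  for (i in 1:20) {
    s <- random_dna(500)
    d1 <- dinucleotide_density(s, "CG")
    d2 <- dinucleotide_density(paste0(s, s), "CG")
    expect_true(abs(d2$count - 2 * d1$count) <= 1)   # one junction window
    expect_true(abs(d2$per_kb - d1$per_kb) <= 1000 / 1000)
  }
})

test_that("aggregate_group_matrix collapses replicates then genes", {
  # replicate ratios 1, 2, 3 -> cell 2
  pg <- data.frame(gene_id = "gA", sample = "s1", replicate = 1:3,
                   at_to_cg = c(2, 4, 6), cg_to_at = c(2, 2, 2))
  m <- aggregate_group_matrix(pg, list(grp = "gA"))
  expect_equal(unname(m$values["grp", "s1"]), 2)

  # mean of gene ratios
  pg2 <- data.frame(gene_id = c("gA", "gB"), sample = "s1", replicate = 1L,
                    at_to_cg = c(1, 3), cg_to_at = c(1, 1))
  m2 <- aggregate_group_matrix(pg2, list(grp = c("gA", "gB")),
                               scheme = "mean_of_gene_ratios")
  expect_equal(unname(m2$values["grp", "s1"]), 2)

  # ratio of summed counts: (2+0)/(1+3)
  pg3 <- data.frame(gene_id = c("gA", "gB"), sample = "s1", replicate = 1L,
                    at_to_cg = c(2, 0), cg_to_at = c(1, 3))
  m3 <- aggregate_group_matrix(pg3, list(grp = c("gA", "gB")),
                               scheme = "ratio_of_summed_counts")
  expect_equal(unname(m3$values["grp", "s1"]), 0.5)

  # undefined per-gene ratios are excluded from the mean
  pg4 <- data.frame(gene_id = c("gA", "gB"), sample = "s1", replicate = 1L,
                    at_to_cg = c(2, 5), cg_to_at = c(1, 0))
  m4 <- aggregate_group_matrix(pg4, list(grp = c("gA", "gB")))
  expect_equal(unname(m4$values["grp", "s1"]), 2)

  expect_error(aggregate_group_matrix(pg, list(g = "gA"), scheme = "nope"))
})

test_that("row z-scores standardize rows and blank degenerate ones", {
  m <- rbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, NA, NA))
  z <- row_zscore(m)
  expect_equal(unname(z["a", ]), c(-1, 0, 1))
  expect_true(all(is.na(z["b", ])))
  expect_true(all(is.na(z["c", ])))
  # invariant: mean 0, sample SD 1
  set.seed(5)
  mm <- matrix(rnorm(40), 4, 10)
  zz <- row_zscore(mm)
  expect_equal(unname(rowMeans(zz)), rep(0, 4))
  expect_equal(unname(apply(zz, 1, sd)), rep(1, 4))
})
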