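## Substitution spectra (consensus vs reference), the AT>CG / CG>AT ratio,
## dinucleotide densities, and group x sample aggregation.
##
## The twelve ordered substitution classes are lumped into two sums:
##   AT>CG = A>C + A>G + T>C + T>G   (an A or T replaced by a C or G)
##   CG>AT = C>A + C>T + G>A + G>T   (a C or G replaced by an A or T)
## Both sets are closed under complementation, so the ratio is invariant
## under joint reverse complement of reference and consensus.

SUB_CLASSES <- c("A>C", "A>G", "A>T",
                 "C>A", "C>G", "C>T",
                 "G>A", "G>C", "G>T",
                 "T>A", "T>C", "T>G")
AT_TO_CG_CLASSES <- c("A>C", "A>G", "T>C", "T>G")
CG_TO_AT_CLASSES <- c("C>A", "C>T", "G>A", "G>T")

#' Count base substitutions between a reference and a consensus sequence
#'
#' Compares sequences position by position. Positions where the consensus is
#' `N` are counted separately (`n_to_N`) and belong to no substitution
#' class; by default they still count toward the per-kb total substitution
#' load (`n_policy = "total_only"`), or can be excluded entirely
#' (`"exclude"`). The total is normalized to gene length per 1000 bp.
#'
#' @param reference String over A,C,G,T.
#' @param consensus String over A,C,G,T,N of the same length.
#' @param gene_id Optional id stored on the result.
#' @param n_policy How consensus-N positions enter the total:
#'   `"total_only"` (default) or `"exclude"`.
#' @return A list of class `substitution_spectrum`: `gene_id`,
#'   `class_counts` (named integer vector over the 12 classes), `n_to_N`,
#'   `length_bp`, `total_per_kb`, `at_to_cg`, `cg_to_at`, `ratio`
#'   (`NA` when `cg_to_at` is 0).
#' @export
count_substitutions <- function(reference, consensus, gene_id = NULL,
                                n_policy = c("total_only", "exclude")) {
  n_policy <- match.arg(n_policy)
  if (nchar(reference) != nchar(consensus))
    stop("reference and consensus must have equal length")
  r <- strsplit(toupper(reference), "")[[1]]
  s <- strsplit(toupper(consensus), "")[[1]]
  if (!all(r %in% PILEUP_BASES))
    stop("reference contains a non-ACGT base")
  if (!all(s %in% c(PILEUP_BASES, "N")))
    stop("consensus contains a base outside A,C,G,T,N")
  mism <- r != s
  to_n <- mism & s == "N"
  sub <- mism & !to_n
  counts <- stats::setNames(integer(length(SUB_CLASSES)), SUB_CLASSES)
  if (any(sub)) {
    tab <- table(paste0(r[sub], ">", s[sub]))
    counts[names(tab)] <- as.integer(tab)
  }
  L <- length(r)
  n_to_N <- sum(to_n)
  total <- sum(counts) + if (n_policy == "total_only") n_to_N else 0L
  at <- sum(counts[AT_TO_CG_CLASSES])
  cg <- sum(counts[CG_TO_AT_CLASSES])
  structure(
    list(gene_id = gene_id,
         class_counts = counts,
         n_to_N = n_to_N,
         length_bp = L,
         total_per_kb = total / (L / 1000),
         at_to_cg = at,
         cg_to_at = cg,
         ratio = if (cg > 0) at / cg else NA_real_),
    class = "substitution_spectrum"
  )
}

#' AT>CG / CG>AT ratio of a substitution spectrum
#'
#' @param spec A `substitution_spectrum` (or any list with `at_to_cg` and
#'   `cg_to_at`).
#' @param pseudocount Non-negative value added to numerator and denominator;
#'   with the default 0 the ratio is `NA` when `cg_to_at` is 0.
#' @return The ratio, or `NA_real_` when undefined.
#' @export
substitution_ratio <- function(spec, pseudocount = 0) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  num <- spec$at_to_cg + pseudocount
  den <- spec$cg_to_at + pseudocount
  if (den == 0) NA_real_ else num / den
}

#' Dinucleotide density of a sequence
#'
#' Counts occurrences of a 2-mer in overlapping windows (step 1). Windows
#' containing `N` are skipped and excluded from `n_valid_windows`. The
#' density is the count normalized to gene length in kb
#' (`count / (length_bp / 1000)`).
#'
#' @param seq String over A,C,G,T,N.
#' @param pattern A 2-mer over A,C,G,T, e.g. `"CG"`.
#' @param length_bp Gene length used for normalization; defaults to
#'   `nchar(seq)`.
#' @param gene_id Optional id stored on the result.
#' @return A list of class `dinucleotide_density`: `gene_id`, `pattern`,
#'   `count`, `per_kb`, `n_valid_windows`.
#' @export
dinucleotide_density <- function(seq, pattern, length_bp = nchar(seq),
                                 gene_id = NULL) {
  pattern <- toupper(pattern)
  if (nchar(pattern) != 2L ||
      !all(strsplit(pattern, "")[[1]] %in% PILEUP_BASES))
    stop("pattern must be a 2-mer over A,C,G,T")
  if (length_bp != nchar(seq))
    stop("length_bp must equal the sequence length")
  v <- strsplit(toupper(seq), "")[[1]]
  if (length(v) < 2L) {
    count <- 0L; nvalid <- 0L
  } else {
    a <- v[-length(v)]
    b <- v[-1L]
    valid <- a != "N" & b != "N"
    p <- strsplit(pattern, "")[[1]]
    count <- sum(valid & a == p[1] & b == p[2])
    nvalid <- sum(valid)
  }
  structure(
    list(gene_id = gene_id, pattern = pattern, count = count,
         per_kb = if (length_bp > 0) count / (length_bp / 1000) else NA_real_,
         n_valid_windows = nvalid),
    class = "dinucleotide_density"
  )
}

#' Aggregate per-gene ratios into a group x sample matrix
#'
#' Collapses the replicate dimension first by arithmetic mean (the study
#' design has n = 3 library replicates per sample), then the gene dimension
#' per group according to the chosen scheme:
#' \describe{
#'   \item{mean_of_gene_ratios}{mean over genes of the per-gene
#'     replicate-averaged AT>CG/CG>AT ratios; undefined ratios are excluded.}
#'   \item{ratio_of_summed_counts}{replicate-averaged class counts are
#'     summed over the group's genes, then the ratio of the sums is taken.}
#' }
#' A cell is `NA` when no defined value remains.
#'
#' @param per_gene A data.frame with columns `gene_id`, `sample`,
#'   `replicate`, `at_to_cg`, `cg_to_at` (a `ratio` column is derived;
#'   alternatively a precomputed `value` column is used directly for the
#'   `mean_of_gene_ratios` scheme).
#' @param groups A `gene_partition` (see [venn_partition()]), or a named
#'   list of gene-id vectors, or a data.frame with columns `gene_id`, `cell`.
#' @param scheme Aggregation scheme (see above).
#' @return A list of class `group_sample_matrix` with elements `values`
#'   (matrix groups x samples), `scheme`, and `z_view` (row-wise z-scores,
#'   see [row_zscore()]).
#' @export
aggregate_group_matrix <- function(per_gene, groups,
                                   scheme = c("mean_of_gene_ratios",
                                              "ratio_of_summed_counts")) {
  scheme <- match.arg(scheme)
  cells <- as_group_list(groups)
  stopifnot(all(c("gene_id", "sample", "replicate") %in% names(per_gene)))
  has_counts <- all(c("at_to_cg", "cg_to_at") %in% names(per_gene))
  if (scheme == "ratio_of_summed_counts" && !has_counts)
    stop("scheme ratio_of_summed_counts needs at_to_cg and cg_to_at columns")
  if (!has_counts && !"value" %in% names(per_gene))
    stop("per_gene needs either at_to_cg/cg_to_at or a value column")
  samples <- sort(unique(as.character(per_gene$sample)))
  values <- matrix(NA_real_, nrow = length(cells), ncol = length(samples),
                   dimnames = list(names(cells), samples))
  key <- interaction(per_gene$gene_id, per_gene$sample, drop = TRUE)
  ## replicate collapse: per (gene, sample)
  if (has_counts) {
    at_m <- tapply(per_gene$at_to_cg, key, mean)
    cg_m <- tapply(per_gene$cg_to_at, key, mean)
    rat <- ifelse(!is.na(per_gene$cg_to_at) & per_gene$cg_to_at > 0,
                  per_gene$at_to_cg / per_gene$cg_to_at, NA_real_)
  } else {
    rat <- per_gene$value
  }
  rat_m <- tapply(rat, key, function(x) {
    x <- x[!is.na(x)]
    if (length(x)) mean(x) else NA_real_
  })
  ## interaction() pastes gene.sample; recover the pairs from the source
  ## table rather than parsing the pasted key (gene ids may contain dots)
  gs <- unique(data.frame(gene_id = as.character(per_gene$gene_id),
                          sample = as.character(per_gene$sample),
                          k = as.character(key), stringsAsFactors = FALSE))
  rownames(gs) <- gs$k
  for (ci in seq_along(cells)) {
    members <- cells[[ci]]
    for (s in samples) {
      ks <- gs$k[gs$sample == s & gs$gene_id %in% members]
      if (!length(ks)) next
      if (scheme == "mean_of_gene_ratios") {
        v <- rat_m[ks]
        v <- v[!is.na(v)]
        if (length(v)) values[ci, s] <- mean(v)
      } else {
        at_s <- sum(at_m[ks], na.rm = TRUE)
        cg_s <- sum(cg_m[ks], na.rm = TRUE)
        if (cg_s > 0) values[ci, s] <- at_s / cg_s
      }
    }
  }
  structure(list(values = values, scheme = scheme,
                 z_view = row_zscore(values)),
            class = "group_sample_matrix")
}

as_group_list <- function(groups) {
  if (inherits(groups, "gene_partition")) return(groups$cells)
  if (is.data.frame(groups)) {
    stopifnot(all(c("gene_id", "cell") %in% names(groups)))
    return(split(as.character(groups$gene_id), groups$cell))
  }
  if (is.list(groups) && !is.null(names(groups))) return(groups)
  stop("groups must be a gene_partition, a named list, or a data.frame")
}

#' Row-wise z-scores of a matrix
#'
#' Each row is standardized as (x - row mean) / row sample SD (ddof 1) over
#' its non-missing cells. Rows with fewer than two non-missing values, or
#' with zero SD, become all-`NA`.
#'
#' @param m A numeric matrix, or a `group_sample_matrix` (its `values` are
#'   used).
#' @return A matrix of the same shape.
#' @export
row_zscore <- function(m) {
  if (inherits(m, "group_sample_matrix")) m <- m$values
  stopifnot(is.matrix(m))
  out <- m
  for (i in seq_len(nrow(m))) {
    x <- m[i, ]
    ok <- !is.na(x)
    if (sum(ok) < 2L) { out[i, ] <- NA_real_; next }
    s <- stats::sd(x[ok])
    if (!is.finite(s) || s == 0) { out[i, ] <- NA_real_; next }
    out[i, ] <- (x - mean(x[ok])) / s
  }
  out
}

#' Per-gene substitution spectra for one sample/replicate
#'
#' Convenience wrapper: calls consensus for each gene pileup and compares it
#' to the gene-local reference.
#'
#' @param reference_seqs Named character vector of gene-local reference
#'   sequences.
#' @param pileups Named list of pileup matrices (same names).
#' @param min_fraction,min_depth Passed to [call_consensus()].
#' @param n_policy Passed to [count_substitutions()].
#' @return A data.frame with one row per gene: `gene_id`, `length_bp`, the
#'   12 class counts, `n_to_N`, `total_per_kb`, `at_to_cg`, `cg_to_at`,
#'   `ratio`, `n_called`, `n_failed`.
#' @export
sample_spectra <- function(reference_seqs, pileups, min_fraction = 0.51,
                           min_depth = 1L,
                           n_policy = c("total_only", "exclude")) {
  n_policy <- match.arg(n_policy)
  stopifnot(all(names(pileups) %in% names(reference_seqs)))
  rows <- lapply(names(pileups), function(g) {
    cons <- call_consensus(pileups[[g]], min_fraction = min_fraction,
                           min_depth = min_depth, gene_id = g)
    sp <- count_substitutions(reference_seqs[[g]], cons$seq, gene_id = g,
                              n_policy = n_policy)
    cbind(data.frame(gene_id = g, length_bp = sp$length_bp,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(sp$class_counts), check.names = FALSE),
          data.frame(n_to_N = sp$n_to_N, total_per_kb = sp$total_per_kb,
                     at_to_cg = sp$at_to_cg, cg_to_at = sp$cg_to_at,
                     ratio = sp$ratio, n_called = cons$n_called,
                     n_failed = cons$n_failed))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
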