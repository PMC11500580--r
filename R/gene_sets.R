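## Gene-set construction and the Venn partition of transposon-derived genes.
## The statistical model fits that produce the input tables (edgeR, rMATS)
## are consumed, not reimplemented; this module owns the thresholding,
## merging and partition logic.

#' Construct a gene set
#'
#' @param label Set label.
#' @param members Character vector of gene ids (made unique).
#' @return A list of class `gene_set` with `label` and `members`.
#' @export
gene_set <- function(label, members = character(0)) {
  structure(list(label = label,
                 members = unique(as.character(members))),
            class = "gene_set")
}

set_members <- function(x) {
  if (inherits(x, "gene_set")) x$members else unique(as.character(x))
}

#' Differentially expressed gene set by adjusted-p and fold-change cutoffs
#'
#' A gene is a member iff its adjusted p-value is below `adj_p_max` and its
#' absolute log2 fold change reaches `log2(min_fold_change)` (inclusive by
#' default; `fc_strict = TRUE` makes the fold-change comparison strict).
#' Records with a missing adjusted p or log2FC are excluded.
#'
#' @param stats A data.frame with columns `gene_id`, `adjusted_p`,
#'   `log2_fold_change`.
#' @param adj_p_max Adjusted p-value cutoff (exclusive), default 0.05.
#' @param min_fold_change Fold-change cutoff on the linear scale, default 2.
#' @param fc_strict Use `>` instead of `>=` for the fold-change comparison.
#' @return A `gene_set` labelled `"de"`.
#' @export
de_gene_set <- function(stats, adj_p_max = 0.05, min_fold_change = 2,
                        fc_strict = FALSE) {
  if (adj_p_max <= 0 || min_fold_change <= 0)
    stop("thresholds must be positive")
  stopifnot(all(c("gene_id", "adjusted_p", "log2_fold_change") %in%
                  names(stats)))
  lfc_min <- log2(min_fold_change)
  p_ok <- !is.na(stats$adjusted_p) & stats$adjusted_p < adj_p_max
  fc <- abs(stats$log2_fold_change)
  fc_ok <- !is.na(fc) & if (fc_strict) fc > lfc_min else fc >= lfc_min
  gene_set("de", stats$gene_id[p_ok & fc_ok])
}

#' Splicing-changed gene set from a flag table
#'
#' @param stats A data.frame with columns `gene_id` and `splicing_changed`
#'   (logical or 0/1); missing flags are excluded.
#' @return A `gene_set` labelled `"splicing"`.
#' @export
splicing_gene_set <- function(stats) {
  stopifnot(all(c("gene_id", "splicing_changed") %in% names(stats)))
  flag <- as.logical(stats$splicing_changed)
  gene_set("splicing", stats$gene_id[!is.na(flag) & flag])
}

#' Low-expression prefilter on counts-per-million
#'
#' Keeps genes with CPM (`count * 1e6 / library total`) at or above
#' `cpm_min` in at least `min_libraries` libraries.
#'
#' @param counts Non-negative count matrix, genes x libraries, with gene ids
#'   as rownames.
#' @param cpm_min CPM cutoff (inclusive), default 0.5.
#' @param min_libraries Minimum number of libraries reaching the cutoff.
#' @return A `gene_set` labelled `"expressed"`.
#' @export
cpm_prefilter <- function(counts, cpm_min = 0.5, min_libraries = 1L) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  if (any(counts < 0)) stop("counts must be non-negative")
  totals <- colSums(counts)
  if (any(totals == 0)) stop("zero-total library")
  cpm <- sweep(counts, 2, totals, "/") * 1e6
  keep <- rowSums(cpm >= cpm_min) >= min_libraries
  gene_set("expressed", rownames(counts)[keep])
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment, returned in input order and capped at 1
#' (delegates to `stats::p.adjust(method = "BH")` after validating the
#' input range).
#'
#' @param p_values Numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must be in [0, 1] with no missing values")
  stats::p.adjust(p_values, method = "BH")
}

#' Merge per-sample TE-derived gene lists within conditions
#'
#' @param per_sample_lists Named list (by sample) of `gene_set`s or gene-id
#'   vectors.
#' @param condition_of Named character vector mapping every sample name to
#'   its condition.
#' @return Named list (by condition) of `gene_set`s, each the union of that
#'   condition's sample sets.
#' @export
merge_te_lists <- function(per_sample_lists, condition_of) {
  samples <- names(per_sample_lists)
  missing <- setdiff(samples, names(condition_of))
  if (length(missing))
    stop("samples without a condition: ", paste(missing, collapse = ", "))
  conds <- unique(condition_of[samples])
  out <- lapply(conds, function(cn) {
    ids <- unlist(lapply(samples[condition_of[samples] == cn],
                         function(s) set_members(per_sample_lists[[s]])))
    gene_set(cn, ids)
  })
  names(out) <- conds
  out
}

#' Venn partition of TE-derived genes by detection condition and change
#' status
#'
#' The universe is the union of the two conditions' TE-derived gene sets.
#' Each gene falls into one detection cell (`A_only`, `B_only`, `both`) and
#' one status cell: `de` if in the expression-changed set, else `splicing`
#' if in the splicing-changed set, else `none`. Genes in both the DE and
#' splicing sets go to the `de` cell by default (the two sets barely overlap
#' in the study design this mirrors); with `overlap_cell = TRUE` they form
#' their own `de_and_splicing` cell instead. Cell labels are
#' `<detection>.<status>`; empty cells are dropped.
#'
#' @param te_condition_a,te_condition_b TE-derived `gene_set`s (or id
#'   vectors) for the two conditions.
#' @param de Expression-changed `gene_set` (or id vector).
#' @param splicing Splicing-changed `gene_set` (or id vector).
#' @param overlap_cell Emit genes in both `de` and `splicing` as a separate
#'   cell instead of applying the de-precedence rule.
#' @return A list of class `gene_partition`: `universe` (character vector)
#'   and `cells` (named list of disjoint gene-id vectors covering the
#'   universe).
#' @export
venn_partition <- function(te_condition_a, te_condition_b, de, splicing,
                           overlap_cell = FALSE) {
  a <- set_members(te_condition_a)
  b <- set_members(te_condition_b)
  de <- set_members(de)
  sp <- set_members(splicing)
  universe <- union(a, b)
  if (!length(universe))
    return(structure(list(universe = character(0), cells = list()),
                     class = "gene_partition"))
  in_a <- universe %in% a
  in_b <- universe %in% b
  det <- ifelse(in_a & in_b, "both", ifelse(in_a, "A_only", "B_only"))
  in_de <- universe %in% de
  in_sp <- universe %in% sp
  status <- rep("none", length(universe))
  if (overlap_cell) {
    status[in_de & in_sp] <- "de_and_splicing"
    status[in_de & !in_sp] <- "de"
    status[!in_de & in_sp] <- "splicing"
  } else {
    status[in_de] <- "de"                 # de takes precedence
    status[!in_de & in_sp] <- "splicing"
  }
  lab <- paste(det, status, sep = ".")
  cells <- split(universe, lab)
  structure(list(universe = universe, cells = cells),
            class = "gene_partition")
}

#' Partition membership as a table
#'
#' @param partition A `gene_partition`.
#' @return A data.frame with columns `gene_id`, `cell`.
#' @export
partition_table <- function(partition) {
  stopifnot(inherits(partition, "gene_partition"))
  if (!length(partition$cells))
    return(data.frame(gene_id = character(0), cell = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(names(partition$cells), function(nm) {
    data.frame(gene_id = partition$cells[[nm]], cell = nm,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Cell sizes of a partition
#'
#' @param partition A `gene_partition`.
#' @return Named integer vector of cell sizes.
#' @export
cell_sizes <- function(partition) {
  vapply(partition$cells, length, integer(1))
}

#' @export
print.gene_partition <- function(x, ...) {
  cat(sprintf("<gene_partition> %d genes in %d cells\n",
              length(x$universe), length(x$cells)))
  if (length(x$cells)) print(cell_sizes(x))
  invisible(x)
}
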