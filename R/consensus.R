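## Per-gene consensus calling with the minimum-fraction rule: a base is the
## consensus of a pileup column iff its count is at least `min_fraction` of
## the column depth; otherwise the position is an N. Because the fraction is
## strictly above 1/2, at most one base can qualify, so the call is always
## unambiguous. The comparison is done by integer cross-multiplication
## (count * scale >= depth * round(min_fraction * scale)) so the 51/100
## boundary is exact rather than subject to floating-point rounding.

FRACTION_SCALE <- 1e6

check_min_fraction <- function(min_fraction) {
  if (!is.numeric(min_fraction) || length(min_fraction) != 1L ||
      min_fraction <= 0.5 || min_fraction > 1)
    stop("min_fraction must be a single value in (0.5, 1]; ",
         "values <= 0.5 would make ties ambiguous")
  round(min_fraction * FRACTION_SCALE)
}

#' Call the consensus base of one pileup column
#'
#' @param counts Named numeric vector of base counts; names must include
#'   A, C, G, T (missing bases count 0).
#' @param min_fraction Minimum count fraction for a base to be called
#'   (inclusive); default 0.51. Must lie in (0.5, 1].
#' @return A single character: the called base, or `"N"` when no base
#'   reaches the fraction (including zero depth).
#' @export
call_base <- function(counts, min_fraction = 0.51) {
  thr <- check_min_fraction(min_fraction)
  if (is.null(names(counts)) && length(counts) == 4L)
    names(counts) <- PILEUP_BASES
  full <- stats::setNames(numeric(4), PILEUP_BASES)
  full[intersect(names(counts), PILEUP_BASES)] <-
    counts[intersect(names(counts), PILEUP_BASES)]
  if (any(full < 0)) stop("negative base count")
  depth <- sum(full)
  if (depth == 0) return("N")
  hit <- which(full * FRACTION_SCALE >= depth * thr)
  if (length(hit) == 1L) PILEUP_BASES[hit] else "N"
}

#' Call a whole-gene consensus sequence from a pileup
#'
#' Applies [call_base()] to every position of a gene pileup. Positions with
#' depth below `min_depth` (default 1, i.e. only zero-depth positions) are
#' emitted as `N`. The consensus never contains insertions or deletions: it
#' has exactly one character per reference position.
#'
#' @param pileup Integer matrix `length_bp x 4` with columns A, C, G, T (as
#'   returned by [read_pileup()]), or a data.frame with columns `position`,
#'   `nA`, `nC`, `nG`, `nT` covering each position at most once.
#' @param min_fraction Minimum called-base fraction, inclusive; in (0.5, 1].
#' @param min_depth Minimum depth for a position to be callable.
#' @param gene_id Optional id stored on the result (defaults to the
#'   pileup's `gene_id` attribute).
#' @param length_bp Required when `pileup` is a data.frame: the gene length.
#' @return A list of class `consensus_seq` with elements `gene_id`, `seq`
#'   (string over A,C,G,T,N), `n_called`, `n_failed`.
#' @export
call_consensus <- function(pileup, min_fraction = 0.51, min_depth = 1L,
                           gene_id = NULL, length_bp = NULL) {
  thr <- check_min_fraction(min_fraction)
  if (is.data.frame(pileup)) {
    if (is.null(length_bp))
      stop("length_bp is required for a data.frame pileup")
    need <- c("position", "nA", "nC", "nG", "nT")
    if (!all(need %in% names(pileup)))
      stop("pileup data.frame must have columns: ",
           paste(need, collapse = ", "))
    if (any(pileup$position < 0L | pileup$position >= length_bp))
      stop("pileup position outside [0, length_bp)")
    if (anyDuplicated(pileup$position))
      stop("duplicated pileup position")
    m <- empty_pileup(length_bp)
    idx <- pileup$position + 1L
    m[idx, ] <- as.matrix(pileup[, c("nA", "nC", "nG", "nT")])
    pileup <- m
  }
  stopifnot(is.matrix(pileup), ncol(pileup) == 4L)
  if (is.null(gene_id)) gene_id <- attr(pileup, "gene_id")
  storage.mode(pileup) <- "double"   # avoid integer overflow in the product
  depth <- rowSums(pileup)
  ok <- pileup * FRACTION_SCALE >= depth * thr   # depth recycled by column
  ok[depth < max(1L, min_depth), ] <- FALSE
  hit <- max.col(ok, ties.method = "first")
  called <- ok[cbind(seq_len(nrow(pileup)), hit)]
  bases <- rep("N", nrow(pileup))
  bases[called] <- PILEUP_BASES[hit[called]]
  structure(
    list(gene_id = gene_id,
         seq = paste(bases, collapse = ""),
         n_called = sum(called),
         n_failed = sum(!called)),
    class = "consensus_seq"
  )
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat(sprintf("<consensus_seq> %s: %d bp, %d called, %d N\n",
              x$gene_id %||% "<unnamed>",
              nchar(x$seq), x$n_called, x$n_failed))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
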