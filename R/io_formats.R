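## Readers/writers for the external formats the pipeline touches.
## All coordinates are 0-based half-open (BED convention) throughout the
## package; conversion to the 1-based closed convention happens only at the
## Rsamtools/IRanges boundary.

#' Read gene models from a BED6 file
#'
#' Parses a BED file with at least six columns (chrom, start, end, name,
#' score, strand) into a gene-model table. Coordinates are kept 0-based
#' half-open, rows keep file order, and `length_bp` is `end - start`.
#' `track`/`browser`/comment lines are skipped.
#'
#' @param path Path to a BED file.
#' @return A data.frame with columns `gene_id`, `chrom`, `start`, `end`,
#'   `strand`, `length_bp`.
#' @export
read_gene_models <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  out <- data.frame(
    gene_id = character(0), chrom = character(0),
    start = integer(0), end = integer(0), strand = character(0),
    length_bp = integer(0), stringsAsFactors = FALSE
  )
  if (length(idx) == 0L) return(out)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- strsplit(lines[i], "\t| +")[[1]]
    if (length(f) < 6L)
      stop(sprintf("malformed BED line %d: fewer than 6 fields", i))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end))
      stop(sprintf("malformed BED line %d: non-integer coordinates", i))
    if (end <= start)
      stop(sprintf("malformed BED line %d: end <= start", i))
    if (!f[6] %in% c("+", "-"))
      stop(sprintf("malformed BED line %d: strand must be + or -", i))
    rows[[k]] <- data.frame(
      gene_id = f[4], chrom = f[1], start = start, end = end,
      strand = f[6], length_bp = end - start, stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  dup <- out$gene_id[duplicated(out$gene_id)]
  if (length(dup))
    stop("duplicate gene_id in BED file: ", paste(unique(dup), collapse = ", "))
  rownames(out) <- NULL
  out
}

#' Read CpG-island intervals from a BED file
#'
#' Only the first three columns are used; coordinates stay 0-based half-open.
#'
#' @param path Path to a BED3+ file.
#' @return A data.frame with columns `chrom`, `start`, `end`.
#' @export
read_cpg_islands <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  rows <- lapply(idx, function(i) {
    f <- strsplit(lines[i], "\t| +")[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed BED line %d: fewer than 3 fields", i))
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end) || end <= start)
      stop(sprintf("malformed BED line %d: bad interval", i))
    data.frame(chrom = f[1], start = start, end = end,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

## Canonical base order used for every pileup matrix in the package.
PILEUP_BASES <- c("A", "C", "G", "T")

empty_pileup <- function(length_bp, gene_id = NULL) {
  m <- matrix(0L, nrow = length_bp, ncol = 4L,
              dimnames = list(NULL, PILEUP_BASES))
  attr(m, "gene_id") <- gene_id
  m
}

#' Read a per-gene pileup from a BAM file or a pileup TSV
#'
#' Returns per-position base counts for one gene, in gene-local 0-based
#' coordinates, as an integer matrix with `length_bp` rows and columns
#' A, C, G, T. Zero-depth positions are included as all-zero rows. For BAM
#' input, only aligned match/mismatch bases are counted: inserted bases are
#' skipped and deleted reference positions contribute no count; reads
#' overlapping the gene boundary are clipped to the gene interval; base and
#' mapping quality are ignored. A gene with no aligned reads yields an
#' all-zero pileup, not an error.
#'
#' @param path Path to a coordinate-sorted, indexed BAM file or to a pileup
#'   TSV with columns `gene_id`, `position`, `nA`, `nC`, `nG`, `nT`
#'   (positions 0-based, gene-local).
#' @param gene One row of a gene-model table (see [read_gene_models()]).
#' @param format `"auto"` (by file extension), `"bam"`, or `"tsv"`.
#' @return Integer matrix `length_bp x 4` with a `gene_id` attribute.
#' @export
read_pileup <- function(path, gene, format = c("auto", "bam", "tsv")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam" else "tsv"
  }
  if (format == "bam") pileup_from_bam(path, gene) else pileup_from_tsv(path, gene)
}

pileup_from_bam <- function(path, gene) {
  L <- gene$length_bp
  which <- GenomicRanges_region(gene$chrom, gene$start, gene$end)
  pp <- Rsamtools::PileupParam(
    max_depth = 250000L,
    min_base_quality = 0L, min_mapq = 0L, min_nucleotide_depth = 1L,
    distinguish_strands = FALSE, distinguish_nucleotides = TRUE,
    ignore_query_Ns = TRUE,
    include_deletions = FALSE, include_insertions = FALSE
  )
  sbp <- Rsamtools::ScanBamParam(which = which)
  res <- Rsamtools::pileup(path, scanBamParam = sbp, pileupParam = pp)
  m <- empty_pileup(L, gene$gene_id)
  if (nrow(res)) {
    res <- res[res$nucleotide %in% PILEUP_BASES, , drop = FALSE]
    offs <- res$pos - 1L - gene$start          # back to 0-based gene-local
    ok <- offs >= 0L & offs < L
    res <- res[ok, , drop = FALSE]
    offs <- offs[ok]
    for (b in PILEUP_BASES) {
      sel <- res$nucleotide == b
      if (any(sel)) {
        cnt <- tapply(res$count[sel], offs[sel], sum)
        m[as.integer(names(cnt)) + 1L, b] <-
          m[as.integer(names(cnt)) + 1L, b] + as.integer(cnt)
      }
    }
  }
  m
}

## IRanges interval for the Rsamtools boundary (converts to 1-based closed).
GenomicRanges_region <- function(chrom, start0, end0) {
  GenomicRanges::GRanges(seqnames = chrom,
                         ranges = IRanges::IRanges(start = start0 + 1L,
                                                   end = end0))
}

pileup_from_tsv <- function(path, gene) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "position", "nA", "nC", "nG", "nT")
  if (!all(need %in% names(tab)))
    stop("pileup TSV must have columns: ", paste(need, collapse = ", "))
  tab <- tab[tab$gene_id == gene$gene_id, , drop = FALSE]
  L <- gene$length_bp
  m <- empty_pileup(L, gene$gene_id)
  if (nrow(tab) == 0L) return(m)
  if (any(tab$position < 0L | tab$position >= L))
    stop(sprintf("pileup position out of [0, %d) for gene %s", L, gene$gene_id))
  if (anyDuplicated(tab$position))
    stop("duplicated pileup position for gene ", gene$gene_id)
  idx <- tab$position + 1L
  m[idx, "A"] <- as.integer(tab$nA)
  m[idx, "C"] <- as.integer(tab$nC)
  m[idx, "G"] <- as.integer(tab$nG)
  m[idx, "T"] <- as.integer(tab$nT)
  if (any(m < 0L)) stop("negative count in pileup TSV")
  m
}

#' Write per-gene pileups to a TSV
#'
#' Inverse of the TSV branch of [read_pileup()]. Zero-depth rows are
#' written too, so the round trip is exact.
#'
#' @param pileups Named list of pileup matrices (names are gene ids).
#' @param path Output path.
#' @export
write_pileup_tsv <- function(pileups, path) {
  stopifnot(!is.null(names(pileups)))
  tabs <- lapply(names(pileups), function(g) {
    m <- pileups[[g]]
    data.frame(gene_id = g, position = seq_len(nrow(m)) - 1L,
               nA = m[, "A"], nC = m[, "C"], nG = m[, "G"], nT = m[, "T"],
               stringsAsFactors = FALSE)
  })
  write_table_tsv(do.call(rbind, tabs), path)
}

#' Write consensus sequences to FASTA
#'
#' Headers carry the gene id only.
#'
#' @param consensus Named character vector of sequences over A,C,G,T,N, or a
#'   list of consensus objects from [call_consensus()].
#' @param path Output path.
#' @export
write_consensus_fasta <- function(consensus, path) {
  if (is.list(consensus) && !is.null(consensus[[1]]$seq)) {
    seqs <- vapply(consensus, function(x) x$seq, character(1))
    names(seqs) <- vapply(consensus, function(x) x$gene_id, character(1))
    consensus <- seqs
  }
  stopifnot(is.character(consensus), !is.null(names(consensus)))
  set <- Biostrings::DNAStringSet(consensus)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a FASTA file as a named character vector
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, names from the FASTA headers.
#' @export
read_fasta_seqs <- function(path) {
  set <- Biostrings::readDNAStringSet(path)
  out <- as.character(set)
  names(out) <- sub("\\s.*$", "", names(set))
  out
}

#' Write / read a tab-delimited table
#'
#' TSV with a header row; missing values (NA/NaN) written as "NA" and read
#' back as missing, so tables round-trip.
#'
#' @param x A data.frame (or matrix, coerced).
#' @param path File path.
#' @export
write_table_tsv <- function(x, path) {
  x <- as.data.frame(x)
  for (j in seq_along(x)) {
    if (is.numeric(x[[j]])) x[[j]][is.nan(x[[j]])] <- NA
  }
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", na.strings = "NA",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
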