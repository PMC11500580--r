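# Brute-force oracles and fixture builders shared across the suite.
# Oracles follow the definitions directly (explicit loops, no shared code
# with the implementation paths they check).

BASES <- c("A", "C", "G", "T")

random_dna <- function(n, alphabet = BASES) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

revcomp <- function(s) {
  # independent of Biostrings on purpose
  comp <- chartr("ACGTN", "TGCAN", s)
  paste(rev(strsplit(comp, "")[[1]]), collapse = "")
}

# consensus: argmax base whose fraction reaches num/den of depth, else N
oracle_call_base <- function(counts, num = 51L, den = 100L) {
  depth <- sum(counts)
  if (depth == 0) return("N")
  best <- "N"
  for (b in names(counts)) {
    if (counts[[b]] * den >= depth * num) best <- b
  }
  best
}

# position-by-position substitution count
oracle_count_subs <- function(ref, cons) {
  r <- strsplit(ref, "")[[1]]
  s <- strsplit(cons, "")[[1]]
  classes <- list()
  n_to_N <- 0L
  at <- 0L
  cg <- 0L
  for (i in seq_along(r)) {
    if (r[i] == s[i]) next
    if (s[i] == "N") {
      n_to_N <- n_to_N + 1L
    } else {
      k <- paste0(r[i], ">", s[i])
      classes[[k]] <- (classes[[k]] %||% 0L) + 1L
      if (r[i] %in% c("A", "T") && s[i] %in% c("C", "G")) at <- at + 1L
      if (r[i] %in% c("C", "G") && s[i] %in% c("A", "T")) cg <- cg + 1L
    }
  }
  list(classes = classes, n_to_N = n_to_N, at = at, cg = cg,
       n_sub = sum(unlist(classes)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# textbook step-up BH, explicit loops
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  for (i in seq_len(n)) {
    m <- Inf
    for (j in i:n) m <- min(m, p[o[j]] * n / j)
    q[o[i]] <- min(m, 1)
  }
  q
}

# per-base membership overlap of an island with a gene window
oracle_overlaps_window <- function(isl_start, isl_end, win_start, win_end) {
  any(seq(isl_start, isl_end - 1L) %in% seq(win_start, win_end - 1L))
}

# expected pileup from a list of simple reads; each read is
# list(pos = 0-based leftmost ref pos, cigar = list of c(op, len), seq)
# M consumes both, I/S consume query only, D/N consume reference only
oracle_pileup_from_reads <- function(reads, gene_start, gene_len) {
  m <- matrix(0L, nrow = gene_len, ncol = 4L, dimnames = list(NULL, BASES))
  for (rd in reads) {
    rp <- rd$pos
    qp <- 1L
    q <- strsplit(rd$seq, "")[[1]]
    for (op in rd$cigar) {
      len <- as.integer(op[2])
      if (op[1] %in% c("M", "=", "X")) {
        for (k in seq_len(len)) {
          off <- rp - gene_start
          if (off >= 0L && off < gene_len && q[qp] %in% BASES)
            m[off + 1L, q[qp]] <- m[off + 1L, q[qp]] + 1L
          rp <- rp + 1L
          qp <- qp + 1L
        }
      } else if (op[1] %in% c("I", "S")) {
        qp <- qp + len
      } else if (op[1] %in% c("D", "N")) {
        rp <- rp + len
      }
    }
  }
  m
}

cigar_string <- function(cigar) {
  paste(vapply(cigar, function(op) paste0(op[2], op[1]), character(1)),
        collapse = "")
}

# write reads to a SAM text file and convert to sorted+indexed BAM
make_bam_fixture <- function(reads, chrom = "chrT", chrlen = 10000L) {
  sam <- tempfile(fileext = ".sam")
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrlen))
  recs <- vapply(seq_along(reads), function(i) {
    rd <- reads[[i]]
    paste(sprintf("r%03d", i), 0, chrom, rd$pos + 1L, 60,
          cigar_string(rd$cigar), "*", 0, 0, rd$seq,
          strrep("I", nchar(rd$seq)), sep = "\t")
  }, character(1))
  writeLines(c(hdr, recs), sam)
  bam <- tempfile()
  out <- Rsamtools::asBam(sam, destination = bam, overwrite = TRUE,
                          indexDestination = TRUE)
  out
}

gene_row <- function(gene_id = "gA", chrom = "chrT", start = 0L,
                     end = 100L, strand = "+") {
  data.frame(gene_id = gene_id, chrom = chrom, start = start, end = end,
             strand = strand, length_bp = end - start,
             stringsAsFactors = FALSE)
}

# all permutations of a vector (small n)
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
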