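## CpG-island intersection with gene bodies +/- flanks, metagene binning,
## and spline smoothing of the positional profile.
##
## All interval arithmetic is 0-based half-open. The metagene layout is
## 20 fixed 100-bp bins upstream, 100 scaled body bins, 20 fixed 100-bp
## bins downstream (defaults; configurable). Minus-strand genes are flipped
## so that "upstream" is always the 5' flank.

#' CpG islands overlapping a gene window
#'
#' Returns the islands with at least 1 bp overlap with the window
#' `[start - flank_bp, end + flank_bp)` on the gene's chromosome, clipped
#' to that window.
#'
#' @param islands A data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param gene One row of a gene-model table.
#' @param flank_bp Flank width in bp (default 2000).
#' @return The overlapping islands, clipped, same columns as `islands`.
#' @export
islands_overlapping_gene <- function(islands, gene, flank_bp = 2000L) {
  if (flank_bp < 0) stop("flank_bp must be non-negative")
  win_start <- gene$start - flank_bp
  win_end <- gene$end + flank_bp
  onchr <- islands[islands$chrom == gene$chrom, , drop = FALSE]
  if (!nrow(onchr))
    return(onchr)
  ## half-open intervals -> 1-based closed for IRanges
  q <- IRanges::IRanges(start = onchr$start + 1L, end = onchr$end)
  s <- IRanges::IRanges(start = win_start + 1L, end = win_end)
  hits <- IRanges::findOverlaps(q, s, minoverlap = 1L)
  keep <- onchr[S4Vectors::queryHits(hits), , drop = FALSE]
  if (nrow(keep)) {
    keep$start <- pmax(keep$start, win_start)
    keep$end <- pmin(keep$end, win_end)
  }
  rownames(keep) <- NULL
  keep
}

## Bin boundaries in window-local coordinates (plus orientation).
## Returns a numeric vector of length n_bins + 1.
metagene_boundaries <- function(length_bp, flank_bp, body_bins, flank_bin_bp) {
  if (flank_bp %% flank_bin_bp != 0)
    stop("flank_bp must be a multiple of flank_bin_bp")
  n_flank <- flank_bp %/% flank_bin_bp
  up <- seq(0, flank_bp, by = flank_bin_bp)
  body <- flank_bp + length_bp * seq_len(body_bins) / body_bins
  down <- flank_bp + length_bp + seq_len(n_flank) * flank_bin_bp
  c(up, body, down)
}

#' Raw metagene profile of island coverage over a gene group
#'
#' For each gene, islands (already clipped to the gene window, see
#' [islands_overlapping_gene()]) are converted to window-local coordinates
#' and their bp coverage is distributed over the bins; body bins use
#' fractional overlap so genes shorter than `body_bins` still bin
#' correctly. Minus-strand genes are mirrored. `raw_count` is the mean
#' coverage (bp of island per bin) across all genes of the group; genes
#' with no island contribute zero coverage but stay in the denominator.
#'
#' @param islands_by_gene List, parallel to the rows of `genes`, of clipped
#'   island data.frames.
#' @param genes Gene-model table (one row per gene of the group).
#' @param body_bins Number of scaled gene-body bins (default 100).
#' @param flank_bin_bp Width of the fixed flank bins in bp (default 100).
#' @param flank_bp Flank width in bp (default 2000).
#' @param mode `"coverage"` (bp of island per bin, default) or
#'   `"midpoint"` (count of clipped-island midpoints per bin).
#' @param group_label Label stored on the profile.
#' @return A list of class `metagene_profile`: `group_label`, `bins`
#'   (data.frame `bin_index`, `region`, `raw_count`, `smoothed`),
#'   `n_genes`, `n_genes_with_island`, and the binning parameters.
#' @export
metagene_bin <- function(islands_by_gene, genes, body_bins = 100L,
                         flank_bin_bp = 100L, flank_bp = 2000L,
                         mode = c("coverage", "midpoint"),
                         group_label = "group") {
  mode <- match.arg(mode)
  if (!nrow(genes)) stop("genes must be non-empty")
  stopifnot(length(islands_by_gene) == nrow(genes))
  n_flank <- flank_bp %/% flank_bin_bp
  n_bins <- 2L * n_flank + body_bins
  acc <- numeric(n_bins)
  n_with <- 0L
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    isl <- islands_by_gene[[i]]
    if (is.null(isl) || !nrow(isl)) next
    n_with <- n_with + 1L
    bounds <- metagene_boundaries(g$length_bp, flank_bp, body_bins,
                                  flank_bin_bp)
    lo <- bounds[-length(bounds)]
    hi <- bounds[-1L]
    v <- numeric(n_bins)
    win_start <- g$start - flank_bp
    for (k in seq_len(nrow(isl))) {
      a <- isl$start[k] - win_start
      b <- isl$end[k] - win_start
      if (mode == "coverage") {
        v <- v + pmax(0, pmin(b, hi) - pmax(a, lo))
      } else {
        m <- (a + b) / 2
        j <- findInterval(m, bounds, rightmost.closed = FALSE)
        j <- min(max(j, 1L), n_bins)
        v[j] <- v[j] + 1
      }
    }
    if (g$strand == "-") v <- rev(v)
    acc <- acc + v
  }
  region <- c(rep("upstream", n_flank), rep("body", body_bins),
              rep("downstream", n_flank))
  structure(
    list(group_label = group_label,
         bins = data.frame(bin_index = seq_len(n_bins), region = region,
                           raw_count = acc / nrow(genes),
                           smoothed = NA_real_, stringsAsFactors = FALSE),
         n_genes = nrow(genes), n_genes_with_island = n_with,
         body_bins = body_bins, flank_bin_bp = flank_bin_bp,
         flank_bp = flank_bp, mode = mode),
    class = "metagene_profile"
  )
}

#' Smooth a metagene profile with an RSS-budget smoothing spline
#'
#' Fits a cubic smoothing spline over bin index, choosing the smoothest fit
#' whose residual sum of squares does not exceed `smoothing_factor` (the
#' budget semantics of a classical univariate smoothing spline). A factor
#' of 0 returns the interpolant, i.e. the raw values at the bins. Raw
#' values are never altered. Profiles with fewer than 4 bins are returned
#' unsmoothed with a `smoothing_warning` flag.
#'
#' @param profile A `metagene_profile`.
#' @param smoothing_factor Non-negative residual-sum-of-squares budget
#'   (default 5).
#' @return The profile with its `bins$smoothed` column filled.
#' @export
smooth_profile <- function(profile, smoothing_factor = 5) {
  stopifnot(inherits(profile, "metagene_profile"))
  if (smoothing_factor < 0) stop("smoothing_factor must be >= 0")
  y <- profile$bins$raw_count
  n <- length(y)
  if (n < 4L) {
    profile$bins$smoothed <- y
    profile$smoothing_warning <- TRUE
    warning("fewer than 4 bins: returning raw profile unsmoothed")
    return(profile)
  }
  x <- seq_len(n)
  if (smoothing_factor == 0 || stats::var(y) == 0) {
    ## interpolation limit / constant fixed point
    profile$bins$smoothed <- y
    return(profile)
  }
  rss_at <- function(spar) {
    fit <- suppressWarnings(
      stats::smooth.spline(x, y, spar = spar, all.knots = TRUE,
                           keep.data = FALSE, cv = FALSE))
    sum((stats::predict(fit, x)$y - y)^2)
  }
  lo <- -1.5; hi <- 2.5
  if (rss_at(hi) <= smoothing_factor) {
    best <- hi
  } else if (rss_at(lo) > smoothing_factor) {
    best <- lo   # even the roughest spline overshoots the budget;
                 # take the closest available fit
  } else {
    for (it in 1:40) {         # monotone RSS(spar): bisection
      mid <- (lo + hi) / 2
      if (rss_at(mid) <= smoothing_factor) lo <- mid else hi <- mid
    }
    best <- lo
  }
  fit <- suppressWarnings(
    stats::smooth.spline(x, y, spar = best, all.knots = TRUE,
                         keep.data = FALSE, cv = FALSE))
  profile$bins$smoothed <- stats::predict(fit, x)$y
  profile
}

#' Full metagene profile for one gene group
#'
#' Convenience wrapper: per-gene island overlap, binning, then smoothing.
#'
#' @param islands Island table (`chrom`, `start`, `end`).
#' @param genes Gene-model table for the group.
#' @param flank_bp,body_bins,flank_bin_bp,mode Passed through.
#' @param smoothing_factor Passed to [smooth_profile()].
#' @param group_label Label stored on the profile.
#' @return A smoothed `metagene_profile`.
#' @export
group_metagene_profile <- function(islands, genes, flank_bp = 2000L,
                                   body_bins = 100L, flank_bin_bp = 100L,
                                   mode = "coverage", smoothing_factor = 5,
                                   group_label = "group") {
  islands_by_gene <- lapply(seq_len(nrow(genes)), function(i) {
    islands_overlapping_gene(islands, genes[i, ], flank_bp = flank_bp)
  })
  prof <- metagene_bin(islands_by_gene, genes, body_bins = body_bins,
                       flank_bin_bp = flank_bin_bp, flank_bp = flank_bp,
                       mode = mode, group_label = group_label)
  smooth_profile(prof, smoothing_factor = smoothing_factor)
}
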