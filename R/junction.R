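#' Bin coverage around a 3' splice junction
#'
#' Extracts the 1 kb window centered on a 3' intron-exon junction as 100
#' 10-bp bins, oriented 5'->3' in transcript space: bins 1-50 are the intron
#' side, bins 51-100 the exon side. Minus-strand junctions are reversed so
#' orientation is consistent.
#'
#' @param track a [coverage_track()].
#' @param chrom contig of the junction.
#' @param pos 3' splice-site position (0-based bp).
#' @param strand `"+"` or `"-"`.
#' @param flank half-window in bp (default 500).
#' @param bin_bp bin width in bp (default 10).
#' @return Numeric vector of `2 * flank / bin_bp` bin counts, or `NULL`
#'   (with a message) when the window runs off the contig.
#' @export
bin_junction <- function(track, chrom, pos, strand = "+", flank = 500,
                         bin_bp = 10) {
  clen <- contig_lengths(track)[chrom]
  if (is.na(clen)) stop("contig not present in track: ", chrom)
  if (pos - flank < 0 || pos + flank > clen) {
    message(sprintf("junction %s:%d skipped: window off contig end", chrom, pos))
    return(NULL)
  }
  edges <- seq(pos - flank, pos + flank, by = bin_bp)
  cum <- bin_integral(track$bins[[chrom]], track$bin_width, edges)
  counts <- diff(cum)
  if (strand == "-") counts <- rev(counts)
  counts
}

#' U2 snRNP residency score at a 3' splice junction
#'
#' Poisson enrichment of the 5 intron-side bins adjacent to the 3' splice
#' site (bins 46-50 in transcript orientation). The background rate per bin
#' is the maximum of the intron-side window mean (lambda_up), the exon-side
#' window mean (lambda_down), and the global mean bin count over all
#' junctions (lambda_whole); each of the 5 bins gets the strict Poisson tail
#' `P(X > k)` and the residency score is `-log10(min p)`.
#'
#' @param bins 100-bin vector from [bin_junction()] (transcript-oriented).
#' @param global_mean_bin mean bin count over the full window across all
#'   junctions.
#' @return List with `lambda_up`, `lambda_down`, `lambda_whole`, `lambda`,
#'   `p` (the 5 per-bin p-values) and `score`.
#' @export
residency_score <- function(bins, global_mean_bin) {
  stopifnot(length(bins) %% 2 == 0, length(bins) >= 10)
  half <- length(bins) / 2
  lam_up <- mean(bins[seq_len(half)])
  lam_down <- mean(bins[half + seq_len(half)])
  lam <- max(lam_up, lam_down, global_mean_bin)
  k <- bins[(half - 4):half]
  if (lam == 0) {
    # no background signal: zero counts carry no evidence (p = 1); positive
    # counts are infinitely enriched, capped at the smallest representable p
    p <- ifelse(k > 0, .Machine$double.xmin, 1)
    if (any(k > 0)) message("residency p underflow at lambda = 0: score capped")
  } else {
    p <- poisson_tail(k, lam)
    if (any(p == 0)) {
      p[p == 0] <- .Machine$double.xmin
      message("residency p underflow: score capped at -log10(double.xmin)")
    }
  }
  list(lambda_up = lam_up, lambda_down = lam_down,
       lambda_whole = global_mean_bin, lambda = lam, p = p,
       score = -log10(min(p)))
}

#' Residency scores for a junction-by-bin count matrix
#'
#' Convenience wrapper applying [residency_score()] to every row of a
#' 100-bin matrix (e.g. from [simulate_junction_bins()]), with
#' `lambda_whole` computed as the grand mean bin count over all junctions.
#'
#' @param bin_matrix numeric matrix, junctions x bins (transcript-oriented).
#' @return `data.frame` with `junction`, `lambda`, `min_p`, `score`.
#' @export
residency_scores <- function(bin_matrix) {
  stopifnot(is.matrix(bin_matrix))
  gm <- mean(bin_matrix)
  half <- ncol(bin_matrix) / 2
  lam_up <- rowMeans(bin_matrix[, seq_len(half), drop = FALSE])
  lam_down <- rowMeans(bin_matrix[, half + seq_len(half), drop = FALSE])
  lam <- pmax(lam_up, lam_down, gm)
  k5 <- bin_matrix[, (half - 4):half, drop = FALSE]
  p5 <- matrix(poisson_tail(as.vector(k5), rep(lam, times = 5)),
               nrow = nrow(bin_matrix))
  p5[k5 == 0 & matrix(lam, nrow(p5), 5) == 0] <- 1
  minp <- pmax(apply(p5, 1, min), .Machine$double.xmin)
  data.frame(junction = if (!is.null(rownames(bin_matrix)))
    rownames(bin_matrix) else as.character(seq_len(nrow(bin_matrix))),
    lambda = lam, min_p = minp, score = -log10(minp),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Quantile normalization of a counts matrix
#'
#' Classic rank-mean quantile normalization across experiments (columns):
#' after normalization every column's sorted value vector is identical; ties
#' receive the average of the reference values of their tied ranks.
#'
#' @param counts numeric matrix, entries x experiments (>= 2 columns).
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2L) stop("at least 2 experiments required")
  ref <- rowMeans(apply(counts, 2, sort))
  out <- apply(counts, 2, function(col) {
    v <- numeric(length(col))
    v[order(col)] <- ref
    # tied input values share the mean reference value of their rank block
    stats::ave(v, col, FUN = mean)
  })
  dimnames(out) <- dimnames(counts)
  out
}

#' Fold enrichment against matched and pooled controls
#'
#' For each entry and experiment, the denominator is the maximum of the
#' matched control value and the mean over all control experiments, plus a
#' pseudocount; fold enrichment is `(value + pseudocount) / denominator`.
#'
#' @param normalized matrix, entries x experiments (quantile-normalized).
#' @param control_map named list mapping experiment column name ->
#'   character vector of its matched control column names (may be empty).
#' @param all_controls character vector of all control column names
#'   (nonempty).
#' @param pseudocount added to numerator and denominator (default 1).
#' @return Matrix of fold enrichments for the non-control experiments.
#' @export
fold_enrichment <- function(normalized, control_map, all_controls,
                            pseudocount = 1) {
  normalized <- as.matrix(normalized)
  if (length(all_controls) == 0L) stop("all-control set must be nonempty")
  if (!all(all_controls %in% colnames(normalized))) {
    stop("control columns absent from matrix")
  }
  ctrl_mean <- rowMeans(normalized[, all_controls, drop = FALSE])
  exps <- setdiff(colnames(normalized), all_controls)
  fe <- sapply(exps, function(e) {
    matched <- control_map[[e]]
    denom <- ctrl_mean
    if (length(matched)) {
      mt <- apply(normalized[, matched, drop = FALSE], 1, max)
      denom <- pmax(mt, ctrl_mean)
    }
    (normalized[, e] + pseudocount) / (denom + pseudocount)
  })
  fe <- matrix(fe, nrow = nrow(normalized),
               dimnames = list(rownames(normalized), exps))
  fe
}
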