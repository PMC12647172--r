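#' Strict upper-tail Poisson probability
#'
#' Computes `P(X > k)` for `X ~ Poisson(lam)` — the strict tail, not
#' `P(X >= k)` which many libraries default to. Stable in log-space for
#' rates up to at least 1e6 and p-values below 1e-300.
#'
#' @param k nonnegative integer count(s).
#' @param lam nonnegative Poisson rate(s).
#' @return Tail probability in `[0, 1]`, vectorized.
#' @export
poisson_tail <- function(k, lam) {
  if (any(!is.finite(k)) || any(k < 0) || any(k != floor(k))) {
    stop("k must be a nonnegative integer")
  }
  if (any(lam < 0)) stop("lam must be nonnegative")
  stats::ppois(k, lam, lower.tail = FALSE)
}

#' Local Poisson background for a gene interval
#'
#' Estimates the expected count over a gene from nested background windows
#' (1 kb, 10 kb, 100 kb by default) centered on the gene midpoint and
#' clipped at contig ends, plus a genome-wide rate. Each window's rate
#' (count / effective width) is scaled by the gene length; the background
#' used downstream is the maximum of the four, which adapts to locally
#' elevated signal the way accessibility peak callers do. By default the
#' gene's own interval is excluded from each window (flanking-only
#' background): including it would let a truly active short gene inflate
#' its own background and mask itself.
#'
#' @param track a [coverage_track()] of read counts.
#' @param gene single-row interval table (or a list with `chrom`, `start`,
#'   `end`).
#' @param windows background window widths in bp.
#' @param include_gene include the gene's own reads and width in the local
#'   windows (default `FALSE`).
#' @return List with `lambda_1k`, `lambda_10k`, `lambda_100k`,
#'   `lambda_genome`, `lambda_max`.
#' @export
local_lambda <- function(track, gene, windows = c(1e3, 1e4, 1e5),
                         include_gene = FALSE) {
  lam <- local_lambda_all(track,
                          genomic_intervals(gene$chrom, gene$start, gene$end,
                                            id = "g"),
                          windows, include_gene = include_gene)
  as.list(lam[1, ])
}

# Vectorized backbone: one row per gene, columns lambda_* and lambda_max.
# Windows are centered on the gene midpoint and clipped at contig ends; by
# default the gene's own interval is excluded from both the window count and
# the effective width, so a truly active short gene cannot inflate its own
# background (flanking-only local background).
local_lambda_all <- function(track, genes, windows = c(1e3, 1e4, 1e5),
                             include_gene = FALSE) {
  clen <- contig_lengths(track)
  glen <- genes$end - genes$start
  mid <- (genes$start + genes$end) / 2
  gene_cnt <- numeric(nrow(genes))
  for (chrom in unique(genes$chrom)) {
    sel <- genes$chrom == chrom
    b <- track$bins[[chrom]]
    if (is.null(b)) stop("contig not present in track: ", chrom)
    gene_cnt[sel] <- bin_integral(b, track$bin_width, genes$end[sel]) -
      bin_integral(b, track$bin_width, genes$start[sel])
  }
  out <- matrix(NA_real_, nrow(genes), length(windows) + 1L)
  for (wi in seq_along(windows)) {
    w <- windows[wi]
    lo <- pmax(mid - w / 2, 0)
    hi <- pmin(mid + w / 2, clen[genes$chrom])
    eff <- hi - lo
    cnt <- numeric(nrow(genes))
    for (chrom in unique(genes$chrom)) {
      sel <- genes$chrom == chrom
      b <- track$bins[[chrom]]
      cnt[sel] <- bin_integral(b, track$bin_width, hi[sel]) -
        bin_integral(b, track$bin_width, lo[sel])
    }
    if (!include_gene) {
      ov <- pmax(pmin(hi, genes$end) - pmax(lo, genes$start), 0)
      cnt <- cnt - gene_cnt * (ov / glen)
      eff <- eff - ov
    }
    if (any(eff <= 0)) stop("zero-width effective background window")
    out[, wi] <- cnt / eff * glen
  }
  out[, length(windows) + 1L] <- track$total_reads / sum(clen) * glen
  colnames(out) <- c(paste0("lambda_", c("1k", "10k", "100k")[seq_along(windows)]),
                     "lambda_genome")
  cbind(out, lambda_max = apply(out, 1, max))
}

#' Downsample a count track to a target depth
#'
#' Binomial thinning of each bin with probability `target_total /
#' total_reads`, matching the depth-equalization used before Poisson
#' significance calling (the reference pipeline scales every sample to
#' 250 million reads). Tracks already at or below the target are returned
#' unchanged with a warning.
#'
#' @param track a [coverage_track()] with integer counts.
#' @param target_total target total read count.
#' @param seed RNG seed (thinning is reproducible).
#' @return A thinned [coverage_track()].
#' @export
downsample_track <- function(track, target_total = 2.5e8, seed = 1L) {
  if (target_total <= 0) stop("target_total must be positive")
  if (track$total_reads <= target_total) {
    if (track$total_reads < target_total) {
      warning("track total below target; returned unchanged")
    }
    return(track)
  }
  p <- target_total / track$total_reads
  with_subseed(seed, "downsample_track", {
    bins <- lapply(track$bins, function(b) stats::rbinom(length(b), b, p))
    coverage_track(bins, track$bin_width)
  })
}

#' Call per-gene activity from accessibility coverage
#'
#' For every (gene, sample) pair, the observed count `k` over the gene is
#' compared with the maximum local-background expectation via the strict
#' Poisson tail `P(X > k)`; p-values are then adjusted by Benjamini-Hochberg
#' globally (over all pairs jointly, the default) or per sample. Per-sample
#' states used downstream for survival are `confident_ON` (adjusted p <
#' `alpha`), `confident_OFF` (raw p > `off_p`), otherwise `indeterminate`.
#'
#' @param tracks named list of [coverage_track()]s, one per sample.
#' @param genes interval table of gene coordinates.
#' @param windows background window widths passed to [local_lambda()].
#' @param alpha adjusted-p threshold for `confident_ON` (default 0.05).
#' @param off_p raw-p threshold above which a gene is `confident_OFF`
#'   (default 0.5).
#' @param global if `TRUE` (default) BH runs once over all (gene, sample)
#'   pairs; if `FALSE`, per sample.
#' @param include_gene passed to [local_lambda()] (default `FALSE`:
#'   flanking-only background).
#' @return `data.frame` with columns `gene`, `sample`, `k`, `lambda_max`,
#'   `p_raw`, `p_adj`, `state`.
#' @export
call_activity <- function(tracks, genes, windows = c(1e3, 1e4, 1e5),
                          alpha = 0.05, off_p = 0.5, global = TRUE,
                          include_gene = FALSE) {
  stopifnot(length(tracks) >= 1L, nrow(genes) >= 1L)
  if (is.null(names(tracks))) names(tracks) <- paste0("sample", seq_along(tracks))
  res <- lapply(names(tracks), function(s) {
    lam <- local_lambda_all(tracks[[s]], genes, windows,
                            include_gene = include_gene)
    k <- extract_counts(tracks[[s]], genes)
    data.frame(gene = genes$id, sample = s, k = as.numeric(k),
               lambda_max = lam[, "lambda_max"],
               p_raw = poisson_tail(as.numeric(k), lam[, "lambda_max"]),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  out <- do.call(rbind, res)
  if (global) {
    out$p_adj <- stats::p.adjust(out$p_raw, method = "BH")
  } else {
    out$p_adj <- stats::ave(out$p_raw, out$sample,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  }
  out$state <- ifelse(out$p_adj < alpha, "confident_ON",
                      ifelse(out$p_raw > off_p, "confident_OFF",
                             "indeterminate"))
  out
}

#' Classify genes as always-ON, ON/OFF, or OFF across cancer subtypes
#'
#' Applies the median-p rule set: genes shorter than 1000 bp whose global
#' median raw p is below 0.05 are `always_ON`; of the rest, genes with a
#' median raw p below 0.05 in at least one subtype are `ON_OFF`; all others
#' are `OFF`.
#'
#' @param calls output of [call_activity()].
#' @param genes interval table carrying gene lengths.
#' @param subtypes named character vector mapping sample -> subtype.
#' @param alpha median-p threshold (default 0.05).
#' @param short_gene_bp length cutoff for the always-ON rule (default 1000).
#' @return `data.frame` with `gene`, `length`, `median_p`, `class`, plus a
#'   `"subtype_median_p"` attribute (gene x subtype matrix).
#' @export
classify_gene_states <- function(calls, genes, subtypes, alpha = 0.05,
                                 short_gene_bp = 1000) {
  unmapped <- setdiff(unique(calls$sample), names(subtypes))
  if (length(unmapped)) stop("samples without subtype: ",
                             paste(unmapped, collapse = ", "))
  calls$subtype <- subtypes[calls$sample]
  empty <- setdiff(unique(subtypes), unique(calls$subtype))
  if (length(empty)) warning("subtype(s) without samples excluded: ",
                             paste(empty, collapse = ", "))
  med <- tapply(calls$p_raw, list(calls$gene, calls$subtype), stats::median)
  global_med <- tapply(calls$p_raw, calls$gene, stats::median)
  glen <- stats::setNames(genes$length, genes$id)[rownames(med)]
  any_on <- apply(med < alpha, 1, any, na.rm = TRUE)
  class <- ifelse(glen < short_gene_bp & global_med[rownames(med)] < alpha,
                  "always_ON", ifelse(any_on, "ON_OFF", "OFF"))
  out <- data.frame(gene = rownames(med), length = as.numeric(glen),
                    median_p = as.numeric(global_med[rownames(med)]),
                    class = as.character(class),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "subtype_median_p") <- med
  out
}
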