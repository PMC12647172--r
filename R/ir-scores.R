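#' Filter introns on expression and flanking-coverage quality
#'
#' Retains an intron only if gene expression exceeds CPM 1 in every sample
#' and read support over both flanking exons exceeds 10 in every sample,
#' taken individually (strict inequalities).
#'
#' @param records data frame in the `ir` schema (see [read_table()]) with
#'   per-sample `cpm_`, `flank5_`, `flank3_` column groups.
#' @param min_cpm,min_flank filter floors (defaults 1 and 10).
#' @return List with `retained` (passing rows) and `rejected` (failing rows
#'   plus a `reason` column naming the first failed criterion).
#' @export
filter_introns <- function(records, min_cpm = 1, min_flank = 10) {
  cpm_cols <- grep("^cpm_", names(records), value = TRUE)
  f5_cols <- grep("^flank5_", names(records), value = TRUE)
  f3_cols <- grep("^flank3_", names(records), value = TRUE)
  if (!length(cpm_cols) || !length(f5_cols) || !length(f3_cols)) {
    stop("records must carry cpm_, flank5_ and flank3_ columns per sample")
  }
  ok_cpm <- rowSums(records[cpm_cols] <= min_cpm) == 0L
  ok_f5 <- rowSums(records[f5_cols] <= min_flank) == 0L
  ok_f3 <- rowSums(records[f3_cols] <= min_flank) == 0L
  keep <- ok_cpm & ok_f5 & ok_f3
  rejected <- records[!keep, , drop = FALSE]
  if (nrow(rejected)) {
    rejected$reason <- ifelse(!ok_cpm[!keep], "CPM",
                              ifelse(!ok_f5[!keep], "flank5", "flank3"))
  } else {
    rejected$reason <- character(0)
  }
  list(retained = records[keep, , drop = FALSE], rejected = rejected)
}

# Monte-Carlo null of the control-as-suspect Dixon Q statistic at n = 4
# (1 control + 3 treatments), drawn i.i.d. Gaussian. Cached per
# (mc_reps, seed); returned sorted.
.qnull_cache <- new.env(parent = emptyenv())

q_null_draws <- function(mc_reps, seed) {
  key <- paste(mc_reps, seed, sep = "_")
  if (!is.null(.qnull_cache[[key]])) return(.qnull_cache[[key]])
  draws <- with_subseed(seed, "q_test_null", {
    ctrl <- stats::rnorm(mc_reps)
    trt <- matrix(stats::rnorm(3 * mc_reps), mc_reps, 3)
    dixon_q(ctrl, trt)
  })
  .qnull_cache[[key]] <- sort(draws)
  .qnull_cache[[key]]
}

# Vectorized Dixon Q with the control as the suspect value: gap between the
# control and its nearest treatment over the range of all four values; 0 when
# the control does not sit at an extreme (the test asks whether the control
# separates from the treatment distribution) or when the range is degenerate.
dixon_q <- function(ctrl, trt) {
  tmin <- do.call(pmin, as.data.frame(trt))
  tmax <- do.call(pmax, as.data.frame(trt))
  rng <- pmax(ctrl, tmax) - pmin(ctrl, tmin)
  gap <- ifelse(ctrl >= tmax, ctrl - tmax,
                ifelse(ctrl <= tmin, tmin - ctrl, 0))
  ifelse(rng > 0, gap / rng, 0)
}

#' Dixon Q outlier score for one control against three treatment IR ratios
#'
#' Treats the control IR ratio as the suspect value of a Dixon Q test over
#' the pooled four values; the p-value is the Monte-Carlo tail probability of
#' Q under an i.i.d. Gaussian null at n = 4 (add-one smoothed), and the
#' intron IR score is `-log10(p)`. A control lying inside the treatment
#' range, or a degenerate (zero) range, gives Q = 0 and p = 1.
#'
#' @param control_ir numeric vector of control IR ratios (one per intron).
#' @param treatment_irs matrix (introns x 3) of treatment IR ratios.
#' @param mc_reps Monte-Carlo null size (default 1e5).
#' @param seed RNG seed for the null draws.
#' @return `data.frame` with `q_stat`, `p_q`, `score`.
#' @export
q_test_score <- function(control_ir, treatment_irs, mc_reps = 1e5, seed = 1L) {
  if (!is.matrix(treatment_irs)) {
    if (length(treatment_irs) %% 3 != 0) {
      stop("exactly 3 treatment replicates required per intron")
    }
    treatment_irs <- matrix(treatment_irs, ncol = 3)
  }
  if (ncol(treatment_irs) != 3L) {
    stop("exactly 3 treatment replicates required per intron")
  }
  if (length(control_ir) != nrow(treatment_irs)) {
    stop("control and treatment arities disagree")
  }
  vals <- cbind(control_ir, treatment_irs)
  if (any(!is.finite(vals)) || any(vals < 0 | vals > 1)) {
    stop("IR ratios must be finite values in [0, 1]")
  }
  q <- dixon_q(control_ir, treatment_irs)
  nullq <- q_null_draws(mc_reps, seed)
  # number of null draws >= q, via the sorted null
  n_ge <- mc_reps - findInterval(q, nullq, left.open = TRUE)
  p <- empirical_p(n_ge, mc_reps)
  rng <- apply(vals, 1, function(v) max(v) - min(v))
  p[rng == 0] <- 1
  data.frame(q_stat = q, p_q = p, score = -log10(p))
}

#' Collapse overlapping (nested) introns into single entities
#'
#' Introns overlapping on the same contig (e.g. a parent intron and a
#' smaller nested one) are grouped by connected components and each
#' component becomes one intron entity scored by the median of its members'
#' scores. Disjoint introns pass through unchanged. Output is independent of
#' input ordering.
#'
#' @param scores data frame with `intron_id`, `transcript_id`, `chrom`,
#'   `start`, `end`, `score`.
#' @return data frame with one row per entity: `entity_id`,
#'   `transcript_id`, `chrom`, `start`, `end`, `n_members`, `score`.
#' @export
collapse_nested <- function(scores) {
  o <- order(scores$chrom, scores$start, scores$end, scores$intron_id)
  s <- scores[o, , drop = FALSE]
  comp <- integer(nrow(s))
  cid <- 0L
  max_end <- -Inf
  cur_chrom <- ""
  for (i in seq_len(nrow(s))) {
    if (s$chrom[i] != cur_chrom || s$start[i] >= max_end) {
      cid <- cid + 1L
      cur_chrom <- s$chrom[i]
      max_end <- s$end[i]
    } else {
      max_end <- max(max_end, s$end[i])
    }
    comp[i] <- cid
  }
  res <- do.call(rbind, lapply(split(s, comp), function(d) {
    data.frame(entity_id = d$intron_id[1],
               transcript_id = d$transcript_id[1],
               chrom = d$chrom[1], start = min(d$start), end = max(d$end),
               n_members = nrow(d), score = stats::median(d$score),
               stringsAsFactors = FALSE)
  }))
  rownames(res) <- NULL
  res
}

# B null means of size-n draws (without replacement) from a score pool.
null_means <- function(pool, n, B) {
  if (n > length(pool)) stop("draw size exceeds pool size")
  if (n == length(pool)) return(rep(mean(pool), B))
  vapply(seq_len(B), function(i) mean(pool[sample.int(length(pool), n)]), 0)
}

#' Transcript-level intron-retention significance by permutation
#'
#' Compares the mean intron IR score of each transcript against an
#' empirical null of equally many scores drawn (without replacement) from
#' the global score pool, under two frameworks: [1] only introns with
#' positive scores (`-log10(p) > 0`), and [2] all introns including zero
#' scores. Empirical p-values are add-one smoothed, BH-adjusted across
#' transcripts per framework; a transcript is called sensitive when the
#' adjusted p is below `alpha` in both frameworks.
#'
#' @param entity_scores data frame with `transcript_id` and `score` (one row
#'   per intron entity, e.g. from [collapse_nested()]).
#' @param B permutation draws (default 10000).
#' @param seed RNG seed.
#' @param alpha adjusted-p threshold for the sensitive call (default 0.05).
#' @param stat summary of a transcript's scores: `"mean"` (default) or
#'   `"median"`.
#' @return `data.frame` per transcript: `n_introns`, `n_positive`,
#'   `obs_f1`, `obs_f2`, `p_f1`, `p_f2`, `p_adj_f1`, `p_adj_f2`,
#'   `evaluable_f1`, `sensitive`.
#' @export
transcript_significance <- function(entity_scores, B = 10000, seed = 1L,
                                    alpha = 0.05, stat = c("mean", "median")) {
  stat <- match.arg(stat)
  stopifnot(B >= 1)
  sfun <- if (stat == "mean") mean else stats::median
  pool2 <- entity_scores$score
  pool1 <- pool2[pool2 > 0]
  groups <- split(entity_scores$score, entity_scores$transcript_id)
  n2 <- lengths(groups)
  n1 <- vapply(groups, function(g) sum(g > 0), 0L)
  obs2 <- vapply(groups, sfun, 0)
  obs1 <- vapply(groups, function(g) if (any(g > 0)) sfun(g[g > 0]) else NA_real_, 0)
  with_subseed(seed, "transcript_significance", {
    # shared size-matched null draws per framework (marginally identical to
    # per-transcript draws; the null depends only on n)
    nulls1 <- lapply(stats::setNames(nm = unique(n1[n1 > 0])),
                     function(n) sort(null_means_stat(pool1, n, B, sfun)))
    nulls2 <- lapply(stats::setNames(nm = unique(n2)),
                     function(n) sort(null_means_stat(pool2, n, B, sfun)))
    p1 <- rep(NA_real_, length(groups))
    for (i in seq_along(groups)) {
      if (n1[i] > 0) {
        nv <- nulls1[[as.character(n1[i])]]
        p1[i] <- empirical_p(B - findInterval(obs1[i], nv, left.open = TRUE), B)
      }
    }
    p2 <- vapply(seq_along(groups), function(i) {
      nv <- nulls2[[as.character(n2[i])]]
      empirical_p(B - findInterval(obs2[i], nv, left.open = TRUE), B)
    }, 0)
    padj1 <- rep(NA_real_, length(p1))
    padj1[!is.na(p1)] <- stats::p.adjust(p1[!is.na(p1)], "BH")
    padj2 <- stats::p.adjust(p2, "BH")
    data.frame(transcript_id = names(groups), n_introns = as.integer(n2),
               n_positive = as.integer(n1), obs_f1 = obs1, obs_f2 = obs2,
               p_f1 = p1, p_f2 = p2, p_adj_f1 = padj1, p_adj_f2 = padj2,
               evaluable_f1 = n1 > 0,
               sensitive = !is.na(padj1) & padj1 < alpha & padj2 < alpha,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

null_means_stat <- function(pool, n, B, sfun) {
  if (n > length(pool)) stop("draw size exceeds pool size")
  if (n == length(pool)) return(rep(sfun(pool), B))
  vapply(seq_len(B), function(i) sfun(pool[sample.int(length(pool), n)]), 0)
}

#' Transcript delta-IR z-scores from standardized log2 fold-changes
#'
#' Per intron, the delta-IR value is `log2((IR_treatment + eps) /
#' (IR_control + eps))`, standardized against the global delta distribution
#' (z-units). Each transcript's statistic is the mean standardized delta of
#' its introns, compared against a randomization null of equally many
#' standardized values drawn from the global pool.
#'
#' @param ir_control,ir_treatment per-intron IR ratios (treatment typically
#'   the mean over treatment replicates).
#' @param transcript_id transcript grouping per intron.
#' @param B null draws (default 10000).
#' @param seed RNG seed.
#' @param eps pseudocount for the log2 ratio (default 0.01).
#' @return `data.frame` per transcript: `n_introns`, `obs` (mean
#'   standardized delta), `null_mean`, `null_sd`, `z`.
#' @export
delta_ir_z <- function(ir_control, ir_treatment, transcript_id, B = 10000,
                       seed = 1L, eps = 0.01) {
  stopifnot(eps > 0)
  delta <- log2((ir_treatment + eps) / (ir_control + eps))
  g_sd <- stats::sd(delta)
  if (!is.finite(g_sd) || g_sd == 0) {
    stop("degenerate input: global delta-IR standard deviation is zero")
  }
  zvals <- (delta - mean(delta)) / g_sd
  groups <- split(zvals, transcript_id)
  n <- lengths(groups)
  obs <- vapply(groups, mean, 0)
  with_subseed(seed, "delta_ir_z", {
    nulls <- lapply(stats::setNames(nm = unique(n)),
                    function(k) null_means(zvals, k, B))
    nm <- vapply(as.character(n), function(k) mean(nulls[[k]]), 0)
    ns <- vapply(as.character(n), function(k) stats::sd(nulls[[k]]), 0)
    data.frame(transcript_id = names(groups), n_introns = as.integer(n),
               obs = obs, null_mean = nm, null_sd = ns,
               z = (obs - nm) / ns,
               stringsAsFactors = FALSE, row.names = NULL)
  })
}

#' Percent spliced-in from gel band intensities
#'
#' `PSI = intensity_retained / (intensity_retained + intensity_spliced)`.
#'
#' @param intensity_retained,intensity_spliced nonnegative band intensities.
#' @return PSI in `[0, 1]`.
#' @export
gel_psi <- function(intensity_retained, intensity_spliced) {
  if (any(intensity_retained < 0) || any(intensity_spliced < 0)) {
    stop("intensities must be nonnegative")
  }
  tot <- intensity_retained + intensity_spliced
  if (any(tot == 0)) stop("both intensities zero: PSI undefined")
  intensity_retained / tot
}
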