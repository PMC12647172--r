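#' Permutation-test result container
#'
#' Bundles an observed statistic with its empirical null summary: `z =
#' (obs - null mean) / null sd` and the add-one-smoothed empirical p
#' (`(1 + #more-extreme) / (B + 1)`, where "more extreme" means >= / <= on
#' the chosen sidedness), never exactly zero.
#'
#' @param observed observed statistic.
#' @param null_draws numeric vector of B null statistics.
#' @param sided `"greater"`, `"less"` or `"two.sided"`.
#' @return Object of class `perm_result`: `observed`, `B`, `null_mean`,
#'   `null_sd`, `z`, `p`, `sided`, `degenerate`.
#' @export
perm_result <- function(observed, null_draws, sided = c("greater", "less",
                                                        "two.sided")) {
  sided <- match.arg(sided)
  B <- length(null_draws)
  m <- mean(null_draws)
  s <- stats::sd(null_draws)
  degenerate <- !is.finite(s) || s == 0
  z <- if (degenerate) NA_real_ else (observed - m) / s
  n_extreme <- switch(sided,
    greater = sum(null_draws >= observed),
    less = sum(null_draws <= observed),
    two.sided = sum(abs(null_draws - m) >= abs(observed - m)))
  p <- if (degenerate && observed == m) 1 else empirical_p(n_extreme, B)
  structure(list(observed = observed, B = B, null_mean = m, null_sd = s,
                 z = z, p = p, sided = sided, degenerate = degenerate),
            class = "perm_result")
}

#' @export
print.perm_result <- function(x, ...) {
  cat(sprintf("perm_result: obs=%.4g null=%.4g+/-%.4g z=%.3g p=%.4g (%s, B=%d)%s\n",
              x$observed, x$null_mean, x$null_sd,
              ifelse(is.na(x$z), NaN, x$z), x$p, x$sided, x$B,
              if (x$degenerate) " [degenerate null]" else ""))
  invisible(x)
}

#' Gene-set statistic against size-matched random sets
#'
#' Compares a summary statistic (median, mean, or frequency of a binary
#' label) of a gene subset against B random subsets of the same size drawn
#' without replacement from the universe.
#'
#' @param values named numeric vector: statistic per universe element (for
#'   `stat = "frequency"`, 0/1 labels).
#' @param subset ids of the subset (must be names of `values`).
#' @param stat `"median"`, `"mean"` or `"frequency"`.
#' @param B null draws (default 10000).
#' @param seed RNG seed.
#' @param sided test sidedness (default `"greater"`).
#' @return A [perm_result()].
#' @export
set_statistic_z <- function(values, subset, stat = c("median", "mean",
                                                     "frequency"),
                            B = 10000, seed = 1L, sided = "greater") {
  stat <- match.arg(stat)
  stopifnot(B >= 1, length(subset) >= 1)
  if (!all(subset %in% names(values))) stop("subset must lie in the universe")
  sfun <- switch(stat, median = stats::median, mean = mean, frequency = mean)
  obs <- sfun(values[subset])
  n <- length(subset)
  N <- length(values)
  null <- with_subseed(seed, "set_statistic_z", {
    if (n == N) rep(obs, B)
    else vapply(seq_len(B), function(i) sfun(values[sample.int(N, n)]), 0)
  })
  perm_result(obs, null, sided)
}

#' Mean marker correlation against random gene sets
#'
#' Computes the Spearman correlation between a per-sample activity score and
#' each marker gene's expression, summarizes the marker set by the mean
#' correlation, and compares it against B random same-size gene sets.
#'
#' @param activity numeric activity score per sample.
#' @param expression matrix, genes x samples (rownames = gene ids).
#' @param markers gene ids of the marker set.
#' @param B null draws (default 10000).
#' @param seed RNG seed.
#' @param sided sidedness (default `"greater"`).
#' @return List: `result` (a [perm_result()]) and `rho` (per-marker
#'   Spearman correlations).
#' @export
mean_correlation_test <- function(activity, expression, markers, B = 10000,
                                  seed = 1L, sided = "greater") {
  stopifnot(length(activity) >= 3, length(activity) == ncol(expression))
  if (stats::sd(activity) == 0) stop("activity vector is constant")
  if (!all(markers %in% rownames(expression))) {
    stop("marker set must be a subset of expression genes")
  }
  rho_all <- apply(expression, 1, function(g) {
    suppressWarnings(stats::cor(activity, g, method = "spearman"))
  })
  rho_all[!is.finite(rho_all)] <- 0
  res <- set_statistic_z(rho_all, markers, stat = "mean", B = B, seed = seed,
                         sided = sided)
  list(result = res, rho = rho_all[markers])
}

# rank of events in one list: key = -log10(fdr) * |delta_psi|, descending.
event_rank_key <- function(df) -log10(pmax(df$fdr, 1e-300)) * abs(df$delta_psi)

#' Overlap permutation over three ranked splicing-event lists
#'
#' Events are partitioned by (type, direction), ranked within each list by
#' the significance-weighted change `-log10(FDR) * |dPSI|`, and the observed
#' triple top-k intersection is compared at every depth k against B random
#' rank permutations. The selected depth `k*` is the largest k whose
#' empirical p is below `alpha`; the final event set is the triple
#' intersection at `k*` further filtered to FDR < 0.05 (minimum across
#' lists) and maximum absolute dPSI > 0.1 across lists.
#'
#' @param lists list of three event data frames (schema `events`, sharing
#'   `event_id` universes per partition).
#' @param B permutations (default 10000).
#' @param alpha depth-selection p cutoff (default 0.05).
#' @param seed RNG seed.
#' @param k_rule `"largest"` (default): k* = largest significant depth;
#'   `"first_loss"`: depth before significance is first lost.
#' @param fdr_max,min_dpsi final-filter thresholds.
#' @return List of per-partition results, each with `depth` (data frame:
#'   `k`, `observed`, `expected`, `p`), `k_star`, `events` (final filtered
#'   event ids) and `intersection` (ids at `k_star`).
#' @export
overlap_permutation <- function(lists, B = 10000, alpha = 0.05, seed = 1L,
                                k_rule = c("largest", "first_loss"),
                                fdr_max = 0.05, min_dpsi = 0.1) {
  k_rule <- match.arg(k_rule)
  stopifnot(length(lists) == 3)
  lists <- lapply(lists, validate_table, schema = "events")
  parts <- unique(do.call(rbind, lapply(lists, function(d)
    d[c("type", "direction")])))
  out <- list()
  with_subseed(seed, "overlap_permutation", {
    for (pi in seq_len(nrow(parts))) {
      ty <- parts$type[pi]; dir <- parts$direction[pi]
      sub <- lapply(lists, function(d) d[d$type == ty & d$direction == dir, ,
                                         drop = FALSE])
      ids <- Reduce(intersect, lapply(sub, `[[`, "event_id"))
      N <- length(ids)
      if (N == 0L) {
        message(sprintf("partition %s/%s empty: skipped", ty, dir))
        next
      }
      sub <- lapply(sub, function(d) d[match(ids, d$event_id), , drop = FALSE])
      # per-event rank in each list (1 = strongest)
      ranks <- vapply(sub, function(d) rank(-event_rank_key(d),
                                            ties.method = "first"),
                      numeric(N))
      m_obs <- apply(ranks, 1, max)
      obs_k <- cumsum(tabulate(m_obs, nbins = N))
      n_ge <- integer(N)
      exp_sum <- numeric(N)
      for (b in seq_len(B)) {
        m <- pmax(sample.int(N), sample.int(N), sample.int(N))
        nk <- cumsum(tabulate(m, nbins = N))
        n_ge <- n_ge + (nk >= obs_k)
        exp_sum <- exp_sum + nk
      }
      p_k <- empirical_p(n_ge, B)
      sig <- which(p_k < alpha)
      k_star <- if (!length(sig)) 0L else if (k_rule == "largest") {
        max(sig)
      } else {
        # depth before significance is first lost: longest significant prefix
        consec <- cumsum(seq_len(N) %in% sig) == seq_len(N)
        if (any(consec)) max(which(consec)) else 0L
      }
      inter <- if (k_star > 0) ids[m_obs <= k_star] else character(0)
      if (length(inter)) {
        sel <- match(inter, ids)
        min_fdr <- do.call(pmin, lapply(sub, function(d) d$fdr[sel]))
        max_dpsi <- do.call(pmax, lapply(sub, function(d) abs(d$delta_psi[sel])))
        final <- inter[min_fdr < fdr_max & max_dpsi > min_dpsi]
      } else final <- character(0)
      out[[paste(ty, dir, sep = "_")]] <- list(
        type = ty, direction = dir, n_universe = N,
        depth = data.frame(k = seq_len(N), observed = obs_k,
                           expected = exp_sum / B, p = p_k),
        k_star = k_star, intersection = inter, events = final)
    }
  })
  out
}

#' Prognostic-label frequency enrichment in a gene subset
#'
#' For each prognostic label class (e.g. negative / positive), compares the
#' frequency of that label within a gene subset against size-matched random
#' subsets (one-sided, overrepresentation).
#'
#' @param labels named character vector: gene -> label (e.g. `"negative"`,
#'   `"positive"`, `"none"`).
#' @param subset gene ids (subset of `names(labels)`).
#' @param classes label classes to test (default all except `"none"`).
#' @param B null draws (default 10000).
#' @param seed RNG seed.
#' @return Named list of [perm_result()], one per label class.
#' @export
prognostic_frequency_test <- function(labels, subset,
                                      classes = setdiff(unique(labels), "none"),
                                      B = 10000, seed = 1L) {
  stopifnot(all(subset %in% names(labels)))
  res <- lapply(stats::setNames(nm = classes), function(cl) {
    vals <- stats::setNames(as.numeric(labels == cl), names(labels))
    set_statistic_z(vals, subset, stat = "frequency", B = B,
                    seed = subseed(seed, cl), sided = "greater")
  })
  res
}
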