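# Per-stratum sufficient statistics for the binary-covariate Cox partial
# likelihood: risk-set and tied-event counts at every event time, with the
# Efron tie-fraction expansion precomputed.
cox_stratum_prep <- function(time, event, x) {
  o <- order(time)
  time <- time[o]; event <- event[o]; x <- x[o]
  n <- length(time)
  suf1 <- rev(cumsum(rev(x)))        # x = 1 at risk from index i on
  suf0 <- rev(cumsum(rev(1 - x)))
  ev_idx <- which(event == 1)
  if (!length(ev_idx)) return(NULL)
  et <- time[ev_idx]
  grp <- match(et, unique(et))
  # risk sets start at the first observation (event or censored) tied at
  # each event time, not the first event
  first_idx <- match(unique(et), time)
  r1 <- suf1[first_idx]; r0 <- suf0[first_idx]
  d1 <- as.numeric(tapply(x[ev_idx], grp, sum))
  d <- as.numeric(table(grp))
  d0 <- d - d1
  g <- rep(seq_along(d), d)
  jfrac <- unlist(lapply(d, function(k) (seq_len(k) - 1) / k), use.names = FALSE)
  list(r1 = r1[g], r0 = r0[g], d1e = d1[g], d0e = d0[g], jfrac = jfrac,
       sum_d1 = sum(d1), n = n)
}

cox_eval <- function(preps, beta) {
  eb <- exp(beta)
  ll <- 0; U <- 0; I <- 0
  for (p in preps) {
    a1 <- p$r1 - p$jfrac * p$d1e
    a0 <- p$r0 - p$jfrac * p$d0e
    S0 <- a0 + a1 * eb
    S1 <- a1 * eb
    ll <- ll + beta * p$sum_d1 - sum(log(S0))
    U <- U + p$sum_d1 - sum(S1 / S0)
    I <- I + sum((S1 / S0) * (1 - S1 / S0))
  }
  list(loglik = ll, U = U, I = I)
}

#' Cox proportional-hazards fit for a binary ON/OFF covariate
#'
#' Maximizes the (optionally subtype-stratified) Cox partial likelihood with
#' Efron tie handling by Newton-Raphson, for a single 0/1 state covariate.
#' The standard error comes from the observed information; `wald` is the
#' signed `coefficient / SE`.
#'
#' @param time survival times.
#' @param event event indicator (1 = event, 0 = censored).
#' @param state binary covariate (0/1), e.g. confident OFF/ON.
#' @param strata optional stratum labels (e.g. cancer subtype).
#' @return Object of class `cox_result`: `coefficient`, `se`, `hr`, `wald`,
#'   `n`, `n_events`, `iterations`, `estimable` (FALSE for constant
#'   covariates, no events, or monotone likelihoods).
#' @export
cox_wald <- function(time, event, state, strata = NULL) {
  stopifnot(length(time) == length(event), length(time) == length(state))
  if (is.null(strata)) strata <- rep(1L, length(time))
  not_est <- function(reason) {
    structure(list(coefficient = NA_real_, se = NA_real_, hr = NA_real_,
                   wald = NA_real_, n = length(time), n_events = sum(event),
                   iterations = 0L, estimable = FALSE, reason = reason),
              class = "cox_result")
  }
  if (length(unique(state)) < 2L) return(not_est("constant covariate"))
  if (sum(event[state == 1]) == 0 || sum(event[state == 0]) == 0) {
    return(not_est("no events in one covariate group"))
  }
  idx <- split(seq_along(time), strata)
  preps <- Filter(Negate(is.null), lapply(idx, function(i) {
    if (length(unique(state[i])) < 2L) return(NULL)  # stratum carries no info
    cox_stratum_prep(time[i], event[i], state[i])
  }))
  if (!length(preps)) return(not_est("no informative stratum"))
  beta <- 0
  for (it in seq_len(40L)) {
    ev <- cox_eval(preps, beta)
    if (ev$I < 1e-12) return(not_est("singular information"))
    step <- ev$U / ev$I
    step <- max(min(step, 2), -2)   # damp large Newton steps
    beta <- beta + step
    if (abs(beta) > 15) return(not_est("monotone likelihood"))
    if (abs(step) < 1e-12) break
  }
  ev <- cox_eval(preps, beta)
  se <- 1 / sqrt(ev$I)
  structure(list(coefficient = beta, se = se, hr = exp(beta),
                 wald = beta / se, n = length(time), n_events = sum(event),
                 iterations = it, estimable = TRUE, reason = NA_character_),
            class = "cox_result")
}

#' @export
print.cox_result <- function(x, ...) {
  if (!x$estimable) {
    cat("cox_result: not estimable (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("cox_result: beta=%.4f se=%.4f HR=%.3f wald=%.3f (n=%d, events=%d)\n",
                x$coefficient, x$se, x$hr, x$wald, x$n, x$n_events))
  }
  invisible(x)
}

#' Restrict samples and subtypes for per-gene survival analysis
#'
#' Applies the eligibility rules used before per-gene Cox fitting: genes of
#' 400 bp or longer are dropped; indeterminate samples are dropped; a
#' subtype is eligible for a gene only if it contains at least one
#' confident-ON and one confident-OFF sample (uniform subtypes, e.g. a
#' tissue where the gene is always ON, are excluded to avoid tissue
#' effects). Designated multi-copy gene families are first collapsed to one
#' per-sample family state via the median p across members.
#'
#' @param calls output of [call_activity()] (columns `gene`, `sample`,
#'   `p_raw`, `p_adj`, `state`).
#' @param subtypes named character vector sample -> subtype.
#' @param gene_lengths named numeric vector gene -> length (bp). Family
#'   entries default to the maximum member length.
#' @param families optional named list: family id -> member gene ids; each
#'   family is added as one unit (members removed).
#' @param max_len genes must be strictly shorter than this (default 400).
#' @param alpha,off_p state thresholds for the family median rule (defaults
#'   0.05 / 0.5).
#' @return List: `mask` (data frame `gene`, `sample`, `subtype`, `state` of
#'   eligible confident calls) and `excluded_genes` (data frame with
#'   `gene`, `reason`).
#' @export
restrict_samples <- function(calls, subtypes, gene_lengths, families = NULL,
                             max_len = 400, alpha = 0.05, off_p = 0.5) {
  df <- calls
  if (!is.null(families)) {
    fam_rows <- lapply(names(families), function(f) {
      members <- families[[f]]
      sub <- df[df$gene %in% members, , drop = FALSE]
      med_raw <- tapply(sub$p_raw, sub$sample, stats::median)
      med_adj <- tapply(sub$p_adj, sub$sample, stats::median)
      data.frame(gene = f, sample = names(med_raw),
                 p_raw = as.numeric(med_raw), p_adj = as.numeric(med_adj),
                 state = ifelse(med_adj < alpha, "confident_ON",
                                ifelse(med_raw > off_p, "confident_OFF",
                                       "indeterminate")),
                 stringsAsFactors = FALSE, row.names = NULL)
    })
    keep_cols <- c("gene", "sample", "p_raw", "p_adj", "state")
    df <- rbind(df[!df$gene %in% unlist(families), keep_cols],
                do.call(rbind, fam_rows))
    fam_len <- vapply(families, function(m) max(gene_lengths[m]), 0)
    gene_lengths <- c(gene_lengths[setdiff(names(gene_lengths),
                                           unlist(families))], fam_len)
  }
  excluded <- data.frame(gene = character(), reason = character(),
                         stringsAsFactors = FALSE)
  long <- setdiff(unique(df$gene),
                  names(gene_lengths)[gene_lengths < max_len])
  if (length(long)) {
    excluded <- rbind(excluded, data.frame(gene = long, reason = "length"))
    df <- df[!df$gene %in% long, , drop = FALSE]
  }
  df$subtype <- subtypes[df$sample]
  df <- df[df$state != "indeterminate", , drop = FALSE]
  keep <- logical(nrow(df))
  for (g in unique(df$gene)) {
    sel <- df$gene == g
    tab <- table(df$subtype[sel], df$state[sel])
    ok_sub <- rownames(tab)[rowSums(tab > 0) == 2L]
    keep[sel] <- df$subtype[sel] %in% ok_sub
    if (!length(ok_sub)) {
      excluded <- rbind(excluded,
                        data.frame(gene = g, reason = "no eligible subtype"))
    }
  }
  mask <- df[keep, c("gene", "sample", "subtype", "state")]
  rownames(mask) <- NULL
  list(mask = mask, excluded_genes = excluded)
}

#' Per-gene survival fits over eligible ON/OFF samples
#'
#' Runs [cox_wald()] for each gene over its eligible samples (from
#' [restrict_samples()]), with the subtype as stratum (default) or pooled.
#'
#' @param mask eligibility data frame (`gene`, `sample`, `subtype`,
#'   `state`) from [restrict_samples()].
#' @param clinical data frame in the `survival` schema (`sample`, `time`,
#'   `event`, `subtype`).
#' @param stratified stratify the partial likelihood by subtype (default
#'   TRUE).
#' @return `data.frame`: one row per gene with `n`, `n_events`,
#'   `coefficient`, `se`, `hr`, `wald`, `estimable`.
#' @export
gene_survival <- function(mask, clinical, stratified = TRUE) {
  clinical <- validate_table(clinical, "survival")
  rows <- lapply(unique(mask$gene), function(g) {
    sub <- mask[mask$gene == g, , drop = FALSE]
    cl <- clinical[match(sub$sample, clinical$sample), , drop = FALSE]
    fit <- cox_wald(cl$time, cl$event,
                    as.integer(sub$state == "confident_ON"),
                    strata = if (stratified) sub$subtype else NULL)
    data.frame(gene = g, n = fit$n, n_events = fit$n_events,
               coefficient = fit$coefficient, se = fit$se, hr = fit$hr,
               wald = fit$wald, estimable = fit$estimable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank RNA types by median Wald statistic against size-matched null sets
#'
#' Assigns each RNA type (e.g. 5S rRNA, snaR-A) the median Wald statistic
#' of its genes and compares it against random same-size gene sets drawn
#' from all estimable genes.
#'
#' @param cox_results data frame from [gene_survival()].
#' @param type_map named character vector gene -> RNA type.
#' @param B null draws (default 10000).
#' @param seed RNG seed.
#' @return `data.frame`: `type`, `n_genes`, `median_wald`, `z`, `p`.
#' @export
rank_gene_types <- function(cox_results, type_map, B = 10000, seed = 1L) {
  est <- cox_results[cox_results$estimable, , drop = FALSE]
  vals <- stats::setNames(est$wald, est$gene)
  types <- unique(type_map[names(vals)])
  types <- types[!is.na(types)]
  rows <- lapply(types, function(ty) {
    members <- intersect(names(type_map)[type_map == ty], names(vals))
    if (!length(members)) return(NULL)
    pr <- set_statistic_z(vals, members, stat = "median", B = B,
                          seed = subseed(seed, ty), sided = "greater")
    data.frame(type = ty, n_genes = length(members),
               median_wald = pr$observed, z = pr$z, p = pr$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  out <- out[order(-out$median_wald), , drop = FALSE]
  rownames(out) <- NULL
  out
}
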