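#' @keywords internal
"_PACKAGE"

# Stable sub-seed so each generator owns an RNG stream: adding a generator
# never perturbs the draws of another under the same master seed.
subseed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 7919 + h * 104729) %% 2147483629)
}

# Evaluate `expr` under a seeded RNG stream, restoring global RNG state after.
with_subseed <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(subseed(seed, name))
  expr
}

# Add-one smoothed empirical p-value: never 0, floor 1/(B+1).
empirical_p <- function(n_extreme, B) (1 + n_extreme) / (B + 1)

# Rank-based (Mann-Whitney) AUC for scores of a binary outcome.
rank_auc <- function(score, label) {
  stopifnot(length(score) == length(label))
  pos <- score[label == 1L]
  neg <- score[label == 0L]
  if (length(pos) == 0L || length(neg) == 0L) return(NA_real_)
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Round half away from zero (half-up for nonnegative input).
round_half_up <- function(x) floor(x + 0.5)

logit <- function(p) log(p / (1 - p))
inv_logit <- function(x) 1 / (1 + exp(-x))
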