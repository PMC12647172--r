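# Independent Efron partial-likelihood oracle for small instances: direct
# loop over event times, maximized by optimize().
efron_loglik <- function(beta, time, event, x, strata = rep(1, length(time))) {
  ll <- 0
  for (st in unique(strata)) {
    sel <- strata == st
    tt <- time[sel]; ee <- event[sel]; xx <- x[sel]
    for (ut in sort(unique(tt[ee == 1]))) {
      risk <- tt >= ut
      tied <- tt == ut & ee == 1
      d <- sum(tied)
      s0 <- sum(exp(beta * xx[risk]))
      t0 <- sum(exp(beta * xx[tied]))
      ll <- ll + beta * sum(xx[tied])
      for (j in 0:(d - 1)) ll <- ll - log(s0 - (j / d) * t0)
    }
  }
  ll
}

test_that("cox_wald matches the partial-likelihood oracle on the 4-point case", {
  fit <- cox_wald(c(1, 3, 2, 4), c(1, 1, 1, 1), c(1, 1, 0, 0))
  opt <- optimize(efron_loglik, c(-5, 5), maximum = TRUE,
                  time = c(1, 3, 2, 4), event = rep(1, 4), x = c(1, 1, 0, 0))
  expect_lt(abs(fit$coefficient - opt$maximum), 1e-6)
  expect_equal(fit$coefficient, 0.94, tolerance = 0.01)
  expect_equal(fit$hr, exp(fit$coefficient))
  expect_equal(fit$wald, fit$coefficient / fit$se)
  # antisymmetry: swapping the state labels negates the coefficient
  swap <- cox_wald(c(1, 3, 2, 4), rep(1, 4), c(0, 0, 1, 1))
  expect_equal(swap$coefficient, -fit$coefficient, tolerance = 1e-8)
  # identical survival in both groups: no effect
  none <- cox_wald(c(1, 1, 2, 2), rep(1, 4), c(1, 0, 1, 0))
  expect_lt(abs(none$coefficient), 1e-6)
})

test_that("cox_wald matches the oracle on random small instances with ties", {
  set.seed(21)
  for (i in 1:8) {
    n <- sample(5:8, 1)
    time <- sample(1:4, n, replace = TRUE)      # forces ties
    event <- rbinom(n, 1, 0.8)
    x <- rbinom(n, 1, 0.5)
    strata <- sample(1:2, n, replace = TRUE)
    fit <- cox_wald(time, event, x, strata)
    if (!fit$estimable) next
    opt <- optimize(efron_loglik, c(-8, 8), maximum = TRUE, time = time,
                    event = event, x = x, strata = strata)
    expect_lt(abs(fit$coefficient - opt$maximum), 1e-5)
  }
})

test_that("cox_wald agrees with survival::coxph (Efron ties, strata)", {
  skip_if_not_installed("survival")
  set.seed(13)
  n <- 300
  x <- rbinom(n, 1, 0.4)
  time <- round(rexp(n, 0.1 * exp(0.5 * x)), 1) + 0.1
  event <- rbinom(n, 1, 0.8)
  st <- sample(c("A", "B", "C"), n, replace = TRUE)
  fit <- cox_wald(time, event, x, st)
  ref <- survival::coxph(survival::Surv(time, event) ~ x +
                           survival::strata(st), ties = "efron")
  expect_lt(abs(fit$coefficient - unname(coef(ref))), 1e-6)
  expect_lt(abs(fit$se - sqrt(unname(vcov(ref)[1, 1]))), 1e-6)
})

test_that("non-estimable designs are flagged, not fitted", {
  expect_false(cox_wald(1:4, rep(1, 4), rep(1, 4))$estimable)
  expect_false(cox_wald(1:4, c(1, 1, 0, 0), c(1, 1, 0, 0))$estimable)
})

test_that("sample restriction drops long genes and uniform subtypes", {
  samples <- paste0("s", 1:8)
  subtypes <- setNames(rep(c("A", "B"), each = 4), samples)
  mk <- function(gene, states) {
    data.frame(gene = gene, sample = samples,
               p_raw = ifelse(states == "confident_ON", 0.001, 0.9),
               p_adj = ifelse(states == "confident_ON", 0.01, 0.95),
               state = states, stringsAsFactors = FALSE)
  }
  # gene gA: subtype A mixed, subtype B all-ON (excluded for gA)
  calls <- rbind(
    mk("gA", c("confident_ON", "confident_OFF", "confident_ON",
               "indeterminate", rep("confident_ON", 4))),
    mk("gLong", rep(c("confident_ON", "confident_OFF"), 4)))
  lens <- c(gA = 300, gLong = 450)
  res <- restrict_samples(calls, subtypes, lens)
  expect_true("gLong" %in% res$excluded_genes$gene)
  mA <- res$mask[res$mask$gene == "gA", ]
  expect_true(all(mA$subtype == "A"))
  expect_false(any(mA$state == "indeterminate"))
  # invariant: every retained subtype carries both states
  for (g in unique(res$mask$gene)) {
    tab <- table(res$mask$subtype[res$mask$gene == g],
                 res$mask$state[res$mask$gene == g])
    expect_true(all(rowSums(tab > 0) == 2))
  }
})

test_that("family state aggregation uses the median p across members", {
  samples <- "s1"
  mk <- function(gene, p_raw, p_adj) {
    data.frame(gene = gene, sample = samples, p_raw = p_raw, p_adj = p_adj,
               state = "indeterminate", stringsAsFactors = FALSE)
  }
  calls <- rbind(mk("m1", 0.01, 0.01), mk("m2", 0.02, 0.02),
                 mk("m3", 0.9, 0.9))
  fam_state <- restrict_samples(
    calls, setNames("A", "s1"),
    c(m1 = 100, m2 = 100, m3 = 100), families = list(fam = c("m1", "m2", "m3")))
  # median p = 0.02 < 0.05: family is confident_ON for that sample (the
  # single-subtype design then drops it for lacking an OFF partner)
  expect_true("fam" %in% fam_state$excluded_genes$gene ||
                all(fam_state$mask$state == "confident_ON"))
})

test_that("planted hazard is recovered and null genes stay quiet", {
  cfg <- sim_config(seed = 33, n_samples = 600, n_genes = 3,
                    censor_rate = 0.3)
  sv <- simulate_survival(cfg)
  fit <- cox_wald(sv$clinical$time, sv$clinical$event, sv$states[, 1],
                  strata = sv$clinical$subtype)
  expect_gt(fit$hr, 1.1)
  expect_lt(fit$hr, 2.0)
  null_fit <- cox_wald(sv$clinical$time, sv$clinical$event, sv$states[, 2],
                       strata = sv$clinical$subtype)
  expect_lt(abs(null_fit$wald), 3)
})

test_that("gene type ranking flags a planted high-Wald type", {
  set.seed(7)
  cox_df <- data.frame(gene = paste0("g", 1:60), n = 100, n_events = 70,
                       coefficient = 0, se = 1,
                       hr = 1, wald = rnorm(60), estimable = TRUE)
  cox_df$wald[1:5] <- 5
  types <- setNames(c(rep("snaR-A", 5), rep("tRNA", 30), rep("5S", 25)),
                    cox_df$gene)
  B <- 2000
  rk <- rank_gene_types(cox_df, types, B = B, seed = 9)
  top <- rk[rk$type == "snaR-A", ]
  expect_equal(top$median_wald, 5)
  expect_gt(top$z, 3)
  # a null draw can tie the observed median by picking >= 3 planted genes
  # (probability ~ 0.003), so p sits at or just above the floor
  expect_lte(top$p, 0.01)
  expect_equal(rk$type[1], "snaR-A")   # ranked first by median Wald
  # a single-gene type reduces to that gene's Wald statistic
  types2 <- types; types2["g60"] <- "lonely"
  rk2 <- rank_gene_types(cox_df, types2, B = 500, seed = 9)
  expect_equal(rk2$median_wald[rk2$type == "lonely"], cox_df$wald[60])
})
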