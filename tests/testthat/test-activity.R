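# log-space brute-force oracle for the strict Poisson upper tail: log-sum-exp
# over P(X = i) for i = k+1, k+2, ... until terms become negligible.
tail_oracle_log <- function(k, lam) {
  i <- (k + 1):(k + 1 + max(200, ceiling(10 * lam + 10 * sqrt(lam))))
  lt <- i * log(lam) - lam - lgamma(i + 1)
  m <- max(lt)
  m + log(sum(exp(lt - m)))
}

test_that("poisson_tail matches closed forms and rejects bad input", {
  expect_equal(poisson_tail(0, 1), 1 - exp(-1), tolerance = 1e-12)
  expect_equal(poisson_tail(1, 2), 1 - 3 * exp(-2), tolerance = 1e-12)
  expect_equal(poisson_tail(5, 0), 0)
  expect_error(poisson_tail(-1, 1), "nonnegative")
  expect_error(poisson_tail(1.5, 1), "integer")
})

test_that("poisson_tail agrees with the partial-sum oracle and is monotone", {
  for (lam in c(0.1, 1, 2, 8, 25, 50)) {
    for (k in c(0, 1, 3, 10, 40, 120, 200)) {
      lo <- tail_oracle_log(k, lam)
      if (lo < log(1e-290)) next
      p <- poisson_tail(k, lam)
      expect_lt(abs(p - exp(lo)) / exp(lo), 1e-10)
    }
  }
  # strict tail decreases in k, increases in lambda
  expect_true(all(diff(poisson_tail(0:30, 4)) < 0))
  expect_true(all(diff(poisson_tail(5, seq(0.5, 10, by = 0.5))) > 0))
  # numerically sane in extreme regimes
  expect_gt(poisson_tail(2000, 1e6), 0.999)
  expect_true(poisson_tail(250, 10) > 0 && poisson_tail(250, 10) < 1e-200)
})

test_that("local_lambda follows the window-rate rule with clipping", {
  # uniform coverage at rate r per bp: every lambda equals r * length
  tr <- coverage_track(list(chr1 = rep(5, 30000)), bin_width = 10)  # 0.5/bp
  g <- genomic_intervals("chr1", 150000, 150200, id = "g")
  lam <- local_lambda(tr, g)
  expect_equal(lam$lambda_1k, 0.5 * 200, tolerance = 1e-9)
  expect_equal(lam$lambda_genome, 0.5 * 200, tolerance = 1e-9)
  expect_equal(lam$lambda_max, 0.5 * 200, tolerance = 1e-9)

  # inclusive-window arithmetic: gene 200 bp, 1 kb window holding 100 reads
  # gives rate 0.1/bp and lambda 20; clipped edge window of 600 bp with 60
  # reads gives the same rate
  bins <- rep(0, 200)
  bins[1:100] <- 1   # 100 reads over the first 1000 bp
  tr2 <- coverage_track(list(chr1 = bins), bin_width = 10)
  g2 <- genomic_intervals("chr1", 400, 600, id = "g2")
  lam2 <- local_lambda(tr2, g2, include_gene = TRUE)
  expect_equal(lam2$lambda_1k, 100 / 1000 * 200, tolerance = 1e-9)
  g3 <- genomic_intervals("chr1", 0, 200, id = "g3")  # window clipped to 600
  lam3 <- local_lambda(tr2, g3, include_gene = TRUE)
  expect_equal(lam3$lambda_1k, 60 / 600 * 200, tolerance = 1e-9)

  # flanking-only default subtracts the gene's own reads and width
  lam4 <- local_lambda(tr2, g2)
  expect_equal(lam4$lambda_1k, (100 - 20) / 800 * 200, tolerance = 1e-9)
})

test_that("downsample_track thins binomially and reproducibly", {
  set.seed(3)
  tr <- coverage_track(list(chr1 = rpois(5000, 100)), bin_width = 10)
  target <- round(tr$total_reads / 2)
  thin1 <- downsample_track(tr, target, seed = 9)
  thin2 <- downsample_track(tr, target, seed = 9)
  expect_identical(thin1$bins, thin2$bins)
  expect_lt(abs(thin1$total_reads - target), 3 * sqrt(target))
  expect_true(all(unlist(thin1$bins) <= unlist(tr$bins)))
  same <- downsample_track(tr, tr$total_reads, seed = 1)
  expect_identical(same$bins, tr$bins)
  expect_warning(downsample_track(tr, tr$total_reads * 2, seed = 1), "below")
  expect_error(downsample_track(tr, 0, seed = 1), "positive")
})

test_that("call_activity applies global BH and the state thresholds", {
  cfg <- sim_config(seed = 5, n_genes = 120, n_samples = 2)
  sim <- simulate_accessibility(cfg)
  calls <- call_activity(sim$tracks, sim$genes)
  expect_equal(calls$p_adj, p.adjust(calls$p_raw, "BH"))
  expect_true(all(calls$p_adj >= calls$p_raw))
  expect_true(all((calls$state == "confident_ON") == (calls$p_adj < 0.05)))
  expect_true(all(calls$state[calls$p_adj >= 0.05 & calls$p_raw > 0.5] ==
                    "confident_OFF"))
  # per-sample adjustment mode adjusts within sample
  calls_ps <- call_activity(sim$tracks, sim$genes, global = FALSE)
  s1 <- calls_ps$sample == calls_ps$sample[1]
  expect_equal(calls_ps$p_adj[s1], p.adjust(calls_ps$p_raw[s1], "BH"))
  # single gene, single sample: adjustment is a no-op
  one <- call_activity(sim$tracks[1], sim$genes[1, ])
  expect_equal(one$p_adj, one$p_raw)
})

test_that("null accessibility (fold = 1) keeps the raw positive rate near alpha", {
  cfg <- sim_config(seed = 8, n_genes = 800, n_samples = 1, activity_fold = 1)
  sim <- simulate_accessibility(cfg)
  calls <- call_activity(sim$tracks, sim$genes)
  frac <- mean(calls$p_raw < 0.05)
  se <- sqrt(0.05 * 0.95 / nrow(calls))
  expect_lt(frac, 0.05 + 2 * se)
})

test_that("gene state classification follows the median-p rule set", {
  samples <- paste0("s", 1:6)
  subtypes <- setNames(rep(c("A", "B", "C"), each = 2), samples)
  mk <- function(gene, p) data.frame(gene = gene, sample = samples,
                                     k = 0, lambda_max = 1, p_raw = p,
                                     p_adj = p, state = "indeterminate")
  calls <- rbind(
    mk("short_on", rep(0.01, 6)),                 # global median 0.01
    mk("onoff", c(0.8, 0.8, 0.03, 0.03, 0.6, 0.6)),  # one subtype < 0.05
    mk("off", rep(0.3, 6)),
    mk("long", rep(0.01, 6)))                     # active but >= 1000 bp
  genes <- genomic_intervals("chr1", c(0, 1000, 2000, 3000),
                             c(800, 1800, 2800, 4500),
                             id = c("short_on", "onoff", "off", "long"))
  cls <- classify_gene_states(calls, genes, subtypes)
  got <- setNames(cls$class, cls$gene)
  expect_equal(got[["short_on"]], "always_ON")
  expect_equal(got[["onoff"]], "ON_OFF")
  expect_equal(got[["off"]], "OFF")
  # genes >= 1000 bp can never be always_ON, but can be ON_OFF
  expect_equal(got[["long"]], "ON_OFF")
  expect_error(classify_gene_states(calls, genes, subtypes[-1]),
               "without subtype")
})
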