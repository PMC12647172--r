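test_that("config validation rejects out-of-range parameters", {
  expect_error(sim_config(active_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(background_rate = 0), "positive")
  expect_error(sim_config(activity_fold = 0.5), ">= 1")
  expect_error(sim_config(ir_effect = -1.5), "\\[-1, 1\\]")
  expect_error(sim_config(true_log_hr = Inf), "finite")
})

test_that("all generators are byte-identical under the same config", {
  cfg <- sim_config(seed = 7, n_genes = 50, n_transcripts = 40,
                    n_junctions = 30, n_proteins = 40, n_events = 60,
                    n_samples = 30)
  expect_identical(simulate_accessibility(cfg), simulate_accessibility(cfg))
  expect_identical(suppressWarnings(simulate_ir_tables(cfg)),
                   suppressWarnings(simulate_ir_tables(cfg)))
  expect_identical(simulate_junction_bins(cfg), simulate_junction_bins(cfg))
  expect_identical(simulate_survival(cfg), simulate_survival(cfg))
  expect_identical(simulate_event_lists(cfg), simulate_event_lists(cfg))
  expect_identical(simulate_proteomics(cfg), simulate_proteomics(cfg))
  # generators draw from independent sub-streams: changing one config knob
  # that only one generator uses leaves the others untouched
  cfg2 <- sim_config(seed = 7, n_genes = 50, n_transcripts = 40,
                     n_junctions = 30, n_proteins = 40, n_events = 60,
                     n_samples = 30, overlap_rho = 0.9)
  expect_identical(simulate_proteomics(cfg)$intensities,
                   simulate_proteomics(cfg2)$intensities)
})

test_that("accessibility counts have the planted Poisson means", {
  cfg <- sim_config(seed = 12, n_genes = 1000, n_samples = 1)
  sim <- simulate_accessibility(cfg)
  k <- extract_counts(sim$tracks[[1]], sim$genes)
  act <- sim$genes$id %in% sim$truth$active_genes
  # 0.01/bp over 200 bp at fold 5: mean 10 active vs 2 inactive (the smooth
  # background multiplier averages out across gene positions)
  expect_lt(abs(mean(k[act]) - 10), 0.6)
  expect_lt(abs(mean(k[!act]) - 2), 0.2)
  expect_error(simulate_accessibility(cfg, contig_length = 1000), "short")
})

test_that("IR tables respect ratio bounds, clipping and filter planting", {
  cfg <- sim_config(seed = 9, n_transcripts = 100)
  expect_warning(sim <- simulate_ir_tables(cfg), "clipped")
  ircols <- grep("^ir_", names(sim$table), value = TRUE)
  for (cn in ircols) {
    expect_true(all(sim$table[[cn]] > 0 & sim$table[[cn]] < 1))
  }
  # truth containment: every planted transcript exists in the table
  expect_true(all(sim$truth$sensitive_transcripts %in%
                    sim$table$transcript_id))
  # planted filter failures are rejected, and only failures are
  flt <- filter_introns(sim$table)
  expect_setequal(flt$rejected$intron_id, sim$truth$filter_fail_introns)
})

test_that("junction generator plants enrichment in the 5 junction-adjacent bins", {
  cfg <- sim_config(seed = 4, n_junctions = 400, activity_fold = 10)
  sim <- simulate_junction_bins(cfg, lambda0 = 1)
  enr <- rownames(sim$bins) %in% sim$truth$enriched_junctions
  expect_gt(mean(sim$bins[enr, 46:50]), 8)
  expect_lt(mean(sim$bins[enr, c(1:45, 51:100)]), 1.5)
  # enriched junctions at 10x fold and lambda0 = 1 score far above background
  rs <- residency_scores(sim$bins)
  expect_gt(median(rs$score[enr]), 4)
  # an empty track scores exactly zero everywhere
  empty <- matrix(0L, 10, 100)
  expect_true(all(residency_scores(empty)$score == 0))
})

test_that("survival generator refuses total censoring and plants the hazard", {
  expect_error(simulate_survival(sim_config(censor_rate = 1)), "refused")
  cfg <- sim_config(seed = 3, n_samples = 1200, n_genes = 2,
                    censor_rate = 0.3)
  sv <- simulate_survival(cfg)
  expect_lt(abs(mean(1 - sv$clinical$event) - 0.3), 0.06)
  # two subtypes are state-uniform by design
  expect_length(sv$truth$uniform_subtypes, 2)
  for (s in sv$truth$uniform_subtypes) {
    st <- sv$states[sv$clinical$subtype == s, ]
    expect_true(all(st == st[1]))
  }
})

test_that("null hazard gives approximately standard-normal Wald statistics", {
  z <- vapply(1:200, function(r) {
    cfg <- sim_config(seed = 5000 + r, n_samples = 120, n_genes = 1,
                      true_log_hr = 0, censor_rate = 0.2)
    sv <- simulate_survival(cfg)
    f <- cox_wald(sv$clinical$time, sv$clinical$event, sv$states[, 1],
                  strata = sv$clinical$subtype)
    if (f$estimable) f$wald else NA_real_
  }, 0)
  z <- z[is.finite(z)]
  expect_gt(length(z), 150)
  expect_lt(abs(mean(z)), 0.2)
  expect_lt(abs(sd(z) - 1), 0.25)
})

test_that("event lists have rank-consistent fields and controlled overlap", {
  cfg1 <- sim_config(seed = 2, n_events = 300, overlap_rho = 1)
  ev1 <- simulate_event_lists(cfg1)
  # rho = 1: identical rankings across the three lists
  key <- function(d) d$event_id[order(-(-log10(d$fdr) * abs(d$delta_psi)))]
  expect_equal(key(ev1$lists[[1]]), key(ev1$lists[[2]]))
  expect_equal(key(ev1$lists[[2]]), key(ev1$lists[[3]]))
  for (l in ev1$lists) {
    # FDR monotone nondecreasing in within-partition rank, |dPSI| <= 1
    part <- interaction(l$type, l$direction, drop = TRUE)
    for (p in levels(part)) {
      d <- l[part == p, ]
      o <- order(-(-log10(d$fdr) * abs(d$delta_psi)))
      expect_true(all(diff(d$fdr[o]) >= 0))
    }
    expect_true(all(abs(l$delta_psi) <= 1))
    expect_true(all(l$fdr > 0 & l$fdr < 1))
  }
  # direction encodes the dPSI sign
  l1 <- ev1$lists[[1]]
  expect_true(all(l1$delta_psi[l1$direction == "inclusion"] > 0))
  expect_true(all(l1$delta_psi[l1$direction == "exclusion"] < 0))
})

test_that("proteomics generator plants a recoverable enriched set", {
  cfg <- sim_config(seed = 6, n_proteins = 300)
  sim <- simulate_proteomics(cfg)
  norm <- normalize_total(sim$intensities)
  expect_equal(unname(colSums(norm)), rep(1, 4), tolerance = 1e-12)
  hits <- enrich_filter(norm, sim$peptides, c("target_1", "target_2"),
                        c("scramble", "beads"))
  expect_setequal(hits$protein_id[hits$enriched],
                  sim$truth$enriched_proteins)
  # peptide decoys carry strong intensity but fail the both-replicates rule
  decoys <- hits[hits$protein_id %in% sim$truth$peptide_decoys, ]
  expect_true(all(decoys$min_log2_ratio > 2))
  expect_true(all(!decoys$enriched))
  # zero planted: the filter returns an empty set
  cfg0 <- sim_config(seed = 6, n_proteins = 200, active_fraction = 0)
  sim0 <- simulate_proteomics(cfg0)
  hits0 <- enrich_filter(normalize_total(sim0$intensities), sim0$peptides,
                         c("target_1", "target_2"), c("scramble", "beads"))
  expect_equal(sum(hits0$enriched), 0L)
})

test_that("accessibility datasets round-trip through BED/bedGraph files", {
  cfg <- sim_config(seed = 10, n_genes = 20, n_samples = 2)
  sim <- simulate_accessibility(cfg)
  dir <- withr::local_tempdir()
  paths <- write_accessibility(sim, dir)
  genes2 <- read_intervals(paths[["genes"]])
  expect_equal(genes2, sim$genes)
  tr2 <- read_bedgraph(paths[["s01"]], bin_width = 10)
  expect_equal(tr2$bins$chr1, sim$tracks$s01$bins$chr1)
})
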