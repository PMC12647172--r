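#' Simulation configuration
#'
#' Parameters for the seeded generators that produce every input the
#' pipeline consumes, with planted ground truth. Defaults mirror the study
#' designs the pipeline was built for: short Pol III gene intervals over a
#' Poisson accessibility background (gene-level rate near 2), a 1-control +
#' 3-treatment intron-retention design, a planted hazard ratio of 1.5 with
#' 30% censoring, and a 5% planted-positive fraction throughout.
#'
#' @param seed master RNG seed; every generator derives its own stable
#'   sub-stream from it.
#' @param n_samples samples per generated dataset.
#' @param n_genes,n_transcripts,n_junctions,n_proteins,n_events entity
#'   counts per generator.
#' @param background_rate accessibility background in reads per bp (> 0).
#' @param active_fraction planted-positive fraction in `[0, 1]` (active
#'   genes, sensitive transcripts, enriched junctions/proteins).
#' @param activity_fold signal fold-change over planted entities (>= 1).
#' @param ir_effect additive IR-ratio shift in `[-1, 1]` for sensitive
#'   transcripts (negative = retention reduced by treatment).
#' @param ir_noise_sd replicate noise SD on the logit of the IR ratio.
#' @param true_log_hr log hazard ratio of the causal gene's ON state.
#' @param censor_rate target censoring proportion in `[0, 1)`.
#' @param overlap_rho inter-list rank correlation in `[0, 1]` for the
#'   splicing-event lists.
#' @param filter_fail_fraction fraction of introns constructed to fail a
#'   quality filter.
#' @param introns_per_transcript introns per simulated transcript.
#' @return Validated object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_samples = 4L, n_genes = 1000L,
                       n_transcripts = 1000L, n_junctions = 1000L,
                       n_proteins = 500L, n_events = 500L,
                       background_rate = 0.01, active_fraction = 0.05,
                       activity_fold = 5, ir_effect = -0.3,
                       ir_noise_sd = 0.05, true_log_hr = log(1.5),
                       censor_rate = 0.3, overlap_rho = 0.5,
                       filter_fail_fraction = 0.05,
                       introns_per_transcript = 5L) {
  cfg <- list(seed = as.integer(seed), n_samples = as.integer(n_samples),
              n_genes = as.integer(n_genes),
              n_transcripts = as.integer(n_transcripts),
              n_junctions = as.integer(n_junctions),
              n_proteins = as.integer(n_proteins),
              n_events = as.integer(n_events),
              background_rate = background_rate,
              active_fraction = active_fraction,
              activity_fold = activity_fold, ir_effect = ir_effect,
              ir_noise_sd = ir_noise_sd, true_log_hr = true_log_hr,
              censor_rate = censor_rate, overlap_rho = overlap_rho,
              filter_fail_fraction = filter_fail_fraction,
              introns_per_transcript = as.integer(introns_per_transcript))
  props <- c("active_fraction", "censor_rate", "overlap_rho",
             "filter_fail_fraction")
  for (p in props) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (cfg$background_rate <= 0) stop("background_rate must be positive")
  if (cfg$activity_fold < 1) stop("activity_fold must be >= 1")
  if (abs(cfg$ir_effect) > 1) stop("ir_effect must lie in [-1, 1]")
  if (!is.finite(cfg$true_log_hr)) stop("true_log_hr must be finite")
  structure(cfg, class = "sim_config")
}

#' Simulate accessibility coverage with a planted active-gene set
#'
#' One linear contig holds `n_genes` short genes (default 200 bp, spaced
#' 2 kb) with 100 kb flanks. Bin counts (10 bp bins) are Poisson with rate
#' `background_rate` per bp, scaled by a smooth sinusoidal local multiplier
#' (+/-20%), and multiplied by `activity_fold` over active genes in ON
#' samples. A fraction `active_fraction` of genes is planted active (ON in
#' every sample by default).
#'
#' @param cfg a [sim_config()].
#' @param gene_length,gene_spacing gene size and start-to-start spacing (bp).
#' @param bin_width track bin width (bp).
#' @param contig_length optional explicit contig length; an error is raised
#'   if the genes plus 100 kb flanks do not fit.
#' @param on_sample_fraction fraction of samples in which an active gene is
#'   ON (default 1).
#' @param background_amplitude relative amplitude of the smooth sinusoidal
#'   local-background multiplier (default 0.2; use 0 for a flat background
#'   with every gene at exactly `background_rate * gene_length`).
#' @return List: `genes` (interval table), `tracks` (named list of
#'   [coverage_track()] per sample), `truth` (list with `active_genes`,
#'   `active_pairs`, `config`).
#' @export
simulate_accessibility <- function(cfg, gene_length = 200L,
                                   gene_spacing = 2000L, bin_width = 10L,
                                   contig_length = NULL,
                                   on_sample_fraction = 1,
                                   background_amplitude = 0.2) {
  stopifnot(inherits(cfg, "sim_config"))
  flank <- 1e5
  need <- 2 * flank + cfg$n_genes * gene_spacing
  if (is.null(contig_length)) contig_length <- need
  if (contig_length < need) {
    stop(sprintf("contig too short: need %d bp for %d genes plus flanks",
                 need, cfg$n_genes))
  }
  starts <- flank + (seq_len(cfg$n_genes) - 1L) * gene_spacing
  genes <- genomic_intervals("chr1", starts, starts + gene_length,
                             id = sprintf("g%04d", seq_len(cfg$n_genes)),
                             strand = rep("+", cfg$n_genes))
  n_bins <- ceiling(contig_length / bin_width)
  mids <- (seq_len(n_bins) - 0.5) * bin_width
  mult <- 1 + background_amplitude * sin(2 * pi * mids / 5e5)
  base_lam <- cfg$background_rate * bin_width * mult
  with_subseed(cfg$seed, "simulate_accessibility", {
    n_active <- round(cfg$active_fraction * cfg$n_genes)
    active <- sort(sample.int(cfg$n_genes, n_active))
    samples <- sprintf("s%02d", seq_len(cfg$n_samples))
    gene_bins <- lapply(seq_len(cfg$n_genes), function(i) {
      (floor(genes$start[i] / bin_width) + 1L):ceiling(genes$end[i] / bin_width)
    })
    pairs <- list()
    tracks <- lapply(samples, function(s) {
      lam <- base_lam
      on_genes <- active[stats::runif(length(active)) <= on_sample_fraction]
      for (i in on_genes) {
        lam[gene_bins[[i]]] <- lam[gene_bins[[i]]] * cfg$activity_fold
      }
      pairs[[s]] <<- on_genes
      coverage_track(list(chr1 = stats::rpois(n_bins, lam)), bin_width)
    })
    names(tracks) <- samples
    active_pairs <- do.call(rbind, lapply(samples, function(s) {
      if (!length(pairs[[s]])) return(NULL)
      data.frame(gene = genes$id[pairs[[s]]], sample = s,
                 stringsAsFactors = FALSE)
    }))
    list(genes = genes, tracks = tracks,
         truth = list(active_genes = genes$id[active],
                      active_pairs = active_pairs, config = cfg))
  })
}

#' Simulate an IRFinder-style intron-retention table
#'
#' One control (scramble) plus three treatment replicates per intron.
#' Baseline IR ratios are uniform on [0.1, 0.6]; sensitive transcripts
#' shift all their introns by `ir_effect` in the treatments (clipped into
#' [0.01, 0.99] with a warning when the shift leaves the unit interval);
#' replicate noise is Gaussian on the logit scale (`ir_noise_sd`), keeping
#' ratios inside (0, 1). CPM and flanking-exon support columns are
#' populated so the quality filters are exercisable; a fraction
#' `filter_fail_fraction` of introns is constructed to fail one filter.
#'
#' @param cfg a [sim_config()].
#' @return List: `table` (data frame in the `ir` schema; samples `ctrl`,
#'   `si1`, `si2`, `si3`), `truth` (list with `sensitive_transcripts`,
#'   `filter_fail_introns`, `config`).
#' @export
simulate_ir_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_subseed(cfg$seed, "simulate_ir_tables", {
    nt <- cfg$n_transcripts
    k <- cfg$introns_per_transcript
    n <- nt * k
    tid <- rep(sprintf("t%04d", seq_len(nt)), each = k)
    iid <- sprintf("%s_i%d", tid, rep(seq_len(k), nt))
    start <- (seq_len(n) - 1L) * 3000L + 500L
    sens <- sort(sample.int(nt, round(cfg$active_fraction * nt)))
    is_sens <- rep(seq_len(nt) %in% sens, each = k)
    base <- stats::runif(n, 0.1, 0.6)
    samples <- c("ctrl", "si1", "si2", "si3")
    clipped <- FALSE
    shift <- function(treated) {
      m <- base + ifelse(treated & is_sens, cfg$ir_effect, 0)
      if (any(m < 0.01 | m > 0.99)) {
        clipped <<- TRUE
        m <- pmin(pmax(m, 0.01), 0.99)
      }
      inv_logit(logit(m) + stats::rnorm(n, 0, cfg$ir_noise_sd))
    }
    ir <- vapply(samples, function(s) shift(s != "ctrl"), numeric(n))
    if (clipped) warning("ir_effect pushed ratios outside [0,1]: values clipped")
    cpm <- matrix(exp(stats::rnorm(n * 4, log(20), 0.4)), n, 4,
                  dimnames = list(NULL, samples))
    fl5 <- matrix(stats::rpois(n * 4, 50), n, 4)
    fl3 <- matrix(stats::rpois(n * 4, 50), n, 4)
    n_fail <- round(cfg$filter_fail_fraction * n)
    fail <- sample.int(n, n_fail)
    mode <- sample(1:3, n_fail, replace = TRUE)
    cpm[fail[mode == 1], 1 + (fail[mode == 1] %% 4)] <- 0.5
    fl5[fail[mode == 2], 1 + (fail[mode == 2] %% 4)] <- 5L
    fl3[fail[mode == 3], 1 + (fail[mode == 3] %% 4)] <- 8L
    tab <- data.frame(transcript_id = tid, intron_id = iid, chrom = "chr1",
                      start = start, end = start + 1000L, strand = "+",
                      stringsAsFactors = FALSE)
    for (j in seq_along(samples)) {
      tab[[paste0("ir_", samples[j])]] <- ir[, j]
      tab[[paste0("cpm_", samples[j])]] <- cpm[, j]
      tab[[paste0("flank5_", samples[j])]] <- fl5[, j]
      tab[[paste0("flank3_", samples[j])]] <- fl3[, j]
    }
    list(table = validate_table(tab, "ir"),
         truth = list(sensitive_transcripts = sprintf("t%04d", sens),
                      filter_fail_introns = iid[fail], config = cfg))
  })
}

#' Simulate junction-proximal eCLIP bin counts
#'
#' For each 3' splice junction, 100 transcript-oriented 10-bp bins (50
#' intron-side, 50 exon-side) with Poisson(`lambda0`) background counts;
#' enriched junctions (fraction `active_fraction`) receive
#' `activity_fold`-elevated counts in the 5 intron-side bins adjacent to
#' the splice site (bins 46-50).
#'
#' @param cfg a [sim_config()].
#' @param lambda0 background rate per 10-bp bin (default 2).
#' @return List: `junctions` (ids), `bins` (junction x 100 count matrix),
#'   `truth` (list with `enriched_junctions`, `lambda0`, `config`).
#' @export
simulate_junction_bins <- function(cfg, lambda0 = 2) {
  stopifnot(inherits(cfg, "sim_config"))
  with_subseed(cfg$seed, "simulate_junction_bins", {
    nj <- cfg$n_junctions
    ids <- sprintf("j%05d", seq_len(nj))
    lam <- matrix(lambda0, nj, 100)
    enr <- sort(sample.int(nj, round(cfg$active_fraction * nj)))
    lam[enr, 46:50] <- lambda0 * cfg$activity_fold
    bins <- matrix(stats::rpois(nj * 100, lam), nj, 100,
                   dimnames = list(ids, NULL))
    list(junctions = ids, bins = bins,
         truth = list(enriched_junctions = ids[enr], lambda0 = lambda0,
                      config = cfg))
  })
}

#' Simulate a survival table with per-gene binary ON/OFF states
#'
#' Samples are split over 6 subtypes; the first (causal) gene's ON state
#' multiplies the exponential event hazard by `exp(true_log_hr)`, all other
#' genes carry independent null states. Two subtypes are state-uniform
#' (all-ON and all-OFF for every gene) to exercise the subtype-exclusion
#' rule; the remaining subtypes have imbalanced ON probabilities.
#' Independent exponential censoring is tuned to the target `censor_rate`.
#'
#' @param cfg a [sim_config()]; `censor_rate = 1` is refused (no events).
#' @param baseline_hazard exponential event rate for OFF samples
#'   (default 0.1).
#' @param n_subtypes number of subtypes (default 6; >= 3).
#' @return List: `clinical` (data frame `sample`, `time`, `event`,
#'   `subtype`), `states` (sample x gene 0/1 matrix), `truth` (list with
#'   `causal_gene`, `true_log_hr`, `config`).
#' @export
simulate_survival <- function(cfg, baseline_hazard = 0.1, n_subtypes = 6L) {
  stopifnot(inherits(cfg, "sim_config"), n_subtypes >= 3L)
  if (cfg$censor_rate >= 1) stop("censor_rate = 1 leaves no events: refused")
  with_subseed(cfg$seed, "simulate_survival", {
    n <- cfg$n_samples
    ng <- cfg$n_genes
    subtype <- sprintf("sub%d", 1 + (seq_len(n) - 1L) %% n_subtypes)
    p_on <- c(stats::runif(n_subtypes - 2L, 0.25, 0.75), 1, 0)
    names(p_on) <- sprintf("sub%d", seq_len(n_subtypes))
    states <- vapply(seq_len(ng), function(g) {
      as.integer(stats::runif(n) < p_on[subtype])
    }, integer(n))
    colnames(states) <- sprintf("g%04d", seq_len(ng))
    rownames(states) <- sprintf("s%04d", seq_len(n))
    hz <- baseline_hazard * exp(cfg$true_log_hr * states[, 1])
    te <- stats::rexp(n, hz)
    if (cfg$censor_rate > 0) {
      crate <- cfg$censor_rate / (1 - cfg$censor_rate) * mean(hz)
      tc <- stats::rexp(n, crate)
    } else {
      tc <- rep(Inf, n)
    }
    clinical <- data.frame(sample = rownames(states),
                           time = pmin(te, tc),
                           event = as.integer(te <= tc),
                           subtype = subtype, stringsAsFactors = FALSE)
    list(clinical = validate_table(clinical, "survival"), states = states,
         truth = list(causal_gene = "g0001", true_log_hr = cfg$true_log_hr,
                      uniform_subtypes = names(p_on)[p_on %in% c(0, 1)],
                      config = cfg))
  })
}

#' Simulate three ranked splicing-event lists with controlled overlap
#'
#' A shared universe of `n_events` events (five rMATS types, inclusion or
#' exclusion direction) receives one latent quality value; each list's
#' ranking score is a Gaussian-copula mixture with pairwise correlation
#' `overlap_rho` (1 = identical rankings, 0 = independent). Within each
#' (type, direction) partition, FDR increases and |dPSI| decreases with
#' rank so the ranking key `-log10(FDR) * |dPSI|` is consistent with rank.
#'
#' @param cfg a [sim_config()].
#' @return List: `lists` (three event data frames in the `events` schema),
#'   `truth` (list with `latent_rank`, `overlap_rho`, `config`).
#' @export
simulate_event_lists <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  with_subseed(cfg$seed, "simulate_event_lists", {
    N <- cfg$n_events
    ids <- sprintf("e%05d", seq_len(N))
    type <- sample(c("RI", "SE", "A5SS", "A3SS", "MXE"), N, replace = TRUE)
    direction <- sample(c("inclusion", "exclusion"), N, replace = TRUE)
    latent <- stats::rnorm(N)
    rho <- cfg$overlap_rho
    lists <- lapply(1:3, function(l) {
      score <- sqrt(rho) * latent +
        if (rho < 1) sqrt(1 - rho) * stats::rnorm(N) else 0
      df <- data.frame(event_id = ids, type = type, direction = direction,
                       score = score, stringsAsFactors = FALSE)
      part <- interaction(df$type, df$direction, drop = TRUE)
      df$rank_in_part <- stats::ave(-df$score, part, FUN = rank)
      np <- stats::ave(rep(1, N), part, FUN = sum)
      df$fdr <- df$rank_in_part / (np + 1)
      mag <- 0.02 + 0.6 * (1 - (df$rank_in_part - 1) / np)
      df$delta_psi <- ifelse(df$direction == "inclusion", mag, -mag)
      df$psi_ctrl <- stats::runif(N, 0.2, 0.8)
      df$psi_trt <- pmin(pmax(df$psi_ctrl + df$delta_psi, 0), 1)
      validate_table(df[c("event_id", "type", "direction", "delta_psi",
                          "fdr", "psi_ctrl", "psi_trt")], "events")
    })
    list(lists = lists,
         truth = list(latent_rank = rank(-latent), overlap_rho = rho,
                      config = cfg))
  })
}

#' Simulate a pull-down proteomics intensity table
#'
#' Two target replicates plus scramble and beads controls. Background
#' intensities are log-normal; planted enriched proteins (fraction
#' `active_fraction`) receive a 20-fold intensity boost in both target
#' replicates (comfortably above the 4x normalized threshold) and 1-5
#' unique peptides in both replicates. Decoys include proteins with high
#' target intensity but zero peptides in one replicate, which must fail the
#' filter.
#'
#' @param cfg a [sim_config()].
#' @param enrich_fold raw target fold for planted proteins (default 20).
#' @return List: `intensities` (protein x sample matrix; columns
#'   `target_1`, `target_2`, `scramble`, `beads`), `peptides` (matching
#'   unique-peptide count matrix), `truth` (list with `enriched_proteins`,
#'   `peptide_decoys`, `config`).
#' @export
simulate_proteomics <- function(cfg, enrich_fold = 20) {
  stopifnot(inherits(cfg, "sim_config"))
  with_subseed(cfg$seed, "simulate_proteomics", {
    np <- cfg$n_proteins
    ids <- sprintf("P%04d", seq_len(np))
    samples <- c("target_1", "target_2", "scramble", "beads")
    base <- exp(stats::rnorm(np, log(1e6), 1))
    m <- vapply(samples, function(s) base * exp(stats::rnorm(np, 0, 0.2)),
                numeric(np))
    rownames(m) <- ids
    n_enr <- round(cfg$active_fraction * np)
    enr <- sort(sample.int(np, n_enr))
    m[enr, c("target_1", "target_2")] <- m[enr, c("target_1", "target_2")] *
      enrich_fold
    # decoys: strong target signal but a missing peptide in one replicate
    rest <- setdiff(seq_len(np), enr)
    decoy <- sort(sample(rest, max(1L, round(0.01 * np))))
    m[decoy, c("target_1", "target_2")] <-
      m[decoy, c("target_1", "target_2")] * enrich_fold
    pep <- matrix(stats::rpois(np * 4, 1), np, 4,
                  dimnames = list(ids, samples))
    pep[enr, c("target_1", "target_2")] <-
      matrix(sample(1:5, 2 * n_enr, replace = TRUE), n_enr, 2)
    pep[decoy, "target_1"] <- sample(1:5, length(decoy), replace = TRUE)
    pep[decoy, "target_2"] <- 0L
    list(intensities = m, peptides = pep,
         truth = list(enriched_proteins = ids[enr],
                      peptide_decoys = ids[decoy], config = cfg))
  })
}

#' Write a simulated accessibility dataset to disk
#'
#' Writes the gene annotation as BED and each sample's coverage as
#' bedGraph, in the schemas the readers in this package consume.
#'
#' @param sim output of [simulate_accessibility()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_accessibility <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(genes = file.path(dir, "genes.bed"))
  write_intervals(sim$genes, paths["genes"])
  for (s in names(sim$tracks)) {
    p <- file.path(dir, paste0("coverage_", s, ".bedgraph"))
    write_bedgraph(sim$tracks[[s]], p)
    paths[s] <- p
  }
  invisible(paths)
}
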