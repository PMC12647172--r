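#' Normalize intensities to each sample's total
#'
#' Divides every value by its sample (column) total, so normalized
#' intensities sum to 1 within each sample. Makes the downstream enrichment
#' filter scale-invariant to raw intensity units.
#'
#' @param intensities numeric matrix or data frame, proteins x samples.
#' @return Matrix of the same shape with unit column sums.
#' @export
normalize_total <- function(intensities) {
  m <- as.matrix(intensities)
  tot <- colSums(m)
  if (any(tot <= 0)) stop("zero-total sample: cannot normalize")
  sweep(m, 2, tot, "/")
}

#' Pull-down enrichment filter for RNA-interacting proteins
#'
#' A protein is called enriched when (a) it has at least one unique peptide
#' in both target pull-down replicates and (b) the minimum log2 ratio of
#' normalized target intensity over both controls (scramble and beads)
#' exceeds `min_log2`. The ratio uses the minimum of the two target
#' replicates over each control ("minimum log2(intensity ratio)"); zero
#' control values are floored at the smallest nonzero normalized intensity
#' in that control sample before taking logs.
#'
#' @param normalized normalized intensity matrix (from [normalize_total()]);
#'   rownames are protein ids.
#' @param peptides matrix of unique-peptide counts with the two target
#'   columns.
#' @param targets character vector of the two target replicate columns.
#' @param controls character vector of the control columns (scramble,
#'   beads).
#' @param min_log2 enrichment threshold on the minimum log2 ratio
#'   (default 2).
#' @param ratio `"min"` (default) uses the minimum target replicate;
#'   `"mean"` uses the replicate mean.
#' @return `data.frame`: `protein_id`, `min_log2_ratio`, `peptides_ok`,
#'   `enriched`.
#' @export
enrich_filter <- function(normalized, peptides, targets, controls,
                          min_log2 = 2, ratio = c("min", "mean")) {
  ratio <- match.arg(ratio)
  m <- as.matrix(normalized)
  if (!all(targets %in% colnames(m)) || !all(controls %in% colnames(m))) {
    stop("target/control columns absent from normalized matrix")
  }
  stopifnot(length(targets) == 2L, length(controls) >= 1L)
  tgt <- if (ratio == "min") {
    do.call(pmin, as.data.frame(m[, targets, drop = FALSE]))
  } else {
    rowMeans(m[, targets, drop = FALSE])
  }
  ratios <- sapply(controls, function(cc) {
    ctrl <- m[, cc]
    floorv <- min(ctrl[ctrl > 0])
    if (any(ctrl == 0)) {
      message(sum(ctrl == 0), " zero value(s) in control '", cc,
              "' floored at smallest nonzero")
    }
    log2(tgt / pmax(ctrl, floorv))
  })
  min_ratio <- apply(matrix(ratios, nrow = nrow(m)), 1, min)
  pep <- as.matrix(peptides)[, targets, drop = FALSE]
  pep_ok <- rowSums(pep >= 1) == 2L
  data.frame(protein_id = rownames(m), min_log2_ratio = min_ratio,
             peptides_ok = pep_ok, enriched = pep_ok & min_ratio > min_log2,
             stringsAsFactors = FALSE, row.names = NULL)
}
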