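#' Genomic interval table
#'
#' Construct and validate a strand-aware interval table using the BED
#' convention: 0-based, half-open coordinates. All internal coordinates in
#' this package follow this convention; 1-based inputs must be converted at
#' the boundary by the caller.
#'
#' @param chrom character contig names.
#' @param start,end integer coordinates, 0-based half-open (`start < end`).
#' @param id unique interval identifiers; defaults to `chrom:start-end`.
#' @param strand one of `"+"`, `"-"`, `"."` per interval.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `id`,
#'   `strand` and `length = end - start`.
#' @export
genomic_intervals <- function(chrom, start, end, id = NULL, strand = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  if (any(start != floor(start)) || any(end != floor(end))) {
    stop("interval coordinates must be integers")
  }
  if (any(start < 0) || any(start >= end)) {
    bad <- which(start < 0 | start >= end)[1]
    stop(sprintf("invalid interval at row %d: start=%s end=%s", bad,
                 start[bad], end[bad]))
  }
  if (is.null(id)) id <- sprintf("%s:%d-%d", chrom, start, end)
  if (is.null(strand)) strand <- rep(".", length(chrom))
  if (!all(strand %in% c("+", "-", "."))) {
    stop("strand must be one of '+', '-', '.'")
  }
  if (anyDuplicated(id)) stop("interval ids must be unique")
  data.frame(chrom = as.character(chrom), start = start, end = end,
             id = as.character(id), strand = as.character(strand),
             length = end - start, stringsAsFactors = FALSE)
}

#' Read a BED file of intervals
#'
#' @param path path to a tab-separated BED file (>= 3 columns).
#' @return An interval table as from [genomic_intervals()].
#' @export
read_intervals <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines) == 0L) {
    return(genomic_intervals(character(), integer(), integer()))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3L)) {
    stop("BED parse error at line ", which(ncol < 3L)[1], ": fewer than 3 columns")
  }
  chrom <- vapply(fields, `[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad)) stop("BED parse error at line ", bad[1],
                        ": non-integer coordinates")
  bad <- which(start >= end | start < 0)
  if (length(bad)) stop("BED parse error at line ", bad[1],
                        ": start >= end or negative start")
  id <- ifelse(ncol >= 4L, vapply(fields, function(f) f[min(4L, length(f))], ""),
               sprintf("%s:%d-%d", chrom, start, end))
  strand <- ifelse(ncol >= 6L, vapply(fields, function(f) f[min(6L, length(f))], ""),
                   ".")
  bad <- which(!strand %in% c("+", "-", "."))
  if (length(bad)) stop("BED parse error at line ", bad[1],
                        ": unknown strand symbol '", strand[bad[1]], "'")
  genomic_intervals(chrom, start, end, id, strand)
}

#' Write intervals as BED
#'
#' @param intervals interval table from [genomic_intervals()].
#' @param path output path.
#' @export
write_intervals <- function(intervals, path) {
  df <- data.frame(intervals$chrom, intervals$start, intervals$end,
                   intervals$id, 0L, intervals$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Fixed-bin coverage track
#'
#' A coverage track stores per-contig counts (or scores) at a fixed bin
#' width. For read-count tracks `total_reads` equals the sum of counts.
#'
#' @param bins named list of numeric vectors, one per contig.
#' @param bin_width bin width in bp.
#' @param total_reads total read count; defaults to the sum of all bins.
#' @return An object of class `coverage_track`.
#' @export
coverage_track <- function(bins, bin_width, total_reads = NULL) {
  stopifnot(is.list(bins), !is.null(names(bins)), bin_width >= 1)
  if (any(vapply(bins, function(b) any(b < 0, na.rm = TRUE), TRUE))) {
    stop("coverage counts must be nonnegative")
  }
  if (is.null(total_reads)) {
    total_reads <- sum(vapply(bins, function(b) sum(b, na.rm = TRUE), 0))
  }
  structure(list(bins = bins, bin_width = bin_width,
                 total_reads = total_reads),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("coverage_track: %d contig(s), bin width %d bp, total %s\n",
              length(x$bins), x$bin_width,
              format(x$total_reads, big.mark = ",")))
  invisible(x)
}

contig_lengths <- function(track) {
  vapply(track$bins, length, 0L) * track$bin_width
}

#' Write a coverage track as bedGraph
#' @param track a [coverage_track()].
#' @param path output path.
#' @export
write_bedgraph <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- track$bin_width
  for (chrom in names(track$bins)) {
    b <- track$bins[[chrom]]
    n <- length(b)
    writeLines(sprintf("%s\t%d\t%d\t%g", chrom, (seq_len(n) - 1L) * w,
                       seq_len(n) * w, b), con)
  }
  invisible(path)
}

#' Read a fixed-bin bedGraph into a coverage track
#' @param path bedGraph path; every record must span exactly `bin_width` bp
#'   and start on a bin boundary.
#' @param bin_width expected bin width in bp.
#' @export
read_bedgraph <- function(path, bin_width) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = c("character", "numeric", "numeric",
                                         "numeric"))
  if (nrow(df) && any(df$end - df$start != bin_width | df$start %% bin_width != 0)) {
    stop("bedGraph records must be aligned fixed bins of width ", bin_width)
  }
  bins <- lapply(split(df, df$chrom), function(d) {
    n <- max(d$end) / bin_width
    v <- numeric(n)
    v[d$start / bin_width + 1L] <- d$value
    v
  })
  coverage_track(bins[unique(df$chrom)], bin_width)
}

# Continuous "integral" of binned counts up to bp position x (density =
# count / bin_width within each bin). Vectorized in x.
bin_integral <- function(bins, bin_width, x) {
  cum <- c(0, cumsum(bins))
  i <- pmin(pmax(floor(x / bin_width), 0), length(bins))
  frac <- x / bin_width - i
  partial <- ifelse(i < length(bins), bins[i + 1L] * frac, 0)
  cum[i + 1L] + partial
}

# Raw (unrounded) weighted count over [start, end) on one contig.
window_count <- function(track, chrom, start, end) {
  b <- track$bins[[chrom]]
  if (is.null(b)) stop("contig not present in track: ", chrom)
  bin_integral(b, track$bin_width, end) - bin_integral(b, track$bin_width, start)
}

#' Extract per-interval read counts from a coverage track
#'
#' Sums bin counts overlapping each interval, weighting partial bins by their
#' overlap fraction, and rounds half-up to an integer. Strand is ignored.
#'
#' @param track a [coverage_track()].
#' @param intervals an interval table from [genomic_intervals()].
#' @return Integer vector of counts named by interval id.
#' @export
extract_counts <- function(track, intervals) {
  unknown <- setdiff(unique(intervals$chrom), names(track$bins))
  if (length(unknown)) stop("interval contig(s) not in track: ",
                            paste(unknown, collapse = ", "))
  out <- numeric(nrow(intervals))
  for (chrom in unique(intervals$chrom)) {
    sel <- intervals$chrom == chrom
    b <- track$bins[[chrom]]
    out[sel] <- bin_integral(b, track$bin_width, intervals$end[sel]) -
      bin_integral(b, track$bin_width, intervals$start[sel])
  }
  stats::setNames(round_half_up(out), intervals$id)
}

#' Average normalized score over a compilation of tracks
#'
#' For each interval, takes the mean within-interval score in each track
#' (bins without data contribute `NA` and are excluded), then averages over
#' tracks. Used e.g. to compile replicate nuclear-speckle proximity
#' (SON TSA-seq) tracks into a single per-gene score.
#'
#' @param tracks list of score [coverage_track()]s (values may be `NA`).
#' @param intervals interval table.
#' @return Numeric vector of mean scores (NA where no track has data).
#' @export
average_speckle_score <- function(tracks, intervals) {
  if (length(tracks) < 1L) stop("at least one track required")
  per_track <- vapply(tracks, function(tr) {
    w <- tr$bin_width
    vapply(seq_len(nrow(intervals)), function(i) {
      b <- tr$bins[[intervals$chrom[i]]]
      if (is.null(b)) return(NA_real_)
      i0 <- floor(intervals$start[i] / w) + 1L
      i1 <- ceiling(intervals$end[i] / w)
      vals <- b[i0:min(i1, length(b))]
      if (all(is.na(vals))) NA_real_ else mean(vals, na.rm = TRUE)
    }, 0)
  }, numeric(nrow(intervals)))
  per_track <- matrix(per_track, nrow = nrow(intervals))
  out <- rowMeans(per_track, na.rm = TRUE)
  out[!is.finite(out)] <- NA_real_
  stats::setNames(out, intervals$id)
}

# ---- typed TSV tables -------------------------------------------------------

table_schemas <- list(
  ir = c("transcript_id", "intron_id", "chrom", "start", "end", "strand"),
  events = c("event_id", "type", "delta_psi", "fdr", "direction"),
  survival = c("sample", "time", "event", "subtype"),
  proteomics = c("protein_id"),
  features = c("row_id")
)

#' Read a typed, validated TSV table
#'
#' Schemas mirror the tables the pipeline consumes: IRFinder-style per-intron
#' ratios (`ir`, with per-sample `ir_`, `cpm_`, `flank5_`, `flank3_` column
#' groups), rMATS-style events (`events`), clinical survival tables
#' (`survival`), pull-down proteomics (`proteomics`, with `intensity_` and
#' `peptides_` column groups) and feature matrices (`features`). Extra
#' columns are passed through.
#'
#' @param path TSV path with a header row.
#' @param schema one of `"ir"`, `"events"`, `"survival"`, `"proteomics"`,
#'   `"features"`.
#' @return Validated `data.frame`.
#' @export
read_table <- function(path, schema = c("ir", "events", "survival",
                                        "proteomics", "features")) {
  schema <- match.arg(schema)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  validate_table(df, schema)
}

#' @rdname read_table
#' @param df data frame to validate in place of a file.
#' @export
validate_table <- function(df, schema = c("ir", "events", "survival",
                                          "proteomics", "features")) {
  schema <- match.arg(schema)
  req <- table_schemas[[schema]]
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop(sprintf("schema '%s': missing required column(s): %s", schema,
                 paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) return(df)
  if (schema == "ir") {
    irc <- grep("^ir_", names(df), value = TRUE)
    if (length(irc) == 0L) stop("schema 'ir': no ir_<sample> columns")
    for (cn in irc) {
      bad <- which(!is.finite(df[[cn]]) | df[[cn]] < 0 | df[[cn]] > 1)
      if (length(bad)) stop(sprintf("schema 'ir': %s out of [0,1] at row %d",
                                    cn, bad[1]))
    }
    for (cn in grep("^(cpm_|flank5_|flank3_)", names(df), value = TRUE)) {
      bad <- which(!is.finite(df[[cn]]) | df[[cn]] < 0)
      if (length(bad)) stop(sprintf("schema 'ir': %s negative at row %d",
                                    cn, bad[1]))
    }
  } else if (schema == "events") {
    ok <- df$type %in% c("RI", "SE", "A5SS", "A3SS", "MXE")
    if (!all(ok)) stop("schema 'events': unknown event type '",
                       df$type[!ok][1], "'")
    if (any(abs(df$delta_psi) > 1)) stop("schema 'events': |delta_psi| > 1")
    if (any(df$fdr < 0 | df$fdr > 1)) stop("schema 'events': fdr out of [0,1]")
    if (!all(df$direction %in% c("inclusion", "exclusion"))) {
      stop("schema 'events': direction must be inclusion/exclusion")
    }
  } else if (schema == "survival") {
    if (any(df$time < 0)) stop("schema 'survival': negative time")
    if (!all(df$event %in% c(0, 1))) stop("schema 'survival': event must be 0/1")
  } else if (schema == "proteomics") {
    if (!length(grep("^intensity_", names(df)))) {
      stop("schema 'proteomics': no intensity_<sample> columns")
    }
  }
  df
}

#' Write a table as TSV
#' @param df data frame.
#' @param path output path.
#' @export
write_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
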