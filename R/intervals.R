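#' Genomic intervals and scored peaks
#'
#' Intervals are plain data frames in BED convention: 0-based, half-open
#' `[start, end)`. A scored peak additionally carries the peak caller's
#' evidence columns (summit, counts, fold enrichment, -log10 q-value).
#'
#' @name intervals
NULL

#' Construct a table of genomic intervals
#'
#' @param chrom Character vector of chromosome names.
#' @param start 0-based inclusive start positions (non-negative).
#' @param end 0-based exclusive end positions; must satisfy `start < end`.
#' @param strand Optional strand, one of `"+"`, `"-"`, `"*"`; recycled.
#'
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = "*") {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    strand = rep_len(as.character(strand), n),
    stringsAsFactors = FALSE
  )
  validate_intervals(df)
  df
}

validate_intervals <- function(df, what = "interval table") {
  required <- c("chrom", "start", "end")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("%s lacks column(s): %s", what,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  if (nrow(df) == 0L) return(invisible(df))
  if (any(is.na(df$start)) || any(is.na(df$end))) {
    stop(sprintf("%s has missing coordinates", what), call. = FALSE)
  }
  if (any(df$start < 0)) {
    stop(sprintf("%s has negative start positions", what), call. = FALSE)
  }
  if (any(df$start >= df$end)) {
    stop(sprintf("%s has empty or inverted intervals (start >= end)", what),
         call. = FALSE)
  }
  invisible(df)
}

#' Construct a table of scored ChIP-seq peaks
#'
#' One row per peak: interval plus summit position (absolute coordinate of
#' maximum signal), read counts in peak and matched background, the peak
#' caller's fold enrichment and -log10 q-value.
#'
#' @param chrom,start,end Interval coordinates (0-based half-open).
#' @param summit Absolute summit position, in `[start, end)`; `NA` allowed.
#' @param read_count,background_count Non-negative read counts; `NA` when not
#'   supplied (several operations then require a coverage track).
#' @param fold_change Peak-caller fold enrichment (> 0).
#' @param neg_log10_q -log10 of the peak q-value (>= 0).
#' @param name Optional peak names.
#'
#' @return A `data.frame` with class `scored_peaks` prepended.
#' @export
scored_peaks <- function(chrom, start, end, summit = NA_real_,
                         read_count = NA_real_, background_count = NA_real_,
                         fold_change = NA_real_, neg_log10_q = NA_real_,
                         name = NA_character_) {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(
    chrom = rep_len(as.character(chrom), n),
    start = rep_len(as.numeric(start), n),
    end = rep_len(as.numeric(end), n),
    name = rep_len(as.character(name), n),
    summit = rep_len(as.numeric(summit), n),
    read_count = rep_len(as.numeric(read_count), n),
    background_count = rep_len(as.numeric(background_count), n),
    fold_change = rep_len(as.numeric(fold_change), n),
    neg_log10_q = rep_len(as.numeric(neg_log10_q), n),
    stringsAsFactors = FALSE
  )
  validate_peaks(df)
  class(df) <- c("scored_peaks", "data.frame")
  df
}

validate_peaks <- function(df, what = "peak table") {
  validate_intervals(df, what)
  if (nrow(df) == 0L) return(invisible(df))
  ok_summit <- is.na(df$summit) |
    (df$summit >= df$start & df$summit < df$end)
  if (!all(ok_summit)) {
    stop(sprintf("%s has summits outside their peak interval", what),
         call. = FALSE)
  }
  if (any(df$read_count < 0, na.rm = TRUE) ||
      any(df$background_count < 0, na.rm = TRUE)) {
    stop(sprintf("%s has negative read counts", what), call. = FALSE)
  }
  if (any(df$fold_change <= 0, na.rm = TRUE)) {
    stop(sprintf("%s has non-positive fold changes", what), call. = FALSE)
  }
  if (any(df$neg_log10_q < 0, na.rm = TRUE)) {
    stop(sprintf("%s has negative -log10 q-values", what), call. = FALSE)
  }
  invisible(df)
}

#' Normalize chromosome-name dialect
#'
#' Mixed "chr1"/"1" dialects are common across peak files and annotation
#' tables; comparisons in this package are exact-string, so inputs should be
#' normalized to one dialect first.
#'
#' @param chrom Character vector of chromosome names.
#' @param style `"asis"` (default, no change), `"strip"` (remove a leading
#'   "chr"), or `"add"` (ensure a leading "chr").
#' @return Character vector of the same length.
#' @export
normalize_chrom <- function(chrom, style = c("asis", "strip", "add")) {
  style <- match.arg(style)
  chrom <- as.character(chrom)
  switch(style,
    asis = chrom,
    strip = sub("^chr", "", chrom),
    add = ifelse(grepl("^chr", chrom), chrom, paste0("chr", chrom))
  )
}

#' Intersect two interval sets
#'
#' Reports every overlapping pair of intervals between two sets, requiring
#' overlap of at least one basepair after extending set A symmetrically by
#' `slop` bp. A pair `(a, b)` is reported when both intervals lie on the same
#' chromosome and `a$start - slop < b$end` and `b$start < a$end + slop`.
#'
#' @param a,b Interval data frames (columns `chrom`, `start`, `end`).
#' @param slop Non-negative symmetric extension (bp) applied to `a` before
#'   testing overlap. `slop = 1000` reproduces a +/-1 kb peak extension.
#'
#' @return A `data.frame` with columns `index_a`, `index_b` (1-based row
#'   indices into `a` and `b`), sorted by chromosome, then `a` start, then
#'   `b` start.
#' @export
intersect_intervals <- function(a, b, slop = 0) {
  validate_intervals(a, "set A")
  validate_intervals(b, "set B")
  if (length(slop) != 1L || is.na(slop) || slop < 0) {
    stop("slop must be a single non-negative number", call. = FALSE)
  }
  empty <- data.frame(index_a = integer(0), index_b = integer(0))
  if (nrow(a) == 0L || nrow(b) == 0L) return(empty)

  lev <- unique(c(a$chrom, b$chrom))
  gr_a <- GenomicRanges::GRanges(
    factor(a$chrom, levels = lev),
    IRanges::IRanges(pmax(0, a$start - slop) + 1L, a$end + slop)
  )
  gr_b <- GenomicRanges::GRanges(
    factor(b$chrom, levels = lev),
    IRanges::IRanges(b$start + 1L, b$end)
  )
  hits <- GenomicRanges::findOverlaps(gr_a, gr_b, minoverlap = 1L)
  ia <- S4Vectors::queryHits(hits)
  ib <- S4Vectors::subjectHits(hits)
  ord <- order(a$chrom[ia], a$start[ia], b$start[ib], ia, ib)
  data.frame(index_a = ia[ord], index_b = ib[ord])
}

#' Count distinct overlapping intervals per set
#'
#' The statistic behind statements like "N of |A| peaks in set A overlap M of
#' |B| peaks in set B": how many distinct members of each set participate in
#' at least one overlap pair. The two counts may differ because one interval
#' can overlap several on the other side.
#'
#' @inheritParams intersect_intervals
#' @return Named numeric vector `c(n_a_overlapping, n_b_overlapping)`.
#' @export
count_distinct_overlapping <- function(a, b, slop = 0) {
  pairs <- intersect_intervals(a, b, slop)
  c(n_a_overlapping = length(unique(pairs$index_a)),
    n_b_overlapping = length(unique(pairs$index_b)))
}

#' Write overlap pairs as a six-column TSV
#'
#' One line per pair: chromA, startA, endA, chromB, startB, endB.
#'
#' @param pairs Output of [intersect_intervals].
#' @param a,b The interval tables the pair indices refer to.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_overlap_pairs <- function(pairs, a, b, path) {
  df <- data.frame(
    chrom_a = a$chrom[pairs$index_a],
    start_a = format_coord(a$start[pairs$index_a]),
    end_a = format_coord(a$end[pairs$index_a]),
    chrom_b = b$chrom[pairs$index_b],
    start_b = format_coord(b$start[pairs$index_b]),
    end_b = format_coord(b$end[pairs$index_b])
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Threshold presets for peak filtering
#'
#' Fold-enrichment and -log10 q-value cutoff pairs: a single preset for the
#' primary factor (fold change > 5, -log10 q > 10) and liberal / standard /
#' stringent presets for the partner factor's pooled peaks
#' ((5, 25), (10, 60), (15, 200)).
#'
#' @format A named list of numeric vectors
#'   `c(min_fold_change = , min_neg_log10_q = )`.
#' @export
peak_filter_presets <- list(
  primary            = c(min_fold_change = 5,  min_neg_log10_q = 10),
  partner_liberal    = c(min_fold_change = 5,  min_neg_log10_q = 25),
  partner_standard   = c(min_fold_change = 10, min_neg_log10_q = 60),
  partner_stringent  = c(min_fold_change = 15, min_neg_log10_q = 200)
)

#' Filter peaks on fold enrichment and q-value
#'
#' Retains exactly the peaks with `fold_change > min_fold_change` AND
#' `neg_log10_q > min_neg_log10_q`. Both comparisons are strict, so peaks
#' sitting exactly on a threshold are removed. Input order is preserved;
#' filtering is idempotent.
#'
#' @param peaks A `scored_peaks` data frame.
#' @param min_fold_change,min_neg_log10_q Non-negative thresholds; see
#'   [peak_filter_presets] for the standard pairs.
#' @return The retained subset, same class and column layout.
#' @export
filter_peaks <- function(peaks, min_fold_change, min_neg_log10_q) {
  validate_peaks(peaks)
  if (min_fold_change < 0 || min_neg_log10_q < 0) {
    stop("thresholds must be non-negative", call. = FALSE)
  }
  keep <- !is.na(peaks$fold_change) & !is.na(peaks$neg_log10_q) &
    peaks$fold_change > min_fold_change & peaks$neg_log10_q > min_neg_log10_q
  out <- peaks[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
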