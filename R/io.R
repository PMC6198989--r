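#' File readers and writers
#'
#' Plain-text genomic formats used across the pipeline: BED6, ENCODE
#' narrowPeak, bedGraph, and the headered TSV tables for genotypes,
#' expression and summary statistics. Parse errors name the file and
#' 1-based line number. Writers emit files the corresponding reader
#' round-trips with value equality.
#'
#' @name io
NULL

read_delim_lines <- function(path, n_fields, what) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  lineno <- which(keep)
  bad <- which(vapply(fields, length, 1L) < n_fields)
  if (length(bad) > 0L) {
    stop(sprintf("malformed %s in '%s' at line %d: expected %d tab-separated fields, found %d",
                 what, path, lineno[bad[1L]], n_fields,
                 length(fields[[bad[1L]]])), call. = FALSE)
  }
  list(fields = fields, lineno = lineno)
}

parse_numeric_col <- function(values, lineno, path, colname) {
  out <- suppressWarnings(as.numeric(values))
  bad <- which(is.na(out) & !is.na(values) & values != "." & values != "NA")
  if (length(bad) > 0L) {
    stop(sprintf("malformed value '%s' for %s in '%s' at line %d",
                 values[bad[1L]], colname, path, lineno[bad[1L]]),
         call. = FALSE)
  }
  out
}

col_of <- function(parsed, i) vapply(parsed$fields, `[[`, "", i)

#' Read an ENCODE narrowPeak file
#'
#' 10-column BED extension from MACS2 and the ENCODE pipelines. Column 7
#' (signalValue) is taken as the fold enrichment, column 9 (qValue) as the
#' -log10 q-value, and column 10 (peak) as the summit offset from `start`,
#' converted to an absolute position; `-1` and `.` sentinels become `NA`.
#'
#' @param path Path to a narrowPeak file.
#' @return A `scored_peaks` data frame (read counts `NA`; supply them via
#'   [attach_counts] or a coverage track).
#' @export
read_narrowpeak <- function(path) {
  parsed <- read_delim_lines(path, 10L, "narrowPeak line")
  ln <- parsed$lineno
  start <- parse_numeric_col(col_of(parsed, 2L), ln, path, "start")
  end <- parse_numeric_col(col_of(parsed, 3L), ln, path, "end")
  signal <- parse_numeric_col(col_of(parsed, 7L), ln, path, "signalValue")
  qval <- parse_numeric_col(col_of(parsed, 9L), ln, path, "qValue")
  offset <- parse_numeric_col(col_of(parsed, 10L), ln, path, "peak offset")
  signal[!is.na(signal) & signal < 0] <- NA
  qval[!is.na(qval) & qval < 0] <- NA
  offset[!is.na(offset) & offset < 0] <- NA
  nm <- col_of(parsed, 4L)
  nm[nm == "."] <- NA_character_
  scored_peaks(
    chrom = col_of(parsed, 1L), start = start, end = end,
    summit = start + offset, fold_change = signal, neg_log10_q = qval,
    name = nm
  )
}

#' Write peaks as narrowPeak
#'
#' @param peaks A `scored_peaks` data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_narrowpeak <- function(peaks, path) {
  validate_peaks(peaks)
  sentinel <- function(x) ifelse(is.na(x), -1, x)
  df <- data.frame(
    peaks$chrom, format_coord(peaks$start), format_coord(peaks$end),
    ifelse(is.na(peaks$name), ".", peaks$name), 0L, ".",
    sentinel(peaks$fold_change), -1, sentinel(peaks$neg_log10_q),
    format_coord(ifelse(is.na(peaks$summit), -1, peaks$summit - peaks$start))
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

format_coord <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read a BED6 file as intervals
#'
#' Only the first six columns are used; columns 4-6 (name, score, strand)
#' are optional in the input.
#'
#' @param path Path to a BED file with at least 3 columns.
#' @return An interval `data.frame` (`chrom`, `start`, `end`, `name`,
#'   `score`, `strand`).
#' @export
read_bed6 <- function(path) {
  parsed <- read_delim_lines(path, 3L, "BED line")
  ln <- parsed$lineno
  nf <- vapply(parsed$fields, length, 1L)
  get_opt <- function(i, default) {
    vapply(seq_along(parsed$fields), function(j) {
      if (nf[j] >= i) parsed$fields[[j]][i] else default
    }, "")
  }
  score <- parse_numeric_col(get_opt(5L, "0"), ln, path, "score")
  df <- data.frame(
    chrom = col_of(parsed, 1L),
    start = parse_numeric_col(col_of(parsed, 2L), ln, path, "start"),
    end = parse_numeric_col(col_of(parsed, 3L), ln, path, "end"),
    name = get_opt(4L, "."),
    score = ifelse(is.na(score), 0, score),
    strand = get_opt(6L, "*"),
    stringsAsFactors = FALSE
  )
  validate_intervals(df, sprintf("BED file '%s'", path))
  df
}

#' Write intervals as BED6
#' @param intervals Interval data frame; optional `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed6 <- function(intervals, path) {
  validate_intervals(intervals)
  n <- nrow(intervals)
  df <- data.frame(
    intervals$chrom,
    format_coord(intervals$start), format_coord(intervals$end),
    if (!is.null(intervals$name)) ifelse(is.na(intervals$name), ".", intervals$name) else rep(".", n),
    if (!is.null(intervals$score)) intervals$score else rep(0L, n),
    if (!is.null(intervals$strand)) ifelse(intervals$strand %in% c("+", "-"), intervals$strand, ".") else rep(".", n)
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph coverage file
#'
#' @param path Path to a 4-column bedGraph (chrom, start, end, value).
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path) {
  parsed <- read_delim_lines(path, 4L, "bedGraph line")
  ln <- parsed$lineno
  df <- data.frame(
    chrom = col_of(parsed, 1L),
    start = parse_numeric_col(col_of(parsed, 2L), ln, path, "start"),
    end = parse_numeric_col(col_of(parsed, 3L), ln, path, "end"),
    value = parse_numeric_col(col_of(parsed, 4L), ln, path, "value"),
    stringsAsFactors = FALSE
  )
  validate_intervals(df, sprintf("bedGraph file '%s'", path))
  df
}

#' Write a bedGraph coverage table
#' @param coverage Data frame with `chrom`, `start`, `end`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(coverage, path) {
  utils::write.table(
    data.frame(coverage$chrom, format_coord(coverage$start),
               format_coord(coverage$end), coverage$value),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Turn a bedGraph table into per-chromosome coverage vectors
#'
#' @param coverage Data frame as returned by [read_bedgraph].
#' @return An [IRanges::RleList] of per-base coverage, one run-length encoded
#'   vector per chromosome, 1-based indexing (base at 0-based position p is
#'   element p + 1).
#' @export
coverage_tracks <- function(coverage) {
  validate_intervals(coverage, "coverage table")
  gr <- GenomicRanges::GRanges(
    coverage$chrom,
    IRanges::IRanges(coverage$start + 1L, coverage$end)
  )
  GenomicRanges::coverage(gr, weight = coverage$value)
}

#' Read a headered TSV table
#'
#' @param path Path; first line is a header.
#' @param required Character vector of column names that must be present.
#' @return A `data.frame`.
#' @export
read_tsv_table <- function(path, required = character(0)) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "", check.names = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop(sprintf("'%s' lacks required column(s): %s", path,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  df
}

#' Write a headered TSV table
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample-by-variant dosage matrix from TSV
#'
#' First column is the sample id; remaining columns are variant ids holding
#' risk-allele dosages in {0, 1, 2}.
#'
#' @param path Path to the TSV.
#' @return Numeric matrix, samples in rows, variants in columns.
#' @export
read_dosage_tsv <- function(path) {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1L]])
  bad <- !is.na(m) & !(m %in% c(0, 1, 2))
  if (any(bad)) {
    stop(sprintf("'%s' has dosages outside {0,1,2}", path), call. = FALSE)
  }
  m
}

#' Read an expression vector from a two-column TSV
#'
#' @param path TSV with columns `sample` and `value` (header required).
#' @return Named numeric vector.
#' @export
read_expression_tsv <- function(path) {
  df <- read_tsv_table(path, required = c("sample", "value"))
  stats::setNames(as.numeric(df$value), as.character(df$sample))
}

#' Read a summary-statistics table
#'
#' @param path TSV with header columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `p`.
#' @return A `data.frame` with those columns.
#' @export
read_sumstats_tsv <- function(path) {
  read_tsv_table(path,
    required = c("variant_id", "effect_allele", "other_allele", "beta", "p"))
}

#' Read a gene annotation table
#'
#' @param path TSV with header columns `gene_id`, `chrom`, `strand`, `tss`.
#' @return A `data.frame` of gene models (one TSS per row).
#' @export
read_gene_table <- function(path) {
  read_tsv_table(path, required = c("gene_id", "chrom", "strand", "tss"))
}

#' Extract risk-allele dosages from a VCF
#'
#' Dosages are counted from the GT field as the number of ALT alleles per
#' sample, so the ALT allele is taken as the counted (risk) allele; use the
#' variant metadata to re-orient downstream if the risk allele is REF.
#'
#' @param path Path to a VCF (uncompressed or bgzipped).
#' @return Numeric matrix, samples x variants, values in {0, 1, 2} or `NA`.
#' @export
read_vcf_dosages <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the 'vcfR' package; alternatively supply a dosage TSV",
         call. = FALSE)
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    ifelse(is.na(x) | grepl("\\.", x),
           NA_real_,
           vapply(strsplit(gsub("\\|", "/", x), "/", fixed = TRUE),
                  function(a) sum(a != "0"), 0))
  }
  m <- apply(gt, c(1, 2), count_alt)
  t(m)
}

#' Attach precomputed read and background counts to peaks
#'
#' Joins a counts table onto a peak table by exact coordinates.
#'
#' @param peaks A `scored_peaks` data frame.
#' @param counts Data frame with `chrom`, `start`, `end`, `read_count`,
#'   `background_count`.
#' @return `peaks` with its count columns filled where the join matched.
#' @export
attach_counts <- function(peaks, counts) {
  validate_peaks(peaks)
  key <- function(d) paste(d$chrom, format_coord(d$start), format_coord(d$end))
  idx <- match(key(peaks), key(counts))
  hit <- !is.na(idx)
  peaks$read_count[hit] <- counts$read_count[idx[hit]]
  peaks$background_count[hit] <- counts$background_count[idx[hit]]
  validate_peaks(peaks)
  peaks
}

#' Compute per-peak counts from a coverage track
#'
#' Read count is the coverage sum over the peak; the matched background is
#' the average of the sums over the immediately flanking windows of equal
#' length (upstream and downstream), the standard local-background
#' normalizer for ChIP-seq signal.
#'
#' @param peaks A `scored_peaks` data frame.
#' @param tracks An [IRanges::RleList] from [coverage_tracks].
#' @return `peaks` with `read_count` and `background_count` filled.
#' @export
counts_from_coverage <- function(peaks, tracks) {
  validate_peaks(peaks)
  sum_window <- function(chrom, from, to) {
    # [from, to) 0-based; clip at chromosome start, treat beyond-track as 0
    if (!(chrom %in% names(tracks))) return(0)
    r <- tracks[[chrom]]
    from <- max(from, 0)
    lo <- from + 1L
    hi <- min(to, length(r))
    if (lo > hi) return(0)
    sum(as.numeric(S4Vectors::window(r, lo, hi)))
  }
  n <- nrow(peaks)
  rc <- numeric(n)
  bg <- numeric(n)
  for (i in seq_len(n)) {
    w <- peaks$end[i] - peaks$start[i]
    rc[i] <- sum_window(peaks$chrom[i], peaks$start[i], peaks$end[i])
    up <- sum_window(peaks$chrom[i], peaks$start[i] - w, peaks$start[i])
    dn <- sum_window(peaks$chrom[i], peaks$end[i], peaks$end[i] + w)
    bg[i] <- (up + dn) / 2
  }
  peaks$read_count <- rc
  peaks$background_count <- bg
  peaks
}
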