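#' Differential co-binding of two transcription factors
#'
#' At loci where peaks of two ChIP-seq'd factors overlap, binding of each
#' factor is quantified as a background-normalized fold change (relative read
#' count in the peak versus its matched background), rescaled to a relative
#' 0-100 scale across the jointly bound sites, and classified as biased
#' toward one factor when the normalized fold changes differ by more than a
#' ratio threshold (default two-fold).
#'
#' @name cobinding
NULL

#' Background-normalized fold change
#'
#' Relative read count in a peak compared to its matched background region of
#' equal length: `(read_count + c) / (background_count + c)` with pseudocount
#' `c` guarding zero backgrounds. Strictly positive and monotone in
#' `read_count` for fixed background.
#'
#' @param read_count,background_count Non-negative counts (vectorized).
#' @param pseudocount Positive pseudocount `c`, default 1.
#' @return Numeric vector of normalized fold changes.
#' @export
normalized_fold_change <- function(read_count, background_count,
                                   pseudocount = 1) {
  if (any(is.na(read_count)) || any(is.na(background_count))) {
    stop("counts unavailable; supply a coverage track or a counts column",
         call. = FALSE)
  }
  if (any(read_count < 0) || any(background_count < 0)) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (pseudocount <= 0) stop("pseudocount must be positive", call. = FALSE)
  (read_count + pseudocount) / (background_count + pseudocount)
}

#' Min-max rescale to the relative 0-100 scale
#'
#' `(v - min) / (max - min) * 100`: order-preserving, minimum maps to 0,
#' maximum to 100. Intended for the normalized fold changes of one factor
#' across a set of jointly bound sites.
#'
#' @param values Numeric vector, at least 2 values, not all equal.
#' @return Numeric vector in `[0, 100]`.
#' @export
rescale_0_100 <- function(values) {
  if (length(values) < 2L) {
    stop("rescaling needs at least 2 values", call. = FALSE)
  }
  rng <- range(values)
  if (rng[1L] == rng[2L]) {
    stop("degenerate scale: all values equal", call. = FALSE)
  }
  (values - rng[1L]) / (rng[2L] - rng[1L]) * 100
}

#' Build joint binding sites from two peak sets
#'
#' Overlapping (or, with `slop > 0`, adjacent) peak pairs are resolved to one
#' joint site per locus: when a peak overlaps several on the other side, the
#' pair with the largest basepair overlap is kept (ties broken by larger
#' B read count, then leftmost coordinate), one-to-one. Each joint site
#' carries both factors' normalized fold changes, their 0-100 rescaling
#' across the joint-site set, and a bias label: `A_biased` when
#' `nfc_a / nfc_b > bias_threshold`, `B_biased` when
#' `nfc_b / nfc_a > bias_threshold`, otherwise `unbiased` (strict
#' inequalities).
#'
#' @param peaks_a,peaks_b `scored_peaks` tables carrying `read_count` and
#'   `background_count` (see [counts_from_coverage] / [attach_counts]).
#' @param slop Non-negative symmetric extension of A peaks before overlap
#'   testing (bp); 0 requires direct overlap.
#' @param bias_threshold Ratio above which a site is called biased; must be
#'   > 1. Default 2 (the two-fold rule).
#' @param pseudocount Pseudocount for [normalized_fold_change].
#' @param scale_a,scale_b Optional per-library scale factors (> 0) applied to
#'   each factor's read and background counts before normalization. Because
#'   the normalized fold change is a within-library ratio, these matter only
#'   through the pseudocount; they are exposed for count tables already on
#'   different scales.
#'
#' @return A `joint_sites` data frame: merged-span coordinates, row indices
#'   into both peak tables, overlap width, `nfc_a`, `nfc_b`, `scaled_a`,
#'   `scaled_b`, and `bias` (factor with levels `A_biased`, `B_biased`,
#'   `unbiased`).
#' @export
build_joint_sites <- function(peaks_a, peaks_b, slop = 0,
                              bias_threshold = 2, pseudocount = 1,
                              scale_a = 1, scale_b = 1) {
  if (bias_threshold <= 1) {
    stop("bias_threshold must be greater than 1", call. = FALSE)
  }
  if (scale_a <= 0 || scale_b <= 0) {
    stop("library scale factors must be positive", call. = FALSE)
  }
  validate_peaks(peaks_a, "peaks_a")
  validate_peaks(peaks_b, "peaks_b")
  pairs <- intersect_intervals(peaks_a, peaks_b, slop)
  if (nrow(pairs) == 0L) {
    out <- data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), index_a = integer(0),
                      index_b = integer(0), overlap_bp = numeric(0),
                      nfc_a = numeric(0), nfc_b = numeric(0),
                      scaled_a = numeric(0), scaled_b = numeric(0),
                      bias = factor(character(0),
                                    levels = c("A_biased", "B_biased", "unbiased")))
    class(out) <- c("joint_sites", "data.frame")
    return(out)
  }

  ia <- pairs$index_a
  ib <- pairs$index_b
  ov <- pmin(peaks_a$end[ia], peaks_b$end[ib]) -
    pmax(peaks_a$start[ia], peaks_b$start[ib])
  # greedy one-to-one resolution: largest overlap first, ties by larger B
  # read count, then leftmost merged coordinate
  rc_b <- peaks_b$read_count[ib]
  rc_b[is.na(rc_b)] <- -Inf
  ord <- order(-ov, -rc_b, peaks_a$chrom[ia],
               pmin(peaks_a$start[ia], peaks_b$start[ib]), ia, ib)
  used_a <- logical(nrow(peaks_a))
  used_b <- logical(nrow(peaks_b))
  keep <- logical(length(ord))
  for (k in seq_along(ord)) {
    i <- ord[k]
    if (!used_a[ia[i]] && !used_b[ib[i]]) {
      keep[k] <- TRUE
      used_a[ia[i]] <- TRUE
      used_b[ib[i]] <- TRUE
    }
  }
  sel <- ord[keep]
  ia <- ia[sel]
  ib <- ib[sel]

  nfc_a <- normalized_fold_change(scale_a * peaks_a$read_count[ia],
                                  scale_a * peaks_a$background_count[ia],
                                  pseudocount)
  nfc_b <- normalized_fold_change(scale_b * peaks_b$read_count[ib],
                                  scale_b * peaks_b$background_count[ib],
                                  pseudocount)
  scale_or_na <- function(v) {
    if (length(v) >= 2L && diff(range(v)) > 0) rescale_0_100(v) else {
      warning("degenerate normalized fold changes; 0-100 scale undefined",
              call. = FALSE)
      rep(NA_real_, length(v))
    }
  }
  ratio <- nfc_a / nfc_b
  bias <- ifelse(ratio > bias_threshold, "A_biased",
                 ifelse(1 / ratio > bias_threshold, "B_biased", "unbiased"))
  out <- data.frame(
    chrom = peaks_a$chrom[ia],
    start = pmin(peaks_a$start[ia], peaks_b$start[ib]),
    end = pmax(peaks_a$end[ia], peaks_b$end[ib]),
    index_a = ia, index_b = ib,
    overlap_bp = pmin(peaks_a$end[ia], peaks_b$end[ib]) -
      pmax(peaks_a$start[ia], peaks_b$start[ib]),
    nfc_a = nfc_a, nfc_b = nfc_b,
    scaled_a = scale_or_na(nfc_a), scaled_b = scale_or_na(nfc_b),
    bias = factor(bias, levels = c("A_biased", "B_biased", "unbiased")),
    stringsAsFactors = FALSE
  )
  ord2 <- order(out$chrom, out$start, out$end)
  out <- out[ord2, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("joint_sites", "data.frame")
  out
}

#' Summarize the bias classification of joint sites
#'
#' @param sites A `joint_sites` data frame from [build_joint_sites].
#' @return A `bias_summary` list: `n_joint`, `n_biased`, `n_a`, `n_b`,
#'   `frac_a`, `frac_b` (fractions of the biased sites; `NA` when no site is
#'   biased), and display percentages `pct_a`, `pct_b` rounded to the nearest
#'   integer.
#' @export
summarize_bias <- function(sites) {
  n_joint <- nrow(sites)
  n_a <- sum(sites$bias == "A_biased")
  n_b <- sum(sites$bias == "B_biased")
  n_biased <- n_a + n_b
  frac_a <- if (n_biased > 0) n_a / n_biased else NA_real_
  frac_b <- if (n_biased > 0) n_b / n_biased else NA_real_
  structure(
    list(n_joint = n_joint, n_biased = n_biased, n_a = n_a, n_b = n_b,
         frac_a = frac_a, frac_b = frac_b,
         pct_a = if (is.na(frac_a)) NA_real_ else round(100 * frac_a),
         pct_b = if (is.na(frac_b)) NA_real_ else round(100 * frac_b)),
    class = "bias_summary"
  )
}

#' @export
print.bias_summary <- function(x, ...) {
  cat("Joint-site bias summary\n")
  cat(sprintf("  joint sites:  %d\n", x$n_joint))
  cat(sprintf("  biased (>threshold-fold): %d\n", x$n_biased))
  if (!is.na(x$frac_a)) {
    cat(sprintf("  biased toward A: %d (%d%%)\n", x$n_a, x$pct_a))
    cat(sprintf("  biased toward B: %d (%d%%)\n", x$n_b, x$pct_b))
  } else {
    cat("  biased fractions: not applicable (no biased sites)\n")
  }
  invisible(x)
}

#' Summit-centered average signal profile
#'
#' Mean per-base signal in windows of +/- `halfwidth` bp around peak summits,
#' one series per coverage track — the data behind summit-anchored density
#' ("metaplot") figures. Windows truncated at a chromosome start contribute
#' only their defined offsets.
#'
#' @param summits Data frame with columns `chrom` and `pos` (absolute 0-based
#'   summit positions); must be non-empty.
#' @param tracks A named list of coverage tracks ([IRanges::RleList] or list
#'   of such objects, one element per track).
#' @param halfwidth Positive window half-width in bp (default 1000).
#' @return A `summit_profile` list: `halfwidth`, `positions`
#'   (-halfwidth..halfwidth) and `mean_signal`, a matrix with one row per
#'   offset and one column per track.
#' @export
summit_profile <- function(summits, tracks, halfwidth = 1000) {
  if (is.null(summits) || nrow(summits) == 0L) {
    stop("summit list is empty", call. = FALSE)
  }
  if (halfwidth < 1) stop("halfwidth must be positive", call. = FALSE)
  if (inherits(tracks, "RleList")) tracks <- list(track = tracks)
  if (length(tracks) > 0 && is.null(names(tracks))) {
    names(tracks) <- paste0("track", seq_along(tracks))
  }
  width <- 2L * halfwidth + 1L
  offsets <- seq.int(-halfwidth, halfwidth)
  mean_signal <- matrix(0, nrow = width, ncol = length(tracks),
                        dimnames = list(NULL, names(tracks)))
  for (t in seq_along(tracks)) {
    trk <- tracks[[t]]
    acc <- numeric(width)
    n_def <- numeric(width)
    for (i in seq_len(nrow(summits))) {
      chrom <- summits$chrom[i]
      pos <- summits$pos[i]
      # 0-based window positions pos-halfwidth .. pos+halfwidth
      win_lo <- pos - halfwidth
      def <- win_lo + seq_len(width) - 1L >= 0
      vals <- numeric(width)
      if (chrom %in% names(trk)) {
        r <- trk[[chrom]]
        lo <- max(win_lo, 0) + 1L            # 1-based into the Rle
        hi <- min(pos + halfwidth, length(r) - 1L) + 1L
        if (lo <= hi) {
          v <- as.numeric(S4Vectors::window(r, lo, hi))
          at <- (lo - 1L - win_lo) + seq_along(v)
          vals[at] <- v
        }
      }
      acc <- acc + ifelse(def, vals, 0)
      n_def <- n_def + def
    }
    mean_signal[, t] <- ifelse(n_def > 0, acc / n_def, NA_real_)
  }
  structure(
    list(halfwidth = halfwidth, positions = offsets,
         mean_signal = mean_signal, n_sites = nrow(summits)),
    class = "summit_profile"
  )
}

#' @export
print.summit_profile <- function(x, ...) {
  cat(sprintf("Summit profile: %d sites, +/-%d bp, %d track(s)\n",
              x$n_sites, x$halfwidth, ncol(x$mean_signal)))
  cat(sprintf("  mean signal at summit: %s\n",
              paste(sprintf("%s=%.3g", colnames(x$mean_signal),
                            x$mean_signal[x$halfwidth + 1L, ]),
                    collapse = ", ")))
  invisible(x)
}
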