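#' Basal-plus-extension peak-to-gene assignment
#'
#' Each gene gets a basal regulatory domain around its TSS (default 5 kb
#' upstream, 1 kb downstream, strand-aware) which is then extended outward in
#' both directions, up to a maximum (default 1 Mb), stopping early at the
#' nearest flanking gene's basal-domain edge when that is closer. Peaks are
#' assigned to every gene whose extended domain they overlap by at least one
#' basepair. Gene-set overlaps are summarized and tested against a background
#' universe with Fisher's exact test.
#'
#' @name gene_assignment
NULL

#' Basal regulatory domain of a TSS
#'
#' Strand-aware window around the TSS: `up` bp upstream and `down` bp
#' downstream of transcription (plus strand: `[tss - up, tss + down)`; minus
#' strand mirrored), clipped at position 0.
#'
#' @param tss Integer vector of TSS positions.
#' @param strand Character vector, `"+"` or `"-"`.
#' @param up,down Non-negative extents in bp (defaults 5000 and 1000); at
#'   least one must be positive.
#' @return Data frame with columns `start`, `end` (0-based half-open).
#' @export
basal_domain <- function(tss, strand, up = 5000, down = 1000) {
  if (up < 0 || down < 0) stop("up and down must be non-negative", call. = FALSE)
  if (up == 0 && down == 0) stop("basal domain would be empty", call. = FALSE)
  if (!all(strand %in% c("+", "-"))) {
    stop("strand must be '+' or '-' for every gene", call. = FALSE)
  }
  plus <- strand == "+"
  start <- ifelse(plus, tss - up, tss - down)
  end <- ifelse(plus, tss + down, tss + up)
  data.frame(start = pmax(0, start), end = end)
}

#' Build extended regulatory domains for a gene set
#'
#' Applies the basal-plus-extension rule: each gene's extended domain reaches
#' outward from its basal domain by up to `max_extension` bp on each side,
#' but stops at the nearest flanking gene's basal-domain edge when that edge
#' is closer. Basal domains themselves are never truncated by neighbors;
#' when a neighbor's basal domain overlaps a gene's own basal domain, the
#' extension on that side is zero.
#'
#' @param genes Data frame with columns `gene_id`, `chrom`, `strand`, `tss`;
#'   gene ids must be unique (collapse multi-isoform annotation first, e.g.
#'   with [collapse_tss]).
#' @param max_extension Maximum distal extension per side in bp (default 1e6).
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   clip domains at the right edge.
#' @param up,down Basal extents passed to [basal_domain].
#' @return A `regulatory_domains` data frame: `gene_id`, `chrom`, `strand`,
#'   `tss`, `basal_start`, `basal_end`, `ext_start`, `ext_end`.
#' @export
extend_domains <- function(genes, max_extension = 1e6, chrom_lengths = NULL,
                           up = 5000, down = 1000) {
  if (anyDuplicated(genes$gene_id)) {
    stop("duplicate gene_id in gene table; collapse isoforms first",
         call. = FALSE)
  }
  if (max_extension < 0) stop("max_extension must be non-negative", call. = FALSE)
  basal <- basal_domain(genes$tss, genes$strand, up, down)
  n <- nrow(genes)
  ext_start <- numeric(n)
  ext_end <- numeric(n)
  # lexicographic order used only to break exact basal-coordinate ties
  key_lt <- function(i, j) {
    (basal$start[i] < basal$start[j]) ||
      (basal$start[i] == basal$start[j] && basal$end[i] < basal$end[j]) ||
      (basal$start[i] == basal$start[j] && basal$end[i] == basal$end[j] && i < j)
  }
  for (i in seq_len(n)) {
    same <- which(genes$chrom == genes$chrom[i])
    left <- same[vapply(same, function(j) j != i && key_lt(j, i), TRUE)]
    right <- same[vapply(same, function(j) j != i && key_lt(i, j), TRUE)]
    lb <- basal$start[i] - max_extension
    if (length(left) > 0L) {
      lb <- max(lb, min(max(basal$end[left]), basal$start[i]))
    }
    rb <- basal$end[i] + max_extension
    if (length(right) > 0L) {
      rb <- min(rb, max(min(basal$start[right]), basal$end[i]))
    }
    ext_start[i] <- max(0, lb)
    ext_end[i] <- rb
  }
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[genes$chrom]
    has <- !is.na(len)
    ext_end[has] <- pmin(ext_end[has], len[has])
    basal$end[has] <- pmin(basal$end[has], len[has])
  }
  out <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom, strand = genes$strand,
    tss = genes$tss,
    basal_start = basal$start, basal_end = basal$end,
    ext_start = ext_start, ext_end = ext_end,
    stringsAsFactors = FALSE
  )
  class(out) <- c("regulatory_domains", "data.frame")
  out
}

#' Collapse a multi-isoform TSS table to one TSS per gene
#'
#' Keeps the 5'-most TSS per gene id: the smallest position for plus-strand
#' genes, the largest for minus-strand genes.
#'
#' @param genes Data frame with `gene_id`, `chrom`, `strand`, `tss`
#'   (possibly several rows per gene).
#' @return One row per gene id.
#' @export
collapse_tss <- function(genes) {
  pick <- function(d) {
    if (d$strand[1L] == "+") d[which.min(d$tss), , drop = FALSE]
    else d[which.max(d$tss), , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(genes, genes$gene_id), pick))
  rownames(out) <- NULL
  out[order(out$chrom, out$tss), , drop = FALSE]
}

#' Assign peaks to genes via extended regulatory domains
#'
#' A peak is assigned to every gene whose extended domain it overlaps by at
#' least one basepair; a peak may map to several genes, and peaks outside
#' every domain are reported as unassigned.
#'
#' @param peaks Interval data frame (`chrom`, `start`, `end`).
#' @param domains A `regulatory_domains` data frame from [extend_domains].
#' @return A list: `peak_to_genes` (list, one character vector of gene ids
#'   per peak), `gene_to_peaks` (named list of peak row indices per gene),
#'   `unassigned` (peak indices with no gene), `n_assignments`.
#' @export
assign_peaks <- function(peaks, domains) {
  validate_intervals(peaks, "peak table")
  dom <- data.frame(chrom = domains$chrom, start = domains$ext_start,
                    end = domains$ext_end, stringsAsFactors = FALSE)
  pairs <- intersect_intervals(peaks, dom, slop = 0)
  peak_to_genes <- rep(list(character(0)), nrow(peaks))
  if (nrow(pairs) > 0L) {
    sp <- unname(split(domains$gene_id[pairs$index_b], pairs$index_a))
    at <- unique(pairs$index_a)
    peak_to_genes[sort(at)] <- sp
  }
  gene_to_peaks <- split(
    pairs$index_a,
    factor(pairs$index_b, levels = seq_len(nrow(domains)))
  )
  names(gene_to_peaks) <- domains$gene_id
  list(
    peak_to_genes = peak_to_genes,
    gene_to_peaks = gene_to_peaks,
    unassigned = which(lengths(peak_to_genes) == 0L),
    n_assignments = nrow(pairs)
  )
}

#' Summarize the overlap of two gene sets
#'
#' @param genes_a,genes_b Character vectors (duplicates ignored).
#' @return A `gene_overlap` list: `n_a`, `n_b`, `n_shared`,
#'   `frac_of_a_shared`, and the display percentage `pct_of_a_shared`
#'   rounded to the nearest integer.
#' @export
gene_overlap_summary <- function(genes_a, genes_b) {
  a <- unique(genes_a)
  b <- unique(genes_b)
  shared <- length(intersect(a, b))
  frac <- if (length(a) > 0) shared / length(a) else NA_real_
  structure(
    list(n_a = length(a), n_b = length(b), n_shared = shared,
         frac_of_a_shared = frac,
         pct_of_a_shared = if (is.na(frac)) NA_real_ else round(100 * frac)),
    class = "gene_overlap"
  )
}

#' @export
print.gene_overlap <- function(x, ...) {
  cat(sprintf("Gene-set overlap: %d of %d set-A genes (%s%%) shared with %d set-B genes\n",
              x$n_shared, x$n_a,
              ifelse(is.na(x$pct_of_a_shared), "NA", x$pct_of_a_shared),
              x$n_b))
  invisible(x)
}

#' Fisher's exact test for gene-list overlap against a background
#'
#' Two-sided Fisher exact test on the 2x2 table {in A / not in A} x
#' {in B / not in B} over the supplied background universe. Genes in either
#' list but absent from the background are dropped with a warning.
#'
#' @param list_a,list_b Character vectors of gene ids.
#' @param background Character vector: the gene universe (non-empty).
#' @return A list: `odds_ratio`, `p_value`, `table` (the 2x2 matrix),
#'   `n_dropped` (genes removed for falling outside the background).
#' @export
gene_list_fisher <- function(list_a, list_b, background) {
  background <- unique(background)
  if (length(background) == 0L) {
    stop("background gene universe is empty", call. = FALSE)
  }
  a <- unique(list_a)
  b <- unique(list_b)
  dropped <- length(setdiff(a, background)) + length(setdiff(b, background))
  if (dropped > 0L) {
    warning(sprintf("%d gene(s) outside the background universe were dropped",
                    dropped), call. = FALSE)
    a <- intersect(a, background)
    b <- intersect(b, background)
  }
  k11 <- length(intersect(a, b))
  k10 <- length(a) - k11
  k01 <- length(b) - k11
  k00 <- length(background) - k11 - k10 - k01
  tab <- matrix(c(k11, k10, k01, k00), nrow = 2,
                dimnames = list(in_a = c("yes", "no"), in_b = c("yes", "no")))
  ft <- stats::fisher.test(tab, alternative = "two.sided")
  list(odds_ratio = unname(ft$estimate), p_value = ft$p.value,
       table = tab, n_dropped = dropped)
}
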