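# Independent oracles used to check the package's optimized implementations.
# These deliberately use the most direct (often brute-force) formulation.

# all-pairs interval overlap: (a.start - slop) < b.end and b.start < (a.end + slop)
brute_force_pairs <- function(a, b, slop = 0) {
  out <- list()
  k <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (a$chrom[i] == b$chrom[j] &&
          (a$start[i] - slop) < b$end[j] &&
          b$start[j] < (a$end[i] + slop)) {
        k <- k + 1L
        out[[k]] <- c(i, j)
      }
    }
  }
  if (k == 0L) return(data.frame(index_a = integer(0), index_b = integer(0)))
  m <- do.call(rbind, out)
  df <- data.frame(index_a = m[, 1L], index_b = m[, 2L])
  ord <- order(a$chrom[df$index_a], a$start[df$index_a], b$start[df$index_b],
               df$index_a, df$index_b)
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

random_intervals <- function(n, chroms = c("chr1", "chr2"), max_pos = 10000,
                             max_width = 300) {
  start <- sample.int(max_pos, n, replace = TRUE)
  data.frame(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + sample.int(max_width, n, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# two-sided Fisher exact p by exhaustive hypergeometric-tail enumeration:
# sum of the probabilities of all tables at least as extreme (point
# probability <= observed, with the same relative slack R's fisher.test uses)
hypergeom_fisher_p <- function(k11, n_a, n_b, n_bg) {
  support <- max(0L, n_a + n_b - n_bg):min(n_a, n_b)
  probs <- stats::dhyper(support, n_b, n_bg - n_b, n_a)
  p_obs <- stats::dhyper(k11, n_b, n_bg - n_b, n_a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# regulatory-domain oracle: vectorized sweep over basal edges sorted by
# (basal_start, basal_end, input order), per chromosome
sweep_domains_oracle <- function(genes, max_extension = 1e6,
                                 up = 5000, down = 1000) {
  plus <- genes$strand == "+"
  bs <- pmax(0, ifelse(plus, genes$tss - up, genes$tss - down))
  be <- ifelse(plus, genes$tss + down, genes$tss + up)
  ext_s <- numeric(nrow(genes))
  ext_e <- numeric(nrow(genes))
  for (chr in unique(genes$chrom)) {
    on <- which(genes$chrom == chr)
    ord <- on[order(bs[on], be[on], on)]
    n <- length(ord)
    prefix_max_end <- c(-Inf, cummax(be[ord]))[seq_len(n)]
    suffix_min_start <- rev(c(Inf, cummin(rev(bs[ord]))))[-1L]
    ext_s[ord] <- pmax(bs[ord] - max_extension,
                       pmin(prefix_max_end, bs[ord]), 0)
    ext_e[ord] <- pmin(be[ord] + max_extension,
                       pmax(suffix_min_start, be[ord]))
  }
  data.frame(gene_id = genes$gene_id, ext_start = ext_s, ext_end = ext_e,
             stringsAsFactors = FALSE)
}

# minimal peak table with counts, for joint-site tests
make_counted_peaks <- function(chrom, start, end, read_count,
                               background_count) {
  scored_peaks(chrom, start, end,
               read_count = read_count, background_count = background_count,
               fold_change = 10, neg_log10_q = 50)
}
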