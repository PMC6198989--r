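#' GWAS-eQTL effect-size concordance
#'
#' Merges disease GWAS and cis-eQTL summary statistics at stated significance
#' thresholds, harmonizes the eQTL effect sizes to the GWAS effect allele,
#' and correlates the two beta columns. A strong positive correlation for
#' risk-oriented betas indicates that the expression-raising alleles are the
#' risk-raising alleles, i.e. that higher expression tracks higher disease
#' risk.
#'
#' @name concordance
NULL

dedup_smallest_p <- function(df, label) {
  if (anyDuplicated(df$variant_id)) {
    n_dup <- sum(duplicated(df$variant_id))
    warning(sprintf("%d duplicate variant id(s) in %s table: keeping smallest p",
                    n_dup, label), call. = FALSE)
    df <- df[order(df$p), , drop = FALSE]
    df <- df[!duplicated(df$variant_id), , drop = FALSE]
  }
  df
}

#' Merge GWAS and eQTL summary statistics
#'
#' Inner join on `variant_id` after applying both p-value filters (strict
#' `<`). The eQTL beta is flipped in sign when its effect allele is the GWAS
#' record's other allele; variants whose alleles match neither way are
#' dropped and counted. Duplicate variant ids within a table keep the row
#' with the smallest p (with a warning).
#'
#' @param gwas,eqtl Data frames with columns `variant_id`, `effect_allele`,
#'   `other_allele`, `beta`, `p` (GWAS beta on the log odds-ratio scale;
#'   eQTL beta an expression slope). With `join = "position"` both tables
#'   additionally need `chrom` and `pos` columns.
#' @param gwas_p_max,eqtl_p_max Strict upper p-value bounds
#'   (defaults 1e-4 and 0.05).
#' @param join Join key: `"id"` (default, on `variant_id`) or `"position"`
#'   (on `chrom:pos`, for tables without shared ids).
#' @return A `merged_pairs` data frame: `variant_id`, `beta_gwas`,
#'   `beta_eqtl` (both oriented to the GWAS effect allele), with attributes
#'   `n_dropped_alleles` (irreconcilable-allele variants removed) and
#'   `n_flipped` (eQTL betas sign-flipped during harmonization).
#' @export
merge_summary <- function(gwas, eqtl, gwas_p_max = 1e-4, eqtl_p_max = 0.05,
                          join = c("id", "position")) {
  join <- match.arg(join)
  if (join == "position") {
    need <- c("chrom", "pos")
    if (!all(need %in% names(gwas)) || !all(need %in% names(eqtl))) {
      stop("positional join requires 'chrom' and 'pos' columns in both tables",
           call. = FALSE)
    }
    gwas$variant_id <- paste0(gwas$chrom, ":", gwas$pos)
    eqtl$variant_id <- paste0(eqtl$chrom, ":", eqtl$pos)
  }
  gwas <- dedup_smallest_p(gwas, "GWAS")
  eqtl <- dedup_smallest_p(eqtl, "eQTL")
  gwas <- gwas[gwas$p < gwas_p_max, , drop = FALSE]
  eqtl <- eqtl[eqtl$p < eqtl_p_max, , drop = FALSE]
  idx <- match(gwas$variant_id, eqtl$variant_id)
  hit <- !is.na(idx)
  g <- gwas[hit, , drop = FALSE]
  e <- eqtl[idx[hit], , drop = FALSE]
  same <- e$effect_allele == g$effect_allele & e$other_allele == g$other_allele
  swapped <- e$effect_allele == g$other_allele & e$other_allele == g$effect_allele
  bad <- !same & !swapped
  if (any(bad)) {
    warning(sprintf("%d variant(s) with irreconcilable alleles dropped",
                    sum(bad)), call. = FALSE)
  }
  out <- data.frame(
    variant_id = g$variant_id[!bad],
    beta_gwas = g$beta[!bad],
    beta_eqtl = ifelse(swapped[!bad], -e$beta[!bad], e$beta[!bad]),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "n_dropped_alleles") <- sum(bad)
  attr(out, "n_flipped") <- sum(swapped & !bad)
  class(out) <- c("merged_pairs", "data.frame")
  out
}

#' Correlate GWAS and eQTL effect sizes
#'
#' Pearson correlation of the harmonized beta columns with the two-sided
#' p-value from the t distribution (n - 2 df), plus the OLS slope and
#' intercept of `beta_eqtl ~ beta_gwas` for the trend line.
#'
#' @param pairs A `merged_pairs` data frame from [merge_summary] (at least 3
#'   rows, variation in both columns).
#' @return A [regression_result].
#' @export
beta_correlation <- function(pairs) {
  if (nrow(pairs) < 3L) {
    stop("insufficient overlap: fewer than 3 merged variants", call. = FALSE)
  }
  if (stats::sd(pairs$beta_gwas) == 0 || stats::sd(pairs$beta_eqtl) == 0) {
    stop("no variation in one of the beta columns", call. = FALSE)
  }
  fit_ols(pairs$beta_gwas, pairs$beta_eqtl,
          predictor = "GWAS beta (log OR)", response = "eQTL beta")
}
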