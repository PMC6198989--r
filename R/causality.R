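#' Cis-causality and direction-of-effect tests
#'
#' Links disease risk alleles near a gene to that gene's expression in a
#' genotyped cohort: single-variant eQTL regression of expression on
#' risk-allele dosage, and a burden regression in which samples carrying an
#' identical local haplotype profile (dosage vector over the selected risk
#' variants) are collapsed and their expression averaged before regressing
#' group mean expression on risk-allele burden. Collapsing removes the
#' inter-individual component of the variance, sharpening the additive
#' signal in regions of strong linkage disequilibrium.
#'
#' @name causality
NULL

#' Select cis risk variants around a gene
#'
#' Retains the variants on the gene's chromosome with position within
#' `window` bp of the gene body (`gene_start - window` to
#' `gene_end + window`, inclusive) and GWAS p-value strictly below `p_max`,
#' sorted by position.
#'
#' @param variants Data frame with columns `variant_id`, `chrom`, `pos`,
#'   `risk_allele`, `other_allele`, `beta`, `p` (GWAS effect oriented to the
#'   risk allele).
#' @param gene_chrom,gene_start,gene_end Gene body coordinates.
#' @param window Flanking window in bp (default 100000).
#' @param p_max GWAS significance cutoff, strict `<` (default 1e-6).
#' @return The retained rows, sorted by `pos`.
#' @export
select_cis_variants <- function(variants, gene_chrom, gene_start, gene_end,
                                window = 1e5, p_max = 1e-6) {
  if (gene_start > gene_end) {
    stop("gene_start must not exceed gene_end", call. = FALSE)
  }
  if (window < 0) stop("window must be non-negative", call. = FALSE)
  keep <- variants$chrom == gene_chrom &
    variants$pos >= gene_start - window &
    variants$pos <= gene_end + window &
    variants$p < p_max
  out <- variants[keep, , drop = FALSE]
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Orient effect sizes to the risk allele
#'
#' Flips the sign of `beta` on rows whose `effect_allele` is the non-risk
#' allele, so that positive betas always mean the risk allele increases the
#' outcome. Rows whose effect allele matches neither stated allele get
#' `NA` with a warning.
#'
#' @param variants Data frame with `effect_allele`, `risk_allele`,
#'   `other_allele`, `beta`.
#' @return The data frame with `beta` re-oriented and `effect_allele` set to
#'   the risk allele.
#' @export
orient_to_risk <- function(variants) {
  match_risk <- variants$effect_allele == variants$risk_allele
  match_other <- variants$effect_allele == variants$other_allele
  bad <- !match_risk & !match_other
  if (any(bad)) {
    warning(sprintf("%d variant(s) with irreconcilable effect allele set to NA",
                    sum(bad)), call. = FALSE)
  }
  variants$beta <- ifelse(match_risk, variants$beta,
                          ifelse(match_other, -variants$beta, NA_real_))
  variants$effect_allele <- ifelse(bad, variants$effect_allele,
                                   variants$risk_allele)
  variants
}

#' Single-variant eQTL regression
#'
#' Ordinary least-squares regression of expression on risk-allele dosage
#' (additive 0/1/2 coding): slope, Pearson r, and the two-sided p-value from
#' the t distribution with n - 2 degrees of freedom.
#'
#' @param dosage Numeric dosage vector; if named, aligned to `expression`
#'   by sample name.
#' @param expression Numeric expression vector (named or positionally
#'   aligned with `dosage`).
#' @return A [regression_result].
#' @export
single_variant_eqtl <- function(dosage, expression) {
  if (!is.null(names(dosage)) && !is.null(names(expression))) {
    shared <- intersect(names(dosage), names(expression))
    dosage <- dosage[shared]
    expression <- expression[shared]
  }
  if (length(dosage) != length(expression)) {
    stop("dosage and expression must cover the same samples", call. = FALSE)
  }
  ok <- !is.na(dosage) & !is.na(expression)
  dosage <- dosage[ok]
  expression <- expression[ok]
  if (length(dosage) < 3L) {
    stop("need at least 3 samples for the eQTL regression", call. = FALSE)
  }
  if (length(unique(dosage)) < 2L) {
    stop("monomorphic variant: dosage has no variation", call. = FALSE)
  }
  fit_ols(dosage, expression, predictor = "dosage", response = "expression")
}

#' Haplotype profiles from a dosage matrix
#'
#' The (unphased) haplotype profile of a sample is its ordered dosage vector
#' over the selected variants; samples carrying an identical profile carry
#' the same local risk-allele configuration. Samples with any missing dosage
#' among the selected variants are dropped with a warning.
#'
#' @param dosage Numeric matrix, samples in rows (rownames = sample ids),
#'   variants in columns (colnames = variant ids), values in {0, 1, 2}.
#' @param variant_ids Variants to use, in order; default all columns.
#' @return Data frame with columns `sample`, `profile` (dosages joined with
#'   "|"), `burden` (risk-allele count = sum of the profile).
#' @export
haplotype_profiles <- function(dosage, variant_ids = colnames(dosage)) {
  missing_v <- setdiff(variant_ids, colnames(dosage))
  if (length(missing_v) > 0L) {
    stop(sprintf("variant(s) absent from the dosage matrix: %s",
                 paste(missing_v, collapse = ", ")), call. = FALSE)
  }
  m <- dosage[, variant_ids, drop = FALSE]
  complete <- stats::complete.cases(m)
  if (any(!complete)) {
    warning(sprintf("%d sample(s) with missing dosages dropped",
                    sum(!complete)), call. = FALSE)
    m <- m[complete, , drop = FALSE]
  }
  if (!all(m %in% c(0, 1, 2))) {
    stop("dosages must be 0, 1 or 2", call. = FALSE)
  }
  samples <- rownames(m)
  if (is.null(samples)) samples <- as.character(seq_len(nrow(m)))
  data.frame(
    sample = samples,
    profile = apply(m, 1L, paste, collapse = "|"),
    burden = unname(rowSums(m)),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Haplotype profiles from phased genotype strings
#'
#' For callers with phased VCF genotypes: each sample's profile is the
#' unordered pair of its two haplotype allele strings across the selected
#' variants, so samples are collapsed only when they carry the same two
#' local haplotypes (a finer grouping than the unphased dosage profile of
#' [haplotype_profiles]). The burden is unchanged: the total count of
#' alternate (risk) alleles.
#'
#' @param gt Character matrix of phased genotypes ("a|b" with a, b in 0/1),
#'   samples in rows (rownames = sample ids), variants in columns.
#' @param variant_ids Variants to use, in order; default all columns.
#' @return Data frame with columns `sample`, `profile`, `burden`.
#' @export
haplotype_profiles_phased <- function(gt, variant_ids = colnames(gt)) {
  missing_v <- setdiff(variant_ids, colnames(gt))
  if (length(missing_v) > 0L) {
    stop(sprintf("variant(s) absent from the genotype matrix: %s",
                 paste(missing_v, collapse = ", ")), call. = FALSE)
  }
  m <- gt[, variant_ids, drop = FALSE]
  ok <- apply(m, 1L, function(r) all(grepl("^[01]\\|[01]$", r)))
  if (any(!ok)) {
    warning(sprintf("%d sample(s) with missing or unphased genotypes dropped",
                    sum(!ok)), call. = FALSE)
    m <- m[ok, , drop = FALSE]
  }
  samples <- rownames(m)
  if (is.null(samples)) samples <- as.character(seq_len(nrow(m)))
  hap <- function(r, which) {
    paste(vapply(strsplit(r, "|", fixed = TRUE), `[[`, "", which),
          collapse = "")
  }
  profile <- vapply(seq_len(nrow(m)), function(i) {
    pair <- sort(c(hap(m[i, ], 1L), hap(m[i, ], 2L)))
    paste(pair, collapse = "/")
  }, "")
  burden <- vapply(seq_len(nrow(m)), function(i) {
    sum(as.integer(unlist(strsplit(m[i, ], "|", fixed = TRUE))))
  }, 0)
  data.frame(sample = samples, profile = profile, burden = burden,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Collapse samples by haplotype profile and average expression
#'
#' One group per distinct profile, carrying the member count, the arithmetic
#' mean of the members' expression, and the group's risk-allele burden.
#' Profiled samples lacking an expression value are dropped with a warning.
#'
#' @param profiles Data frame from [haplotype_profiles].
#' @param expression Named numeric vector (sample -> expression).
#' @return A `collapsed_groups` data frame: `profile`, `n_members`,
#'   `mean_expression`, `burden`, ordered by burden then profile.
#' @export
collapse_by_profile <- function(profiles, expression) {
  expr <- expression[profiles$sample]
  missing_e <- is.na(expr)
  if (any(missing_e)) {
    warning(sprintf("%d profiled sample(s) without expression dropped",
                    sum(missing_e)), call. = FALSE)
    profiles <- profiles[!missing_e, , drop = FALSE]
    expr <- expr[!missing_e]
  }
  sp <- split(seq_len(nrow(profiles)), profiles$profile)
  out <- data.frame(
    profile = names(sp),
    n_members = vapply(sp, length, 0L),
    mean_expression = vapply(sp, function(i) mean(expr[i]), 0),
    burden = vapply(sp, function(i) profiles$burden[i[1L]], 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- out[order(out$burden, out$profile), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("collapsed_groups", "data.frame")
  out
}

#' Risk-allele burden regression over collapsed groups
#'
#' OLS of group mean expression on risk-allele burden; a positive slope
#' indicates that expression increases with the number of cis-acting risk
#' alleles, as under an additive model. Unweighted by default (plain
#' averaging over haplotype groups); `weighted = TRUE` weights groups by
#' their member counts.
#'
#' @param groups A `collapsed_groups` data frame from [collapse_by_profile]
#'   (at least 3 groups, at least 2 distinct burdens).
#' @param weighted Weight groups by `n_members`? Default `FALSE`.
#' @return A [regression_result].
#' @export
burden_regression <- function(groups, weighted = FALSE) {
  if (nrow(groups) < 3L) {
    stop("need at least 3 haplotype groups", call. = FALSE)
  }
  if (length(unique(groups$burden)) < 2L) {
    stop("no burden variation across groups", call. = FALSE)
  }
  fit_ols(groups$burden, groups$mean_expression,
          weights = if (weighted) groups$n_members else NULL,
          predictor = "risk-allele burden", response = "mean expression")
}
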