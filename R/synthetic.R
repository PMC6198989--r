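#' Seeded synthetic-data generators
#'
#' Generators producing inputs with the statistical structure the analysis
#' stages assume: two ChIP-seq peak sets with a controlled number of jointly
#' bound sites and a planted bias distribution of normalized read counts, and
#' a genotype/expression cohort with an additive cis effect, haplotype-shared
#' noise, and paired GWAS/eQTL summary statistics with a planted beta-beta
#' correlation. Every generator takes an explicit seed and restores the
#' caller's RNG state; the same seed reproduces identical outputs. Truth
#' tables record every planted label so downstream estimates can be scored
#' without re-deriving the plant.
#'
#' @name synthetic_data
NULL

#' Configuration for the co-binding simulator
#'
#' Defaults reproduce the accounting structure of a two-factor ChIP-seq
#' comparison at full scale: 30,392 factor-A peaks and 29,533 factor-B peaks
#' of which 979 overlap as joint sites, 583 of the joint sites biased, with
#' 61.4% (358/583) of the biased sites biased toward factor A.
#'
#' @param n_sites_only_a,n_sites_only_b Peaks unique to each factor.
#' @param n_joint Jointly bound sites (one A and one B peak sharing >= 1 bp).
#' @param n_biased Joint sites with a planted binding bias (<= `n_joint`).
#' @param frac_a_of_biased Fraction of biased sites biased toward factor A.
#' @param peak_width_range Min/max peak width in bp.
#' @param gap_mean Mean intersite gap in bp (exponential).
#' @param background_rate Background read density (reads per bp); the
#'   expected background count of a peak is `background_rate * width`.
#' @param signal_multiplier Expected enrichment of an unbiased bound peak
#'   over background.
#' @param bias_multiplier Extra enrichment of the favored factor at a biased
#'   site; the expected normalized-fold-change ratio at biased sites.
#' @param control_pair Simulate a co-bound equal-affinity factor pair (no
#'   planted bias anywhere, both factors drawn from the same signal model);
#'   overrides `n_biased`.
#' @param n_chroms Number of chromosomes the sites are spread over.
#' @param chrom_length Optional fixed chromosome length; an error is raised
#'   when the simulated sites cannot fit. By default the length is taken
#'   from the layout.
#' @param make_coverage Also emit per-base coverage (bedGraph tables) for
#'   each factor.
#' @param seed Integer seed.
#' @return A `cobind_sim_config` list.
#' @export
cobind_sim_config <- function(n_sites_only_a = 29413,
                              n_sites_only_b = 28554,
                              n_joint = 979,
                              n_biased = 583,
                              frac_a_of_biased = 358 / 583,
                              peak_width_range = c(200, 500),
                              gap_mean = 2000,
                              background_rate = 0.1,
                              signal_multiplier = 6,
                              bias_multiplier = 3,
                              control_pair = FALSE,
                              n_chroms = 2,
                              chrom_length = NULL,
                              make_coverage = FALSE,
                              seed = 1) {
  if (control_pair) n_biased <- 0L
  cfg <- list(n_sites_only_a = n_sites_only_a, n_sites_only_b = n_sites_only_b,
              n_joint = n_joint, n_biased = n_biased,
              frac_a_of_biased = frac_a_of_biased,
              peak_width_range = peak_width_range, gap_mean = gap_mean,
              background_rate = background_rate,
              signal_multiplier = signal_multiplier,
              bias_multiplier = bias_multiplier,
              control_pair = control_pair, n_chroms = n_chroms,
              chrom_length = chrom_length, make_coverage = make_coverage,
              seed = seed)
  if (n_biased > n_joint) stop("n_biased must not exceed n_joint", call. = FALSE)
  if (frac_a_of_biased < 0 || frac_a_of_biased > 1) {
    stop("frac_a_of_biased must lie in [0, 1]", call. = FALSE)
  }
  if (any(c(n_sites_only_a, n_sites_only_b, n_joint) < 0)) {
    stop("site counts must be non-negative", call. = FALSE)
  }
  if (background_rate <= 0 || signal_multiplier <= 0 || bias_multiplier <= 1) {
    stop("signal model parameters out of range", call. = FALSE)
  }
  structure(cfg, class = "cobind_sim_config")
}

#' Simulate two co-binding ChIP-seq peak sets
#'
#' Lays non-overlapping site loci along `n_chroms` chromosomes (exponential
#' gaps), assigns each locus a type (A-only, B-only, or joint), and draws
#' Poisson read counts around a local-background signal model: background
#' counts at `background_rate * width`, bound-peak counts multiplied by
#' `signal_multiplier`, and the favored factor at a biased site further
#' multiplied by `bias_multiplier`. Joint sites are a pair of overlapping A
#' and B peaks (guaranteed >= 1 bp of shared span).
#'
#' @param config A [cobind_sim_config].
#' @return A `cobind_sim` list: `peaks_a`, `peaks_b` (`scored_peaks` with
#'   counts filled), `coverage_a`, `coverage_b` (bedGraph data frames or
#'   `NULL`), `truth` (one row per joint site: peak indices and the planted
#'   label), `chrom_lengths`, and `config`.
#' @export
simulate_cobinding <- function(config = cobind_sim_config()) {
  stopifnot(inherits(config, "cobind_sim_config"))
  withr::with_seed(config$seed, simulate_cobinding_impl(config))
}

simulate_cobinding_impl <- function(cfg) {
  n_total <- cfg$n_sites_only_a + cfg$n_sites_only_b + cfg$n_joint
  types <- sample(rep(c("A", "B", "J"),
                      c(cfg$n_sites_only_a, cfg$n_sites_only_b, cfg$n_joint)))
  chrom_of <- sort(sample.int(cfg$n_chroms, n_total, replace = TRUE))
  chroms <- paste0("chr", chrom_of)
  wmin <- cfg$peak_width_range[1L]
  wmax <- cfg$peak_width_range[2L]
  width <- round(stats::runif(n_total, wmin, wmax))

  # lay sites left to right per chromosome with exponential gaps; a site slot
  # is wide enough for the joint pair's merged span
  slot <- width + round(width / 2)
  start <- numeric(n_total)
  chrom_lengths <- stats::setNames(numeric(cfg$n_chroms),
                                   paste0("chr", seq_len(cfg$n_chroms)))
  for (c_i in seq_len(cfg$n_chroms)) {
    idx <- which(chrom_of == c_i)
    gaps <- round(stats::rexp(length(idx), 1 / cfg$gap_mean)) + 2 * wmax
    start[idx] <- cumsum(gaps + slot[idx]) - slot[idx]
    chrom_lengths[c_i] <- if (length(idx) > 0) {
      start[idx[length(idx)]] + slot[idx[length(idx)]] + cfg$gap_mean
    } else cfg$gap_mean
  }
  if (!is.null(cfg$chrom_length)) {
    if (any(chrom_lengths > cfg$chrom_length)) {
      stop("infeasible geometry: sites do not fit on chromosomes of the requested length",
           call. = FALSE)
    }
    chrom_lengths[] <- cfg$chrom_length
  }

  # planted labels for joint sites
  j_idx <- which(types == "J")
  n_a_biased <- round(cfg$n_biased * cfg$frac_a_of_biased)
  labels <- rep("unbiased", length(j_idx))
  if (cfg$n_biased > 0) {
    biased_pick <- sample(seq_along(j_idx), cfg$n_biased)
    toward_a <- sample(biased_pick, n_a_biased)
    labels[biased_pick] <- "B_biased"
    labels[toward_a] <- "A_biased"
  }

  draw_counts <- function(w, mult) {
    bg <- stats::rpois(length(w), cfg$background_rate * w)
    rd <- stats::rpois(length(w), cfg$background_rate * w * mult)
    list(read = rd, background = bg)
  }

  mk_peak_rows <- function(idx, starts, widths, mult) {
    cnt <- draw_counts(widths, mult)
    summit <- starts + round(widths / 2) +
      round(stats::runif(length(idx), -0.2, 0.2) * widths)
    summit <- pmax(starts, pmin(starts + widths - 1, summit))
    fc <- (cnt$read + 1) / (cnt$background + 1)
    data.frame(chrom = chroms[idx], start = starts, end = starts + widths,
               summit = summit, read_count = cnt$read,
               background_count = cnt$background, fold_change = fc,
               neg_log10_q = pmax(0, stats::rnorm(length(idx), 30, 10)),
               stringsAsFactors = FALSE)
  }

  sm <- cfg$signal_multiplier
  bm <- cfg$bias_multiplier

  # factor-A peaks: A-only sites plus the A member of each joint pair
  a_only <- which(types == "A")
  b_only <- which(types == "B")
  mult_a_joint <- ifelse(labels == "A_biased", sm * bm, sm)
  mult_b_joint <- ifelse(labels == "B_biased", sm * bm, sm)

  # joint pair geometry: B peak shifted against A but guaranteed to overlap
  wa <- width[j_idx]
  wb <- round(stats::runif(length(j_idx), wmin, wmax))
  shift <- round(stats::runif(length(j_idx), -0.4, 0.4) * pmin(wa, wb))

  rows_a <- rbind(
    mk_peak_rows(a_only, start[a_only], width[a_only], sm),
    mk_peak_rows(j_idx, start[j_idx], wa, mult_a_joint)
  )
  rows_b <- rbind(
    mk_peak_rows(b_only, start[b_only], width[b_only], sm),
    mk_peak_rows(j_idx, start[j_idx] + shift, wb, mult_b_joint)
  )

  finalize <- function(rows) {
    ord <- order(rows$chrom, rows$start)
    rows <- rows[ord, , drop = FALSE]
    rownames(rows) <- NULL
    pk <- scored_peaks(rows$chrom, rows$start, rows$end, summit = rows$summit,
                       read_count = rows$read_count,
                       background_count = rows$background_count,
                       fold_change = rows$fold_change,
                       neg_log10_q = rows$neg_log10_q)
    list(peaks = pk, order = ord)
  }
  fa <- finalize(rows_a)
  fb <- finalize(rows_b)

  # joint-site truth: map original joint rows to sorted peak-table indices
  joint_rows_a <- length(a_only) + seq_along(j_idx)
  joint_rows_b <- length(b_only) + seq_along(j_idx)
  truth <- data.frame(
    site = seq_along(j_idx),
    chrom = chroms[j_idx],
    index_a = match(joint_rows_a, fa$order),
    index_b = match(joint_rows_b, fb$order),
    planted_bias = labels,
    stringsAsFactors = FALSE
  )

  coverage_a <- coverage_b <- NULL
  if (cfg$make_coverage) {
    tent <- function(pk) {
      # three-step tent per peak approximating read pileup around the summit
      w <- pk$end - pk$start
      h <- pk$read_count / w
      data.frame(
        chrom = rep(pk$chrom, each = 3),
        start = as.vector(rbind(pk$start, pk$start + round(w / 3),
                                pk$start + round(2 * w / 3))),
        end = as.vector(rbind(pk$start + round(w / 3),
                              pk$start + round(2 * w / 3), pk$end)),
        value = as.vector(rbind(h * 0.5, h * 2, h * 0.5)),
        stringsAsFactors = FALSE
      )
    }
    coverage_a <- tent(fa$peaks)
    coverage_b <- tent(fb$peaks)
  }

  structure(
    list(peaks_a = fa$peaks, peaks_b = fb$peaks,
         coverage_a = coverage_a, coverage_b = coverage_b,
         truth = truth, chrom_lengths = chrom_lengths, config = cfg),
    class = "cobind_sim"
  )
}

#' Configuration for the genotype/expression simulator
#'
#' Defaults emulate a 52-sample cohort genotyped at 4 cis risk variants whose
#' local haplotypes come from a pool of 6 distinct profiles, an additive
#' expression effect of 0.3 units per risk allele, haplotype-group-shared and
#' individual noise of 0.5 sd each, and paired GWAS/eQTL summary statistics
#' for 60 overlapping variants with a planted beta-beta correlation of 0.9.
#'
#' @param n_samples Cohort size (default 52).
#' @param n_variants Cis risk variants genotyped (default 4).
#' @param n_haplotypes Distinct haplotypes in the local pool (default 6).
#' @param per_allele_effect Expression units added per risk allele.
#' @param group_noise_sd Noise shared by samples with an identical haplotype
#'   profile (captures local genetic background).
#' @param individual_noise_sd Per-sample noise (biological + technical).
#' @param planted_beta_correlation Correlation of the GWAS and eQTL betas in
#'   the summary-statistics tables, in [-1, 1].
#' @param n_overlap_variants Summary-stat variants passing both p filters and
#'   present in both tables.
#' @param n_extra_variants Additional variants per table that fail a filter
#'   or are absent from the other table.
#' @param gene_chrom,gene_start,gene_end Coordinates of the simulated gene.
#' @param expression_intercept Baseline expression.
#' @param seed Integer seed.
#' @return A `genetics_sim_config` list.
#' @export
genetics_sim_config <- function(n_samples = 52,
                                n_variants = 4,
                                n_haplotypes = 6,
                                per_allele_effect = 0.3,
                                group_noise_sd = 0.5,
                                individual_noise_sd = 0.5,
                                planted_beta_correlation = 0.9,
                                n_overlap_variants = 60,
                                n_extra_variants = 20,
                                gene_chrom = "chr15",
                                gene_start = 67358195,
                                gene_end = 67487533,
                                expression_intercept = 10,
                                seed = 1) {
  if (n_haplotypes < 1) stop("n_haplotypes must be at least 1", call. = FALSE)
  if (group_noise_sd < 0 || individual_noise_sd < 0) {
    stop("noise standard deviations must be non-negative", call. = FALSE)
  }
  if (abs(planted_beta_correlation) > 1) {
    stop("planted_beta_correlation must lie in [-1, 1]", call. = FALSE)
  }
  structure(
    list(n_samples = n_samples, n_variants = n_variants,
         n_haplotypes = n_haplotypes, per_allele_effect = per_allele_effect,
         group_noise_sd = group_noise_sd,
         individual_noise_sd = individual_noise_sd,
         planted_beta_correlation = planted_beta_correlation,
         n_overlap_variants = n_overlap_variants,
         n_extra_variants = n_extra_variants,
         gene_chrom = gene_chrom, gene_start = gene_start,
         gene_end = gene_end,
         expression_intercept = expression_intercept, seed = seed),
    class = "genetics_sim_config"
  )
}

rand_alleles <- function(n) {
  bases <- c("A", "C", "G", "T")
  eff <- sample(bases, n, replace = TRUE)
  oth <- vapply(eff, function(a) sample(setdiff(bases, a), 1L), "")
  list(effect = eff, other = unname(oth))
}

#' Simulate a genotyped cohort with cis-regulated expression
#'
#' Each sample's genotype is the dosage sum of two haplotypes drawn (with
#' replacement, by random pool frequencies) from a pool of distinct local
#' haplotypes; expression is
#' `intercept + per_allele_effect * burden + group noise + individual noise`,
#' where the group noise is shared by all samples with an identical haplotype
#' profile. GWAS and eQTL summary statistics are drawn jointly with the
#' planted beta-beta correlation; roughly half the eQTL records are emitted
#' on the opposite effect allele (with the beta sign flipped accordingly) to
#' exercise allele harmonization, and extra records failing the p filters or
#' missing from the other table are appended.
#'
#' @param config A [genetics_sim_config].
#' @return A `genetics_sim` list: `dosage` (samples x variants matrix),
#'   `variants` (cis-variant metadata with risk-oriented GWAS effects),
#'   `expression` (named vector), `gwas_sumstats`, `eqtl_sumstats` (summary
#'   tables for the concordance stage), `truth` (planted parameters, group
#'   effects, true harmonized betas), and `config`.
#' @export
simulate_genetics <- function(config = genetics_sim_config()) {
  stopifnot(inherits(config, "genetics_sim_config"))
  withr::with_seed(config$seed, simulate_genetics_impl(config))
}

simulate_genetics_impl <- function(cfg) {
  # distinct haplotype pool; every variant polymorphic across the pool
  pool <- NULL
  for (attempt in seq_len(1000L)) {
    pool <- matrix(stats::rbinom(cfg$n_haplotypes * cfg$n_variants, 1L, 0.4),
                   nrow = cfg$n_haplotypes)
    distinct <- nrow(unique(pool)) == cfg$n_haplotypes
    polymorphic <- all(apply(pool, 2L, function(col) length(unique(col)) > 1L))
    if ((distinct || cfg$n_haplotypes > 2^cfg$n_variants) &&
        (polymorphic || cfg$n_haplotypes == 1L)) break
  }
  freqs <- stats::rexp(cfg$n_haplotypes) + 0.2
  freqs <- freqs / sum(freqs)

  samples <- sprintf("S%02d", seq_len(cfg$n_samples))
  h1 <- sample.int(cfg$n_haplotypes, cfg$n_samples, replace = TRUE, prob = freqs)
  h2 <- sample.int(cfg$n_haplotypes, cfg$n_samples, replace = TRUE, prob = freqs)
  dosage <- pool[h1, , drop = FALSE] + pool[h2, , drop = FALSE]
  variant_ids <- sprintf("rs%07d",
                         sort(sample.int(9999999L, cfg$n_variants,
                                         useHash = TRUE)))
  dimnames(dosage) <- list(samples, variant_ids)

  al <- rand_alleles(cfg$n_variants)
  span <- cfg$gene_end - cfg$gene_start
  variants <- data.frame(
    variant_id = variant_ids,
    chrom = cfg$gene_chrom,
    pos = sort(round(stats::runif(cfg$n_variants,
                                  cfg$gene_start - 0.9e5,
                                  cfg$gene_end + 0.9e5))),
    risk_allele = al$effect, other_allele = al$other,
    beta = abs(stats::rnorm(cfg$n_variants, 0.1, 0.03)),
    p = 10^-stats::runif(cfg$n_variants, 7, 12),
    stringsAsFactors = FALSE
  )

  burden <- rowSums(dosage)
  profile_key <- apply(dosage, 1L, paste, collapse = "|")
  grp <- match(profile_key, unique(profile_key))
  group_effect <- stats::rnorm(length(unique(profile_key)), 0, cfg$group_noise_sd)
  expression <- stats::setNames(
    cfg$expression_intercept + cfg$per_allele_effect * burden +
      group_effect[grp] +
      stats::rnorm(cfg$n_samples, 0, cfg$individual_noise_sd),
    samples
  )

  # paired summary statistics with planted correlation
  rho <- cfg$planted_beta_correlation
  n_ov <- cfg$n_overlap_variants
  z1 <- stats::rnorm(n_ov)
  z2 <- rho * z1 + sqrt(max(0, 1 - rho^2)) * stats::rnorm(n_ov)
  beta_g <- 0.12 * z1
  beta_e <- 0.30 * z2
  ov_num <- sample.int(9999999L, n_ov + cfg$n_variants, useHash = TRUE)
  ov_num <- setdiff(ov_num, as.integer(sub("rs", "", variant_ids)))[seq_len(n_ov)]
  ov_ids <- sprintf("rs%07d", ov_num)
  ov_al <- rand_alleles(n_ov)
  gwas <- data.frame(
    variant_id = ov_ids, effect_allele = ov_al$effect,
    other_allele = ov_al$other, beta = beta_g,
    p = 10^-stats::runif(n_ov, 4.05, 9),
    stringsAsFactors = FALSE
  )
  flip <- stats::runif(n_ov) < 0.5
  eqtl <- data.frame(
    variant_id = ov_ids,
    effect_allele = ifelse(flip, ov_al$other, ov_al$effect),
    other_allele = ifelse(flip, ov_al$effect, ov_al$other),
    beta = ifelse(flip, -beta_e, beta_e),
    p = stats::runif(n_ov, 1e-6, 0.049),
    stringsAsFactors = FALSE
  )

  # extra records: fail a p filter or appear in only one table
  n_x <- cfg$n_extra_variants
  if (n_x > 0) {
    x_ids <- sprintf("rx%07d", sample.int(9999999L, 2L * n_x, useHash = TRUE))
    x_al <- rand_alleles(2L * n_x)
    gwas_x <- data.frame(
      variant_id = x_ids[seq_len(n_x)],
      effect_allele = x_al$effect[seq_len(n_x)],
      other_allele = x_al$other[seq_len(n_x)],
      beta = 0.12 * stats::rnorm(n_x),
      p = 10^-stats::runif(n_x, 0, 3.9),      # fails GWAS p < 1e-4
      stringsAsFactors = FALSE
    )
    eqtl_x <- data.frame(
      variant_id = x_ids[n_x + seq_len(n_x)],
      effect_allele = x_al$effect[n_x + seq_len(n_x)],
      other_allele = x_al$other[n_x + seq_len(n_x)],
      beta = 0.30 * stats::rnorm(n_x),
      p = stats::runif(n_x, 0.051, 1),        # fails eQTL p < 0.05
      stringsAsFactors = FALSE
    )
    gwas <- rbind(gwas, gwas_x)
    eqtl <- rbind(eqtl, eqtl_x)
  }

  truth <- list(
    per_allele_effect = cfg$per_allele_effect,
    planted_beta_correlation = rho,
    burden = stats::setNames(burden, samples),
    profile = stats::setNames(profile_key, samples),
    group_effect = group_effect,
    beta_gwas = stats::setNames(beta_g, ov_ids),
    beta_eqtl_harmonized = stats::setNames(beta_e, ov_ids),
    eqtl_flipped = stats::setNames(flip, ov_ids)
  )

  structure(
    list(dosage = dosage, variants = variants, expression = expression,
         gwas_sumstats = gwas, eqtl_sumstats = eqtl, truth = truth,
         config = cfg),
    class = "genetics_sim"
  )
}

#' Simulate a gene annotation over given chromosomes
#'
#' Uniformly placed TSSs with random strands, for exercising the
#' regulatory-domain and peak-assignment stages.
#'
#' @param n_genes Number of genes.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param seed Integer seed.
#' @return Data frame with `gene_id`, `chrom`, `strand`, `tss`.
#' @export
simulate_genes <- function(n_genes, chrom_lengths, seed = 1) {
  withr::with_seed(seed, {
    chrom <- sample(names(chrom_lengths), n_genes, replace = TRUE)
    df <- data.frame(
      gene_id = sprintf("G%04d", seq_len(n_genes)),
      chrom = chrom,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      tss = round(stats::runif(n_genes, 10000, chrom_lengths[chrom] - 10000)),
      stringsAsFactors = FALSE
    )
    df[order(df$chrom, df$tss), , drop = FALSE]
  })
}
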