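make_variants <- function(pos, p, chrom = "chr15") {
  data.frame(variant_id = sprintf("rs%d", seq_along(pos)), chrom = chrom,
             pos = pos, risk_allele = "A", other_allele = "G",
             beta = 0.1, p = p, stringsAsFactors = FALSE)
}

test_that("cis-variant selection applies window and strict p cutoff", {
  gene <- c(1e6, 1.2e6)
  v <- make_variants(pos = c(950000, 850000, 1.25e6, 1.1e6),
                     p = c(1e-8, 1e-8, 1e-6, 1e-8))
  got <- select_cis_variants(v, "chr15", gene[1], gene[2])
  # 50 kb upstream kept; 150 kb upstream out of window; p == 1e-6 fails "<"
  expect_equal(got$variant_id, c("rs1", "rs4"))
  expect_equal(got$pos, sort(got$pos))
  expect_error(select_cis_variants(v, "chr15", 2e6, 1e6), "gene_start")

  set.seed(31)
  v2 <- data.frame(variant_id = sprintf("rs%d", 1:300),
                   chrom = sample(c("chr15", "chr2"), 300, replace = TRUE),
                   pos = sample.int(3e6, 300), risk_allele = "A",
                   other_allele = "G", beta = 0.1,
                   p = 10^-runif(300, 2, 10), stringsAsFactors = FALSE)
  got2 <- select_cis_variants(v2, "chr15", gene[1], gene[2])
  keep <- v2$chrom == "chr15" & v2$pos >= gene[1] - 1e5 &
    v2$pos <= gene[2] + 1e5 & v2$p < 1e-6
  expect_setequal(got2$variant_id, v2$variant_id[keep])
})

test_that("beta orientation flips rows whose effect allele is the non-risk allele", {
  v <- data.frame(effect_allele = c("A", "G", "T"), risk_allele = "A",
                  other_allele = "G", beta = c(0.5, 0.5, 0.5))
  got <- suppressWarnings(orient_to_risk(v))
  expect_equal(got$beta, c(0.5, -0.5, NA))
})

test_that("single-variant eQTL regression: perfect fit and guards", {
  dosage <- c(0, 0, 1, 1, 2, 2)
  fit <- suppressWarnings(single_variant_eqtl(dosage, dosage))
  expect_equal(fit$slope, 1)
  expect_equal(fit$pearson_r, 1)
  expect_error(single_variant_eqtl(c(1, 1, 1, 1), rnorm(4)), "monomorphic")
  expect_error(single_variant_eqtl(c(0, 1), c(1, 2)), "at least 3")
  # named vectors align by sample
  fit2 <- suppressWarnings(
    single_variant_eqtl(c(a = 0, b = 1, c = 2, d = 1),
                        c(d = 1, c = 2, b = 1, a = 0)))
  expect_gt(fit2$slope, 0)
})

test_that("eQTL p-values are calibrated under permutation of expression", {
  set.seed(37)
  dosage <- rbinom(52, 2, 0.3)
  expr <- rnorm(52)
  pv <- replicate(300, single_variant_eqtl(dosage, sample(expr))$p_value)
  expect_gt(mean(pv < 0.05), 0.02)
  expect_lt(mean(pv < 0.05), 0.09)
  expect_gt(stats::ks.test(pv, "punif")$p.value, 0.001)
})

test_that("eQTL regression recovers a planted slope at cohort scale", {
  set.seed(41)
  est <- replicate(200, {
    dosage <- rbinom(52, 2, 0.4)
    expr <- 0.5 * dosage + rnorm(52, 0, 0.5)
    single_variant_eqtl(dosage, expr)$slope
  })
  expect_gte(mean(abs(est - 0.5) <= 0.3), 0.95)
  expect_gte(mean(est > 0), 0.95)
})

test_that("haplotype profiles are the ordered dosage tuples, dropping incomplete samples", {
  m <- matrix(c(0, 1, 2, 0, 1, 2), nrow = 3,
              dimnames = list(c("s1", "s2", "s3"), c("v1", "v2")))
  pr <- haplotype_profiles(m)
  expect_equal(pr$profile, c("0|0", "1|1", "2|2"))
  expect_equal(pr$burden, c(0, 2, 4))
  m2 <- rbind(m, s4 = c(NA, 1))
  expect_warning(pr2 <- haplotype_profiles(m2), "missing")
  expect_equal(nrow(pr2), 3L)
  expect_error(haplotype_profiles(m, c("v1", "zz")), "absent")
  # identical rows give identical profiles; multiset matches a row-tuple oracle
  set.seed(43)
  m3 <- matrix(sample(0:2, 80, replace = TRUE), nrow = 20,
               dimnames = list(sprintf("s%02d", 1:20), sprintf("v%d", 1:4)))
  pr3 <- haplotype_profiles(m3)
  oracle <- apply(m3, 1, paste, collapse = "|")
  expect_equal(sort(pr3$profile), sort(unname(oracle)))
})

test_that("phased profiles distinguish configurations with equal dosages", {
  # both samples have dosage (1,1) but different haplotype pairs
  gt <- matrix(c("0|1", "1|0",
                 "0|1", "0|1"), nrow = 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("v1", "v2")))
  ph <- haplotype_profiles_phased(gt)
  expect_equal(ph$burden, c(2, 2))
  expect_false(ph$profile[1] == ph$profile[2])
  # the unordered pair is phase-orientation invariant
  gt_swapped <- matrix(c("1|0", "0|1"), nrow = 1,
                       dimnames = list("s3", c("v1", "v2")))
  expect_equal(haplotype_profiles_phased(gt_swapped)$profile, ph$profile[1])
  # unphased or missing entries drop the sample with a warning
  gt_bad <- rbind(gt, s4 = c("0/1", "0|1"))
  expect_warning(ph2 <- haplotype_profiles_phased(gt_bad), "unphased")
  expect_equal(nrow(ph2), 2L)
})

test_that("profile collapsing averages expression within identical profiles", {
  pr <- data.frame(sample = c("s1", "s2", "s3"),
                   profile = c("1|0", "1|0", "2|1"), burden = c(1, 1, 3))
  expr <- c(s1 = 4, s2 = 6, s3 = 10)
  g <- collapse_by_profile(pr, expr)
  expect_equal(g$mean_expression, c(5, 10))
  expect_equal(g$n_members, c(2L, 1L))
  expect_equal(g$burden, c(1, 3))
  # all-distinct profiles: collapse is the identity
  pr2 <- data.frame(sample = c("a", "b"), profile = c("0|1", "1|1"),
                    burden = c(1, 2))
  g2 <- collapse_by_profile(pr2, c(a = 1.5, b = 2.5))
  expect_equal(g2$mean_expression, c(1.5, 2.5))
})

test_that("collapsing conserves sample count and the grand weighted mean", {
  set.seed(47)
  for (rep in 1:10) {
    sim <- simulate_genetics(genetics_sim_config(seed = rep))
    pr <- haplotype_profiles(sim$dosage)
    g <- collapse_by_profile(pr, sim$expression)
    expect_equal(sum(g$n_members), nrow(pr))
    expect_equal(sum(g$mean_expression * g$n_members) / sum(g$n_members),
                 mean(sim$expression))
    # per-key average oracle
    oracle <- tapply(sim$expression[pr$sample], pr$profile, mean)
    expect_equal(g$mean_expression, as.numeric(oracle[g$profile]))
  }
})

test_that("burden regression handles the exact-line case and degenerate input", {
  g <- data.frame(profile = c("0|0", "1|0", "1|1"), n_members = c(2L, 2L, 2L),
                  mean_expression = c(1, 2, 3), burden = c(0, 1, 2))
  fit <- suppressWarnings(burden_regression(g))
  expect_equal(fit$slope, 1)
  expect_equal(fit$pearson_r, 1)
  expect_error(burden_regression(g[1:2, ]), "at least 3")
  g$burden <- 1
  expect_error(burden_regression(g), "burden variation")
})

test_that("uncollapsed burden regression equals the single-variant eQTL fit", {
  set.seed(51)
  dosage <- matrix(rbinom(40, 2, 0.4), ncol = 1,
                   dimnames = list(sprintf("s%02d", 1:40), "v1"))
  expr <- stats::setNames(0.4 * dosage[, 1] + rnorm(40), rownames(dosage))
  # force every sample into its own group
  pr <- haplotype_profiles(dosage)
  groups <- data.frame(profile = pr$sample, n_members = 1L,
                       mean_expression = unname(expr[pr$sample]),
                       burden = pr$burden)
  fit_b <- burden_regression(groups)
  fit_e <- single_variant_eqtl(dosage[, 1], expr)
  expect_equal(fit_b$slope, fit_e$slope)
  expect_equal(fit_b$pearson_r, fit_e$pearson_r)
  expect_equal(fit_b$p_value, fit_e$p_value)
})

test_that("regression results keep slope and correlation signs consistent", {
  set.seed(53)
  for (rep in 1:20) {
    x <- rnorm(20)
    y <- rnorm(20)
    fit <- single_variant_eqtl(round(abs(x)), y)
    expect_equal(sign(fit$slope), sign(fit$pearson_r))
  }
})
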