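test_that("normalized fold change follows the pseudocount formula", {
  expect_equal(normalized_fold_change(50, 10), 51 / 11)
  # a site with no reads anywhere is neutral
  expect_equal(normalized_fold_change(0, 0), 1)
  expect_error(normalized_fold_change(NA, 5), "counts unavailable")
  set.seed(5)
  r <- rpois(500, 100)
  b <- rpois(500, 20)
  expect_equal(normalized_fold_change(r, b, pseudocount = 2),
               (r + 2) / (b + 2))
})

test_that("0-100 rescaling is min-max, order preserving, with guarded edge cases", {
  expect_equal(rescale_0_100(c(2, 7, 12)), c(0, 50, 100))
  expect_equal(rescale_0_100(c(5, 5, 10)), c(0, 0, 100))
  expect_error(rescale_0_100(c(3, 3, 3)), "degenerate")
  expect_error(rescale_0_100(7), "at least 2")
  set.seed(9)
  v <- runif(200, 1, 50)
  s <- rescale_0_100(v)
  expect_equal(s, (v - min(v)) / (max(v) - min(v)) * 100)
  expect_equal(order(s), order(v))
  expect_equal(range(s), c(0, 100))
})

test_that("bias labels apply the strict two-fold ratio rule", {
  # nfc_a = (9+1)/(0+1) = 10; nfc_b = 21 and 19 (ratio 2.1 and 1.9)
  pa <- make_counted_peaks(c("chr1", "chr2"), c(100, 100), c(200, 200),
                           read_count = c(9, 9), background_count = c(0, 0))
  pb <- make_counted_peaks(c("chr1", "chr2"), c(150, 150), c(250, 250),
                           read_count = c(20, 18), background_count = c(0, 0))
  js <- suppressWarnings(build_joint_sites(pa, pb))
  expect_equal(as.character(js$bias), c("B_biased", "unbiased"))
  expect_equal(js$nfc_b, c(21, 19))
  expect_error(build_joint_sites(pa, pb, bias_threshold = 1), "greater than 1")
})

test_that("joint sites resolve multi-overlap one-to-one by largest overlap", {
  # one A peak overlapping two B peaks: the 80-bp overlap wins over 20-bp
  pa <- make_counted_peaks("chr1", 100, 300, 50, 10)
  pb <- make_counted_peaks(c("chr1", "chr1"), c(120, 280), c(200, 400),
                           read_count = c(30, 90), background_count = c(10, 10))
  js <- suppressWarnings(build_joint_sites(pa, pb))
  expect_equal(nrow(js), 1L)
  expect_equal(js$index_b, 1L)
  expect_equal(js$overlap_bp, 80)
  # merged span contains both member peaks
  expect_true(js$start <= 100 && js$end >= 300)
})

test_that("joint-site classification recovers planted labels off the boundary", {
  sim <- simulate_cobinding(cobind_sim_config(
    n_sites_only_a = 100, n_sites_only_b = 100, n_joint = 300,
    n_biased = 180, frac_a_of_biased = 0.6, seed = 21))
  js <- build_joint_sites(sim$peaks_a, sim$peaks_b)
  m <- merge(js, sim$truth, by = "index_a")
  expect_equal(nrow(m), 300L)
  # wherever the realized nfc ratio falls on the planted side of 2, the
  # label must equal the plant
  ratio <- m$nfc_a / m$nfc_b
  clear <- (m$planted_bias == "A_biased" & ratio > 2) |
    (m$planted_bias == "B_biased" & 1 / ratio > 2) |
    (m$planted_bias == "unbiased" & ratio <= 2 & 1 / ratio <= 2)
  expect_true(all(as.character(m$bias[clear]) == m$planted_bias[clear]))
  # and most sites are classified on the planted side under this signal model
  expect_gt(mean(as.character(m$bias) == m$planted_bias), 0.85)
})

test_that("bias labels are invariant to library-scale factors away from the boundary", {
  sim <- simulate_cobinding(cobind_sim_config(
    n_sites_only_a = 50, n_sites_only_b = 50, n_joint = 200,
    n_biased = 120, seed = 33))
  js1 <- build_joint_sites(sim$peaks_a, sim$peaks_b, pseudocount = 1e-9)
  scaled <- sim$peaks_a
  scaled$read_count <- scaled$read_count * 7
  scaled$background_count <- scaled$background_count * 7
  js2 <- build_joint_sites(scaled, sim$peaks_b, pseudocount = 1e-9)
  expect_equal(as.character(js1$bias), as.character(js2$bias))
  expect_equal(js1$nfc_a, js2$nfc_a, tolerance = 1e-6)
})

test_that("per-library scale factors do not change bias labels", {
  sim <- simulate_cobinding(cobind_sim_config(
    n_sites_only_a = 30, n_sites_only_b = 30, n_joint = 100,
    n_biased = 60, seed = 44))
  js1 <- build_joint_sites(sim$peaks_a, sim$peaks_b, pseudocount = 1e-9)
  js2 <- build_joint_sites(sim$peaks_a, sim$peaks_b, pseudocount = 1e-9,
                           scale_a = 5, scale_b = 0.5)
  expect_equal(as.character(js1$bias), as.character(js2$bias))
  expect_error(build_joint_sites(sim$peaks_a, sim$peaks_b, scale_a = 0),
               "positive")
})

test_that("bias summary reproduces the 61/39 split and reconstructs input size", {
  # 358 sites biased toward A and 225 toward B, as joint sites with nfc
  # ratios 3 and 1/3
  n_a <- 358
  n_b <- 225
  reads_a <- c(rep(89, n_a), rep(29, n_b))
  reads_b <- c(rep(29, n_a), rep(89, n_b))
  start <- seq_len(n_a + n_b) * 1000
  pa <- make_counted_peaks("chr1", start, start + 200, reads_a, 9)
  pb <- make_counted_peaks("chr1", start + 50, start + 250, reads_b, 9)
  js <- build_joint_sites(pa, pb)
  s <- summarize_bias(js)
  expect_equal(s$n_joint, 583L)
  expect_equal(s$n_biased, 583L)
  expect_equal(s$n_a, 358L)
  expect_equal(s$n_b, 225L)
  expect_equal(s$pct_a, 61)
  expect_equal(s$pct_b, 39)
  expect_equal(s$frac_a + s$frac_b, 1)
  expect_equal(s$n_joint, nrow(js))
})

test_that("bias summary flags the no-biased-sites case and matches a tally oracle", {
  empty <- summarize_bias(suppressWarnings(
    build_joint_sites(make_counted_peaks("chr1", 1, 100, 10, 10),
                      make_counted_peaks("chr1", 50, 150, 10, 10))))
  expect_true(is.na(empty$frac_a))
  expect_equal(empty$n_biased, 0L)

  set.seed(2)
  labels <- sample(c("A_biased", "B_biased", "unbiased"), 400, replace = TRUE)
  fake <- data.frame(bias = factor(labels,
                                   levels = c("A_biased", "B_biased", "unbiased")))
  s <- summarize_bias(fake)
  expect_equal(s$n_a, sum(labels == "A_biased"))
  expect_equal(s$n_b, sum(labels == "B_biased"))
  expect_equal(s$n_joint, 400L)
})

test_that("summit profiles average per-offset signal with edge truncation", {
  # flat coverage 3.0 over a generous span -> flat profile at 3.0
  flat <- coverage_tracks(data.frame(chrom = "chr1", start = 0, end = 10000,
                                     value = 3))
  summits <- data.frame(chrom = "chr1", pos = c(2000, 5000))
  pr <- summit_profile(summits, list(sig = flat), halfwidth = 100)
  expect_equal(length(pr$positions), 201L)
  expect_equal(unname(pr$mean_signal[, "sig"]), rep(3, 201))

  # delta coverage exactly at each summit -> 1 at offset 0, 0 elsewhere
  delta <- coverage_tracks(data.frame(chrom = "chr1",
                                      start = c(2000, 5000),
                                      end = c(2001, 5001), value = 1))
  pd <- summit_profile(summits, list(sig = delta), halfwidth = 50)
  expect_equal(unname(pd$mean_signal[51, "sig"]), 1)
  expect_equal(sum(pd$mean_signal), 1)

  expect_error(summit_profile(summits[0, ], list(sig = flat)), "empty")
})

test_that("summit profile equals a per-offset loop oracle on random coverage", {
  set.seed(13)
  n_seg <- 80
  seg_start <- sort(sample.int(20000, n_seg))
  cov <- data.frame(chrom = sample(c("chr1", "chr2"), n_seg, replace = TRUE),
                    start = seg_start,
                    end = seg_start + sample.int(50, n_seg, replace = TRUE),
                    value = rpois(n_seg, 4))
  trk <- coverage_tracks(cov)
  summits <- data.frame(chrom = sample(c("chr1", "chr2"), 50, replace = TRUE),
                        pos = sample(30:20000, 50))
  hw <- 30
  pr <- summit_profile(summits, list(x = trk), halfwidth = hw)

  value_at <- function(chrom, pos) {
    if (pos < 0) return(NA_real_)
    r <- trk[[chrom]]
    if (pos + 1 > length(r)) return(0)
    as.numeric(r[pos + 1])
  }
  oracle <- vapply(-hw:hw, function(off) {
    v <- mapply(value_at, summits$chrom, summits$pos + off)
    mean(v, na.rm = TRUE)
  }, 0)
  expect_equal(unname(pr$mean_signal[, "x"]), oracle)
})
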