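test_that("basal domains follow the strand-aware 5kb/1kb rule with clipping", {
  expect_equal(basal_domain(10000, "+"), data.frame(start = 5000, end = 11000))
  expect_equal(basal_domain(10000, "-"), data.frame(start = 9000, end = 15000))
  expect_equal(basal_domain(2000, "+"), data.frame(start = 0, end = 3000))
  expect_error(basal_domain(100, "+", up = 0, down = 0), "empty")
  expect_error(basal_domain(100, "."), "strand")
})

test_that("a lone gene extends the full maximum on both sides", {
  g <- data.frame(gene_id = "g1", chrom = "chr1", strand = "+", tss = 2e6)
  d <- extend_domains(g)
  expect_equal(d$basal_start, 1995000)
  expect_equal(d$basal_end, 2001000)
  expect_equal(d$ext_start, 995000)
  expect_equal(d$ext_end, 3001000)
})

test_that("extension stops at a flanking gene's basal edge, never truncating basal", {
  g <- data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
                  strand = "+", tss = c(1e6, 1.1e6))
  d <- extend_domains(g)
  # hand-applied rule: gene 2's upstream extension stops at gene 1's basal
  # end (1,001,000); gene 1's downstream extension stops at gene 2's basal
  # start (1,095,000)
  expect_equal(d$ext_start[2], 1001000)
  expect_equal(d$ext_end[1], 1095000)
  # full upstream extension for gene 1 would reach below 0; clipped there
  expect_equal(d$ext_start[1], 0)
  expect_equal(d$ext_end[2], 1.1e6 + 1000 + 1e6)
  # basal contained in extended for both
  expect_true(all(d$ext_start <= d$basal_start & d$basal_end <= d$ext_end))
  expect_error(extend_domains(rbind(g, g[1, ])), "duplicate")
})

test_that("domain construction matches the sorted-edge sweep oracle", {
  set.seed(17)
  for (rep in 1:8) {
    n <- 30
    g <- data.frame(gene_id = sprintf("g%02d", 1:n),
                    chrom = sample(c("chr1", "chr2"), n, replace = TRUE),
                    strand = sample(c("+", "-"), n, replace = TRUE),
                    tss = sample.int(8e6, n))
    d <- extend_domains(g)
    o <- sweep_domains_oracle(g)
    expect_equal(d$ext_start, o$ext_start)
    expect_equal(d$ext_end, o$ext_end)
    # invariant: basal inside extended, extension bounded by the maximum
    expect_true(all(d$ext_start <= d$basal_start & d$basal_end <= d$ext_end))
    expect_true(all(d$ext_start >= pmax(0, d$basal_start - 1e6)))
    expect_true(all(d$ext_end <= d$basal_end + 1e6))
  }
})

test_that("peaks map to genes whose extended domain they touch; deserts stay unassigned", {
  g <- data.frame(gene_id = c("near", "far"), chrom = "chr1",
                  strand = "+", tss = c(1e6, 9e6))
  d <- extend_domains(g)
  peaks <- genomic_intervals(
    c("chr1", "chr1", "chr2"),
    c(998000, 5e6, 100),        # inside near's basal; desert; wrong chrom
    c(998200, 5e6 + 200, 300)
  )
  asg <- assign_peaks(peaks, d)
  expect_equal(asg$peak_to_genes[[1]], "near")
  expect_equal(asg$unassigned, c(2L, 3L))
  expect_equal(asg$gene_to_peaks$near, 1L)
})

test_that("assignment equals the brute-force all-pairs overlap oracle", {
  set.seed(23)
  for (rep in 1:5) {
    g <- data.frame(gene_id = sprintf("g%02d", 1:15),
                    chrom = sample(c("chr1", "chr2"), 15, replace = TRUE),
                    strand = sample(c("+", "-"), 15, replace = TRUE),
                    tss = sample.int(6e6, 15))
    d <- extend_domains(g)
    pk <- random_intervals(80, max_pos = 7e6, max_width = 500)
    asg <- assign_peaks(pk, d)
    dom_iv <- data.frame(chrom = d$chrom, start = d$ext_start, end = d$ext_end)
    bf <- brute_force_pairs(pk, dom_iv, 0)
    expect_equal(asg$n_assignments, nrow(bf))
    got <- vapply(asg$peak_to_genes,
                  function(x) paste(sort(x), collapse = ","), "")
    want <- vapply(seq_len(nrow(pk)), function(i) {
      paste(sort(d$gene_id[bf$index_b[bf$index_a == i]]), collapse = ",")
    }, "")
    expect_equal(got, want)
  }
})

test_that("gene-set overlap summary reproduces the 68% worked arithmetic", {
  a <- sprintf("a%04d", 1:4647)
  b <- c(a[1:3143], sprintf("b%04d", 1:(8632 - 3143)))
  s <- gene_overlap_summary(a, b)
  expect_equal(s$n_a, 4647L)
  expect_equal(s$n_b, 8632L)
  expect_equal(s$n_shared, 3143L)
  expect_equal(s$pct_of_a_shared, 68)
  # symmetry of the shared count
  s2 <- gene_overlap_summary(b, a)
  expect_equal(s2$n_shared, s$n_shared)
  expect_equal(gene_overlap_summary(a, a)$pct_of_a_shared, 100)
  expect_equal(gene_overlap_summary(a, "zzz")$pct_of_a_shared, 0)
})

test_that("gene-list Fisher test agrees with hypergeometric enumeration", {
  bg <- sprintf("g%03d", 1:100)
  a <- bg[1:10]
  b <- c(bg[1:5], bg[51:55])
  got <- gene_list_fisher(a, b, bg)
  expect_equal(got$p_value, hypergeom_fisher_p(5, 10, 10, 100),
               tolerance = 1e-10)
  set.seed(29)
  for (rep in 1:15) {
    n_bg <- sample(50:500, 1)
    bg <- sprintf("g%04d", seq_len(n_bg))
    a <- sample(bg, sample.int(n_bg %/% 2, 1))
    b <- sample(bg, sample.int(n_bg %/% 2, 1))
    got <- gene_list_fisher(a, b, bg)
    want <- hypergeom_fisher_p(length(intersect(a, b)), length(a),
                               length(b), n_bg)
    expect_equal(got$p_value, want, tolerance = 1e-10)
  }
})

test_that("Fisher test is unremarkable at expectation and degenerate universes", {
  bg <- sprintf("g%03d", 1:100)
  expect_equal(gene_list_fisher(bg, bg, bg)$p_value, 1)
  # overlap equal to |A||B|/|bg| (20 * 25 / 100 = 5) is unremarkable
  a <- bg[1:20]
  b <- c(bg[1:5], bg[21:40])
  expect_gte(gene_list_fisher(a, b, bg)$p_value, 0.5)
  expect_error(gene_list_fisher(a, b, character(0)), "empty")
  expect_warning(gene_list_fisher(c(a, "not_in_bg"), b, bg), "dropped")
})

test_that("multi-isoform TSS tables collapse to the 5'-most TSS per gene", {
  g <- data.frame(gene_id = c("x", "x", "y", "y"), chrom = "chr1",
                  strand = c("+", "+", "-", "-"),
                  tss = c(500, 100, 900, 2000))
  out <- collapse_tss(g)
  expect_equal(out$tss[out$gene_id == "x"], 100)
  expect_equal(out$tss[out$gene_id == "y"], 2000)
})
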