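#' Run the full synthetic end-to-end pipeline
#'
#' Exercises every stage against freshly simulated data: simulate two
#' co-binding peak sets, build joint sites and summarize the bias split;
#' simulate a gene annotation, build regulatory domains, assign both peak
#' sets to genes, summarize the gene-set overlap and test it with Fisher's
#' exact test against the full simulated gene universe; simulate the
#' genotype/expression cohort, run the collapsed burden regression; merge
#' the paired summary statistics and compute the effect-size concordance.
#' All tabular outputs are written under `out_dir` together with a
#' `manifest.json` recording the package version, seed, configuration and
#' an MD5 checksum per output file, so identical inputs and seed reproduce
#' identical outputs.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer master seed; stage seeds are derived from it.
#' @param cobind_config,genetics_config Optional simulator configurations;
#'   their `seed` fields are overridden by the derived stage seeds.
#' @param n_genes Genes in the simulated annotation (default 200).
#' @param slop,bias_threshold Joint-site parameters (defaults 0 and 2).
#' @return Invisibly, a list with the in-memory stage results
#'   (`bias_summary`, `gene_overlap`, `fisher`, `burden_fit`,
#'   `concordance_fit`, ...) and `manifest_path`.
#' @export
run_pipeline <- function(out_dir, seed = 1,
                         cobind_config = NULL, genetics_config = NULL,
                         n_genes = 200, slop = 0, bias_threshold = 2) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(cobind_config)) cobind_config <- cobind_sim_config()
  if (is.null(genetics_config)) genetics_config <- genetics_sim_config()
  cobind_config$seed <- seed
  genetics_config$seed <- seed + 2L

  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(out_dir, written), force = TRUE))
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write_tsv_table(df, path)
    written <<- c(written, name)
    path
  }

  # -- co-binding stage -----------------------------------------------------
  sim_cb <- simulate_cobinding(cobind_config)
  joint <- build_joint_sites(sim_cb$peaks_a, sim_cb$peaks_b,
                             slop = slop, bias_threshold = bias_threshold)
  bias <- summarize_bias(joint)
  distinct <- count_distinct_overlapping(sim_cb$peaks_a, sim_cb$peaks_b, slop)
  emit(joint, "joint_sites.tsv")
  emit(data.frame(n_joint = bias$n_joint, n_biased = bias$n_biased,
                  n_a = bias$n_a, n_b = bias$n_b,
                  frac_a = bias$frac_a, frac_b = bias$frac_b),
       "bias_summary.tsv")

  # -- gene-assignment stage ------------------------------------------------
  genes <- simulate_genes(n_genes, sim_cb$chrom_lengths, seed = seed + 1L)
  domains <- extend_domains(genes, chrom_lengths = sim_cb$chrom_lengths)
  asg_a <- assign_peaks(sim_cb$peaks_a, domains)
  asg_b <- assign_peaks(sim_cb$peaks_b, domains)
  genes_a <- names(asg_a$gene_to_peaks)[lengths(asg_a$gene_to_peaks) > 0]
  genes_b <- names(asg_b$gene_to_peaks)[lengths(asg_b$gene_to_peaks) > 0]
  overlap <- gene_overlap_summary(genes_a, genes_b)
  fisher <- gene_list_fisher(genes_a, genes_b, background = genes$gene_id)
  emit(domains, "regulatory_domains.tsv")
  emit(data.frame(gene_id = rep(names(asg_a$gene_to_peaks),
                                lengths(asg_a$gene_to_peaks)),
                  peak_index = unlist(asg_a$gene_to_peaks, use.names = FALSE)),
       "assignments_a.tsv")
  emit(data.frame(n_a = overlap$n_a, n_b = overlap$n_b,
                  n_shared = overlap$n_shared,
                  pct_of_a_shared = overlap$pct_of_a_shared,
                  fisher_odds_ratio = fisher$odds_ratio,
                  fisher_p = fisher$p_value),
       "gene_overlap.tsv")

  # -- causality stage ------------------------------------------------------
  sim_gen <- simulate_genetics(genetics_config)
  cis <- select_cis_variants(sim_gen$variants, genetics_config$gene_chrom,
                             genetics_config$gene_start,
                             genetics_config$gene_end)
  profiles <- haplotype_profiles(sim_gen$dosage, cis$variant_id)
  groups <- collapse_by_profile(profiles, sim_gen$expression)
  burden_fit <- burden_regression(groups)
  emit(groups, "collapsed_groups.tsv")
  emit(data.frame(slope = burden_fit$slope, pearson_r = burden_fit$pearson_r,
                  p_value = burden_fit$p_value, n_groups = burden_fit$n),
       "burden_regression.tsv")

  # -- concordance stage ----------------------------------------------------
  pairs <- merge_summary(sim_gen$gwas_sumstats, sim_gen$eqtl_sumstats)
  conc_fit <- beta_correlation(pairs)
  emit(pairs, "merged_pairs.tsv")
  emit(data.frame(pearson_r = conc_fit$pearson_r, p_value = conc_fit$p_value,
                  slope = conc_fit$slope, n_pairs = conc_fit$n),
       "concordance.tsv")

  manifest <- list(
    package = "cobindcis",
    version = as.character(utils::packageVersion("cobindcis")),
    seed = seed,
    config = list(cobinding = unclass(cobind_config),
                  genetics = unclass(genetics_config),
                  n_genes = n_genes, slop = slop,
                  bias_threshold = bias_threshold),
    outputs = as.list(tools::md5sum(file.path(out_dir, sort(written))))
  )
  names(manifest$outputs) <- sort(written)
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  ok <- TRUE

  invisible(list(
    joint_sites = joint, bias_summary = bias,
    distinct_overlapping = distinct,
    gene_overlap = overlap, fisher = fisher,
    collapsed_groups = groups, burden_fit = burden_fit,
    merged_pairs = pairs, concordance_fit = conc_fit,
    manifest_path = manifest_path
  ))
}
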