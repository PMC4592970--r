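#' Run the full 4C analysis pipeline on a simulated study
#'
#' End-to-end driver: simulates a study (genome, planted interactome, two
#' replicate read libraries, feature tracks), calls distal sites per
#' replicate, calls enriched interacting domains on replicate 1, computes
#' replicate-concordance statistics (2 Mb bin Pearson correlation and the
#' relative-distance distribution), and runs the anchor-centric enrichment
#' suite. All outputs are written as plain text under `out_dir`; the run is
#' fully deterministic for a fixed config, so repeating it reproduces every
#' file byte for byte.
#'
#' @param config A [sim_config()].
#' @param out_dir Output directory.
#' @param params A [domain_params()]; its seed defaults to the config seed.
#' @return Invisibly, a list with the in-memory results (`sites_rep1`,
#'   `sites_rep2`, `scores`, `domains`, `concordance`, `enrichment`).
#' @export
run_4c_pipeline <- function(config = sim_config(), out_dir,
                            params = domain_params(seed = config$seed)) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  genome <- config$genome
  sim <- simulate_4c(config)
  rep2 <- simulate_read_pairs(sim$truth, config, seed = config$seed + 5L)
  write_simulation(sim, fp("sim"))

  cs1 <- call_sites(sim$reads$pairs, config$bait, genome)
  cs2 <- call_sites(rep2$pairs, config$bait, genome)
  write_sites_bed(cs1$sites, fp("sites_rep1.bed"))
  write_sites_bed(cs2$sites, fp("sites_rep2.bed"))
  .write_tsv(tibble::tibble(class = names(cs1$class_counts),
                            rep1 = as.integer(cs1$class_counts),
                            rep2 = as.integer(cs2$class_counts)),
             fp("class_counts.tsv"))

  scores <- site_zscores(cs1$sites, genome, params$window_length,
                         params$z_model)
  scores <- permutation_fdr(scores, genome, params)
  .write_tsv(scores, fp("site_scores.tsv"))
  domains <- call_enriched_domains(scores, genome, params)
  .write_tsv(domains, fp("domains.tsv"))

  bins1 <- bin_site_counts(cs1$sites, genome, params$window_length)
  bins2 <- bin_site_counts(cs2$sites, genome, params$window_length)
  rc <- replicate_correlation(bins1, bins2)
  rd <- relative_distance_distribution(cs1$sites, cs2$sites)
  .write_tsv(rd$histogram, fp("relative_distance_hist.tsv"))

  enr <- list()
  if (!is.null(sim$tracks)) {
    tr <- sim$tracks$tracks
    for (nm in c("H3K4me1", "H3K27ac", "H3K4me3", "H3K9ac", "DHS", "5hmC",
                 "H3K27me3", "H3K9me3")) {
      e <- peak_enrichment(cs1$sites, tr[[nm]], genome,
                           flank = config$enrichment_flank,
                           seed = config$seed + 6L)
      enr[[nm]] <- tibble::tibble(track = nm, test = "peak_flank_count",
                                  statistic = e$statistic, p_value = e$p_value)
    }
    for (nm in c("Oct4", "Klf4", "Esrrb", "Tcfcp2l1", "Zfx", "Suz12")) {
      e <- tf_tag_enrichment(cs1$sites, tr[[nm]], genome,
                             control_tags = tr$input,
                             flank = config$tf_flank,
                             seed = config$seed + 7L)
      enr[[nm]] <- tibble::tibble(track = nm, test = "tf_tag_count",
                                  statistic = e$statistic, p_value = e$p_value)
    }
    tp <- replication_timing_profile(cs1$sites, tr$timing, genome,
                                     flank = config$timing_flank,
                                     seed = config$seed + 8L)
    enr[["timing"]] <- tibble::tibble(track = "timing",
                                      test = "timing_window_mean",
                                      statistic = tp$statistic,
                                      p_value = tp$p_value)
    dd <- distance_density(cs1$sites, sim$annotation$tss, genome,
                           seed = config$seed + 9L)
    enr[["tss"]] <- tibble::tibble(track = "TSS", test = "abs_distance",
                                   statistic = dd$statistic,
                                   p_value = dd$p_value)
    ge <- gene_assignment_and_expression(cs1$sites, sim$annotation$genes,
                                         sim$tracks$fpkm, genome,
                                         seed = config$seed + 10L)
    enr[["expression"]] <- tibble::tibble(track = "FPKM",
                                          test = "welch_t",
                                          statistic = ge$statistic,
                                          p_value = ge$p_value)
  }
  enr_tbl <- if (length(enr)) do.call(rbind, enr) else NULL
  if (!is.null(enr_tbl)) .write_tsv(enr_tbl, fp("enrichment.tsv"))

  summary <- list(
    n_sites_rep1 = nrow(cs1$sites),
    n_sites_rep2 = nrow(cs2$sites),
    n_significant = sum(scores$significant),
    n_domains = nrow(domains),
    bin_pearson_r = rc$r,
    relative_distance_ks_p = rd$ks_p
  )
  jsonlite::write_json(summary, fp("summary.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(sites_rep1 = cs1$sites, sites_rep2 = cs2$sites,
                 scores = scores, domains = domains,
                 concordance = list(r = rc$r, relative_distance = rd),
                 enrichment = enr_tbl))
}
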