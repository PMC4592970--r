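# shared study configurations for the simulation-based tests

# clean library: no noise, no duplicates, no quality degradation
clean_config <- function(seed = 1L, ...) {
  sim_config(noise_fraction = 0, duplicate_rate = 0,
             mapq_degraded_fraction = 0, seed = seed, ...)
}

# small genome for sequence/FASTQ-level tests
small_config <- function(seed = 1L, ...) {
  sim_config(genome = genome_def(paste0("chr", 1:3), rep(2e6, 3)),
             bait = bait_region("chr1", 1e6, 1e6 + 600),
             n_hotspots = 2, sites_per_hotspot = 5, n_background_sites = 60,
             n_features_per_track = 100, n_tf_tags = 2000, n_input_tags = 2000,
             n_genes = 60, seed = seed, ...)
}

# association study conditions: sparse sites on a large genome so that the
# 0.5 Mb counting flank is small relative to inter-site spacing
assoc_config <- function(seed = 1L, null = FALSE, ...) {
  eff <- if (null) {
    list(track_enrichment = 1, timing_shift = 0,
         fpkm_meanlog = c(interacting = log(5), background = log(5)))
  } else {
    list()
  }
  do.call(sim_config, c(
    list(genome = genome_def(paste0("chr", 1:3), rep(1e8, 3)),
         bait = bait_region("chr1", 5e7, 5e7 + 600),
         n_hotspots = 0, n_background_sites = 100,
         n_genes = 2000, seed = seed, ...),
    eff
  ))
}

# power-study genome: three 30 Mb chromosomes (window/chromosome ratio near
# the real-genome regime for the 2 Mb scoring window)
power_genome <- function() genome_def(paste0("chr", 1:3), rep(3e7, 3))

power_config <- function(seed) {
  sim_config(genome = power_genome(),
             bait = bait_region("chr1", 1.5e7, 1.5e7 + 600), seed = seed)
}

truth_sites <- function(truth) {
  genomic_sites(truth$sites$chrom, truth$sites$pos)
}

# hotspot recovery / false-domain counts for a called domain set
recovery_stats <- function(truth, domains) {
  hs <- truth$hotspots
  rec <- vapply(seq_len(nrow(hs)), function(h) {
    any(domains$chrom == hs$chrom[h] & domains$start < hs$end[h] &
          domains$end > hs$start[h])
  }, TRUE)
  false_dom <- vapply(seq_len(nrow(domains)), function(k) {
    !any(hs$chrom == domains$chrom[k] & hs$start < domains$end[k] &
           hs$end > domains$start[k])
  }, TRUE)
  c(recovered = sum(rec), false_domains = sum(false_dom))
}

# uniform random site set (test-side construction, independent of the
# package's shuffling code)
uniform_sites <- function(n, genome, seed) {
  set.seed(seed)
  len <- stats::setNames(genome$length, genome$chrom)
  ch <- sample(genome$chrom, n, replace = TRUE, prob = genome$length)
  genomic_sites(ch, floor(runif(n, 0, len[ch])))
}
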