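test_that("peak enrichment separates planted tracks and not site-independent ones", {
  cfg <- assoc_config(seed = 21)
  sim <- simulate_4c(cfg, reads = FALSE)
  st <- truth_sites(sim$truth)
  active <- peak_enrichment(st, sim$tracks$tracks$H3K27ac, cfg$genome,
                            seed = 5)
  expect_lt(active$p_value, 1e-4)
  expect_gt(mean(active$anchor_counts), mean(active$random_counts))
  repressive <- peak_enrichment(st, sim$tracks$tracks$H3K27me3, cfg$genome,
                                seed = 5)
  expect_gt(repressive$p_value, 1e-3)
  expect_error(peak_enrichment(st[1, ], sim$tracks$tracks$DHS, cfg$genome,
                               seed = 1), "at least 2")
})

test_that("tag normalization follows the 10-million-tag convention", {
  # library of 20 M tags, raw count 30 -> normalized 15
  gn <- genome_def("chr1", 1e6)
  sites <- genomic_sites("chr1", c(5e5, 9e5))
  tags <- point_track("tf", "chr1", c(rep(5e5, 30), 1e5))
  r <- tf_tag_enrichment(sites, tags, gn, chip_total = 2e7, seed = 2)
  expect_equal(max(r$anchor_counts), 30 * (1e7 / 2e7))
  # identical chip and control cancel to zero everywhere, p = 1
  r2 <- tf_tag_enrichment(sites, tags, gn, control_tags = tags,
                          chip_total = 2e7, control_total = 2e7, seed = 2)
  expect_true(all(r2$anchor_counts == 0))
  expect_equal(r2$p_value, 1)
  expect_error(tf_tag_enrichment(sites, tags, gn, chip_total = 0, seed = 1),
               "positive")
})

test_that("tag normalization is invariant to doubling library and counts", {
  cfg <- assoc_config(seed = 22)
  sim <- simulate_4c(cfg, reads = FALSE)
  st <- truth_sites(sim$truth)
  tr <- sim$tracks$tracks$Oct4
  r1 <- tf_tag_enrichment(st, tr, cfg$genome, chip_total = 5e4, seed = 7)
  doubled <- point_track("Oct4x2", rep(tr$intervals$chrom, 2),
                         rep(tr$intervals$start, 2))
  r2 <- tf_tag_enrichment(st, doubled, cfg$genome, chip_total = 1e5, seed = 7)
  expect_equal(r2$anchor_counts, r1$anchor_counts)
  # and the planted TF is strongly enriched with background subtraction
  r3 <- tf_tag_enrichment(st, tr, cfg$genome,
                          control_tags = sim$tracks$tracks$input, seed = 7)
  expect_lt(r3$p_value, 1e-4)
})

test_that("timing window means equal the exact piecewise-constant integral", {
  gn <- genome_def("chr1", 1e6)
  segs <- feature_track("timing",
                        gintervals("chr1", c(0, 4e5), c(4e5, 1e6),
                                   value = c(2, -1)),
                        kind = "valued_segment")
  # window [350000, 450000): 50 kb at +2 and 50 kb at -1
  tp <- replication_timing_profile(genomic_sites("chr1", 4e5),
                                   segs, gn, flank = 5e4, seed = 3)
  expect_equal(tp$site_means, (5e4 * 2 + 5e4 * -1) / 1e5)
  # constant field: every mean equals the constant and p ~ 1
  const <- feature_track("t1", gintervals("chr1", 0, 1e6, value = 1),
                         kind = "valued_segment")
  tpc <- replication_timing_profile(genomic_sites("chr1", c(2e5, 8e5)),
                                    const, gn, seed = 4)
  expect_equal(tpc$site_means, c(1, 1))
  expect_equal(tpc$p_value, 1)
  expect_equal(tpc$early_fraction, 1)
  # randomized agreement with a brute-force integrator
  set.seed(5)
  bnd <- sort(sample.int(1e6 - 1, 40))
  iv <- gintervals("chr1", c(0, bnd), c(bnd, 1e6),
                   value = round(rnorm(41), 2))
  trk <- feature_track("t", iv, kind = "valued_segment")
  sites <- uniform_sites(50, gn, seed = 6)
  tpr <- replication_timing_profile(sites, trk, gn, flank = 3e4, seed = 7)
  brute <- vapply(sites$pos, function(p) {
    lo <- p - 3e4
    hi <- p + 3e4
    ov <- pmin(iv$end, hi) - pmax(iv$start, lo)
    keep <- ov > 0
    sum(iv$value[keep] * ov[keep]) / sum(ov[keep])
  }, 0)
  expect_equal(tpr$site_means, brute)
})

test_that("planted timing shift is detected against the shuffle baseline", {
  cfg <- assoc_config(seed = 23)
  sim <- simulate_4c(cfg, reads = FALSE)
  tp <- replication_timing_profile(truth_sites(sim$truth),
                                   sim$tracks$tracks$timing, cfg$genome,
                                   seed = 8)
  expect_lt(tp$p_value, 1e-4)
  expect_gt(mean(tp$site_means), 0.5)
  # the length-weighted segment baseline is also available
  tp2 <- replication_timing_profile(truth_sites(sim$truth),
                                    sim$tracks$tracks$timing, cfg$genome,
                                    baseline = "segments", seed = 8)
  expect_lt(tp2$p_value, 1e-4)
})

test_that("distance density peaks at zero when sites sit on their anchors", {
  cfg <- assoc_config(seed = 24)
  sim <- simulate_4c(cfg, reads = FALSE)
  tss <- sim$annotation$tss
  on_tss <- genomic_sites(tss$intervals$chrom[1:100],
                          tss$intervals$start[1:100])
  dd <- distance_density(on_tss, tss, cfg$genome, seed = 9)
  expect_lt(dd$p_value, 1e-10)
  expect_true(all(dd$site_distances == 0))
  peak0 <- dd$density_sites$y[which.min(abs(dd$density_sites$x))]
  # halving the bandwidth concentrates the point mass further
  dd2 <- distance_density(on_tss, tss, cfg$genome, seed = 9,
                          bandwidth = dd$bandwidth / 2)
  peak0b <- dd2$density_sites$y[which.min(abs(dd2$density_sites$x))]
  expect_gte(peak0b, peak0)
  # uniform sites are indistinguishable from shuffled sites
  dd3 <- distance_density(truth_sites(sim$truth), tss, cfg$genome, seed = 10)
  expect_gt(dd3$p_value, 1e-3)
})

test_that("gene assignment uses overlap-or-nearest with declared tie rules", {
  genes <- feature_track("genes",
                         gintervals("chr1", c(100, 150, 1000), c(300, 400, 1200),
                                    name = c("gA", "gB", "gC")),
                         kind = "peak")
  # site inside two overlapping genes: both assigned
  expect_setequal(assign_genes_to_sites(genomic_sites("chr1", 200), genes),
                  c("gA", "gB"))
  # site in no gene: single nearest assigned
  expect_equal(assign_genes_to_sites(genomic_sites("chr1", 600), genes),
               "gB")
  tie_genes <- feature_track("g", gintervals("chr1", c(0, 201), c(100, 301),
                                             name = c("L", "R")),
                             kind = "peak")
  expect_equal(assign_genes_to_sites(genomic_sites("chr1", 149), tie_genes),
               "L") # 50 bp from L's last base, 52 from R's start
  expect_equal(assign_genes_to_sites(genomic_sites("chr1", 150), tie_genes),
               "L") # exact tie (51/51) breaks to the lower coordinate
})

test_that("expression of interacting genes exceeds random genes when planted", {
  cfg <- assoc_config(seed = 25)
  sim <- simulate_4c(cfg, reads = FALSE)
  ge <- gene_assignment_and_expression(truth_sites(sim$truth),
                                       sim$annotation$genes,
                                       sim$tracks$fpkm, cfg$genome, seed = 11)
  expect_lt(ge$p_value, 1e-3)
  expect_gt(ge$mean_fpkm, ge$mean_random_fpkm)
  expect_equal(ge$n_missing_fpkm, 0)
  # dropped ids are counted
  fp2 <- sim$tracks$fpkm[-1, ]
  first_id <- sim$tracks$fpkm$gene_id[1]
  ge2 <- gene_assignment_and_expression(truth_sites(sim$truth),
                                        sim$annotation$genes, fp2,
                                        cfg$genome, seed = 11)
  expect_equal(ge2$n_missing_fpkm,
               as.integer(first_id %in% ge$gene_ids))
})
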