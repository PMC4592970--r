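test_that("window counts match the brute-force pairwise-distance count", {
  gn <- genome_def("chr1", 1e6)
  sites <- genomic_sites("chr1", c(1000, 2000, 500000))
  expect_equal(window_counts(sites, gn, 10000), c(2L, 2L, 1L))
  expect_equal(window_counts(genomic_sites("chr1", 7), gn, 10000), 1L)
  # saturation: window covering the chromosome counts everything
  expect_equal(window_counts(sites, gn, 2e6), rep(3L, 3))
  for (s in 1:25) {
    inst <- random_instance(s, n_sites = 400)
    lw <- sample(c(1000, 20000, 200000), 1)
    expect_equal(window_counts(inst$sites, inst$genome, lw),
                 brute_window_counts(inst$sites, lw))
  }
})

test_that("z-scores follow the Poisson standardization of window counts", {
  # N_W = 10 sites on a 1 Mb chromosome, lw = 100 kb: mu = 1
  gn <- genome_def("chr1", 1e6)
  pos <- c(0, 100, 200, 300, 2e5, 3e5, 4e5, 6e5, 8e5, 9.9e5)
  sc <- site_zscores(genomic_sites("chr1", pos), gn, lw = 1e5)
  expect_equal(unique(sc$mu), 1.0)
  expect_equal(sc$z[1], (sc$C[1] - 1) / 1) # sqrt(mu) = 1
  expect_equal(sc$C[1], 4L) # the 4 clustered sites
  expect_equal(sc$z[sc$C == 1], rep(0, sum(sc$C == 1))) # C = mu -> z = 0
  for (s in 1:20) {
    inst <- random_instance(s, n_sites = 300)
    sc <- site_zscores(inst$sites, inst$genome, lw = 50000)
    expect_equal(sc$z, brute_zscores(inst$sites, inst$genome, 50000))
  }
  # binomial variant scales by sqrt(1 - lw/L)
  scb <- site_zscores(genomic_sites("chr1", pos), gn, lw = 1e5,
                      z_model = "binomial")
  scp <- site_zscores(genomic_sites("chr1", pos), gn, lw = 1e5)
  expect_equal(scb$z, scp$z / sqrt(1 - 1e5 / 1e6))
})

test_that("empirical z mean under a uniform null matches its expectation", {
  # E[C] = 1 + (n-1)(lw - h^2/L)/L  (self-count plus edge truncation),
  # while mu = n lw / L, so E[z] is slightly positive at finite density
  gn <- genome_def("chr1", 1e7)
  n <- 500
  lw <- 2e5
  h <- lw / 2
  mu <- n * lw / 1e7
  expected <- (1 + (n - 1) * (lw - h^2 / 1e7) / 1e7 - mu) / sqrt(mu)
  zs <- unlist(lapply(1:30, function(s) {
    set.seed(s)
    site_zscores(genomic_sites("chr1", sample.int(1e7, n)), gn, lw)$z
  }))
  expect_lt(abs(mean(zs) - expected), 0.05)
})

test_that("permutation FDR is deterministic, monotone and flags planted clusters", {
  gn <- genome_def("chr1", 1e7)
  set.seed(99)
  bg <- sample.int(1e7, 1000)
  cluster <- 5e6 + sample.int(50000, 20)
  sites <- genomic_sites("chr1", c(bg, cluster))
  # window of 200 kb: every cluster site sees the whole planted cluster
  sc <- site_zscores(sites, gn, lw = 2e5)
  p1 <- permutation_fdr(sc, gn, domain_params(seed = 21))
  p2 <- permutation_fdr(sc, gn, domain_params(seed = 21))
  expect_identical(p1$fdr, p2$fdr)
  # monotone: sorting by descending z gives non-decreasing FDR
  o <- order(p1$z, decreasing = TRUE)
  expect_true(all(diff(p1$fdr[o]) >= 0))
  # the planted cluster carries the top z and is called significant
  in_cluster <- sites$pos >= 5e6 & sites$pos <= 5e6 + 50000
  expect_true(all(p1$significant[in_cluster]))
  expect_gte(min(p1$z[in_cluster]), max(p1$z[!in_cluster & p1$pos < 4.5e6]))
})

test_that("domain merging matches the interval-union oracle", {
  gn <- genome_def("chr1", 1e7)
  params <- domain_params(seed = 1)
  mk_scores <- function(pos, sig) {
    sc <- site_zscores(genomic_sites("chr1", pos), gn, 2e6)
    sc$fdr <- ifelse(sig, 0.01, 0.5)
    sc$significant <- sig
    sc
  }
  # two significant sites 1.5 Mb apart: seeds overlap, one domain
  sc <- mk_scores(c(3e6, 4.5e6), c(TRUE, TRUE))
  d <- call_enriched_domains(sc, gn, params)
  expect_equal(nrow(d), 1)
  expect_equal(d$start, 2e6)
  expect_equal(d$end, 5.5e6 + 1)
  # no significant sites: empty list
  expect_equal(nrow(call_enriched_domains(mk_scores(c(1e6, 2e6), c(FALSE, FALSE)),
                                          gn, params)), 0)
  # one significant site mid-chromosome: one 2 Mb domain centred on it
  d1 <- call_enriched_domains(mk_scores(5e6, TRUE), gn, params)
  expect_equal(d1$end - d1$start, 2e6 + 1)
  # non-significant members are absorbed and counted
  sc3 <- mk_scores(c(3e6, 3.4e6, 8e6), c(TRUE, FALSE, FALSE))
  d3 <- call_enriched_domains(sc3, gn, params)
  expect_equal(d3$n_sites, 2L)
  expect_equal(d3$n_significant, 1L)
  # randomized equivalence with the brute-force oracle, plus order invariance
  for (s in 1:15) {
    set.seed(s)
    n <- 200
    pos <- sample.int(1e7, n)
    sig <- runif(n) < 0.05
    sc <- mk_scores(pos, sig)
    got <- call_enriched_domains(sc, gn, domain_params(seed = s))
    oracle <- brute_domains(sc, gn, 1e6)
    expect_equal(got$start, oracle$start)
    expect_equal(got$end, oracle$end)
    expect_equal(got$n_sites, oracle$n_sites)
    got2 <- call_enriched_domains(sc[sample.int(n), ], gn,
                                  domain_params(seed = s))
    expect_equal(got, got2)
    if (nrow(got) > 1) {
      expect_true(all(got$start[-1] >= got$end[-nrow(got)] |
                        got$chrom[-1] != got$chrom[-nrow(got)]))
    }
  }
})

test_that("region overlap counting uses connected-component semantics", {
  a <- gintervals("chr1", 0, 10)
  b <- gintervals("chr1", 5, 20)
  expect_equal(overlap_regions(a, b)$n_overlap, 1L)
  expect_equal(overlap_regions(a, gintervals("chr1", 50, 60))$n_overlap, 0L)
  # one a-region catching two b-regions is a single component
  ov <- overlap_regions(gintervals("chr1", 0, 100),
                        gintervals("chr1", c(10, 30), c(20, 40)))
  expect_equal(ov$n_overlap, 1L)
  expect_equal(ov$components$n_a, 1L)
  expect_equal(ov$components$n_b, 2L)
  # book-ended regions share no base and do not overlap
  expect_equal(overlap_regions(gintervals("chr1", 0, 10),
                               gintervals("chr1", 10, 20))$n_overlap, 0L)
  expect_error(overlap_regions(gintervals("chr1", c(0, 5), c(10, 15)), b),
               "overlapping")
})
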