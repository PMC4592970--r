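test_that("BED and bedGraph parsing maps fields and rejects malformed lines", {
  gn <- genome_def(c("chr1", "chr2"), c(1e6, 1e6))
  bed <- tempfile(fileext = ".bed")
  writeLines(c("track name=demo", "chr1\t100\t200\tpeakA", "chr2\t0\t50"), bed)
  tr <- read_bed(bed, kind = "peak", genome = gn)
  expect_equal(tr$intervals$chrom, c("chr1", "chr2"))
  expect_equal(tr$intervals$start, c(100, 0))
  expect_equal(tr$intervals$end, c(200, 50))
  expect_equal(tr$intervals$name[1], "peakA")

  bg <- tempfile(fileext = ".bedgraph")
  writeLines("chr2\t0\t1000\t1.5", bg)
  vt <- read_bed(bg, kind = "valued_segment")
  expect_equal(vt$intervals$value, 1.5)

  empty <- tempfile(fileext = ".bed")
  writeLines(character(0), empty)
  expect_equal(nrow(read_bed(empty)$intervals), 0)

  bad <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t10\t20", "chr1\t300\t200"), bad)
  expect_error(read_bed(bad), "line 2.*start >= end")
  writeLines("chr1\tten\t20", bad)
  expect_error(read_bed(bad), "line 1.*non-integer")

  unk <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t1\t2", "chrX\t1\t2"), unk)
  expect_error(read_bed(unk, genome = gn, strict = TRUE), "chrX")
  expect_equal(nrow(read_bed(unk, genome = gn)$intervals), 1)
})

test_that("BED round-trip preserves the 0-based half-open coordinates", {
  iv <- gintervals(c("chr1", "chr1", "chr2"), c(0, 500, 10),
                   c(100, 600, 11), name = c("a", "b", "c"))
  tr <- feature_track("t", iv, kind = "peak")
  f <- tempfile(fileext = ".bed")
  write_bed(tr, f)
  back <- read_bed(f, kind = "peak")
  expect_equal(back$intervals$start, iv$start)
  expect_equal(back$intervals$end, iv$end)
  expect_equal(back$intervals$name, iv$name)

  vt <- feature_track("v", gintervals("chr1", c(0, 1000), c(1000, 2500),
                                      value = c(-0.5, 1.25)),
                      kind = "valued_segment")
  g <- tempfile(fileext = ".bedgraph")
  write_bed(vt, g)
  expect_equal(read_bed(g, kind = "valued_segment")$intervals$value,
               c(-0.5, 1.25))
})

test_that("merge_overlapping handles overlap, book-ends and disjoint input", {
  m <- merge_overlapping(gintervals("c", c(0, 5), c(10, 20)))
  expect_equal(m$start, 0)
  expect_equal(m$end, 20)
  m2 <- merge_overlapping(gintervals("c", c(0, 10), c(10, 20)))
  expect_equal(nrow(m2), 1) # book-ended rule
  expect_equal(m2$end, 20)
  m3 <- merge_overlapping(gintervals("c", c(0, 10), c(10, 20)),
                          bookended = FALSE)
  expect_equal(nrow(m3), 2)
  dis <- gintervals("c", c(0, 50), c(10, 60))
  expect_equal(merge_overlapping(dis)[, c("start", "end")],
               dis[, c("start", "end")])
})

test_that("merge_overlapping is idempotent and conserves covered bases", {
  for (s in 1:20) {
    inst <- random_instance(s, n_iv = 150)
    m <- merge_overlapping(inst$intervals)
    expect_true(all(m$start[-1] > m$end[-nrow(m)] |
                      m$chrom[-1] != m$chrom[-nrow(m)]))
    m2 <- merge_overlapping(m)
    expect_equal(m2[, c("chrom", "start", "end")],
                 m[, c("chrom", "start", "end")])
    # covered bases via explicit per-base union on a coarse check
    cov_in <- sum(vapply(split(inst$intervals, inst$intervals$chrom),
                         function(d) {
                           length(unique(unlist(mapply(seq, d$start, d$end - 1,
                                                       SIMPLIFY = FALSE))))
                         }, 0))
    expect_equal(sum(m$end - m$start), cov_in)
  }
})

test_that("flank counting and nearest distances match the brute-force scan", {
  for (s in 1:30) {
    inst <- random_instance(s)
    tr <- feature_track("t", inst$intervals, kind = "peak")
    flank <- sample(c(500, 5000, 50000), 1)
    expect_identical(
      count_features_in_flank(inst$sites, tr, flank, inst$genome),
      brute_count_flank(inst$sites, inst$intervals, flank)
    )
    nd <- nearest_feature_distance(inst$sites, tr, inst$genome)
    expect_equal(as.numeric(nd), brute_nearest(inst$sites, inst$intervals))
  }
})

test_that("flank counting handles the documented edge cases", {
  gn <- genome_def("chr1", 1e6)
  sites <- genomic_sites("chr1", 5000)
  peaks <- feature_track("p", gintervals("chr1", c(4000, 900000),
                                         c(4100, 900100)), kind = "peak")
  expect_identical(count_features_in_flank(sites, peaks, 10000, gn), 1L)
  empty <- feature_track("e", gintervals(character(), numeric(), numeric()))
  expect_identical(count_features_in_flank(sites, empty, 10000, gn), 0L)
  spanning <- feature_track("s", gintervals("chr1", 4999, 5002))
  expect_gte(count_features_in_flank(sites, spanning, 1, gn), 1L)
  bad_sites <- genomic_sites("chrZ", 10)
  expect_error(count_features_in_flank(bad_sites, peaks, 100, gn), "chrZ")
})

test_that("nearest distance signs, ties and sentinels follow the contract", {
  tss <- point_track("TSS", c("chr1", "chr1"), c(300, 900))
  expect_equal(as.numeric(nearest_feature_distance(genomic_sites("chr1", 500), tss)),
               200) # nearest is 300, anchor downstream -> positive
  expect_equal(as.numeric(nearest_feature_distance(genomic_sites("chr1", 300), tss)),
               0)
  # equidistant: 600 is 300 from both; tie breaks to the lower coordinate
  expect_equal(as.numeric(nearest_feature_distance(genomic_sites("chr1", 600), tss)),
               300)
  d <- nearest_feature_distance(genomic_sites("chr2", 10), tss)
  expect_true(is.na(d[1]))
  expect_equal(attr(d, "n_missing"), 1)
})

test_that("shuffle_sites conserves counts, is seed-deterministic and unbiased", {
  gn <- genome_def(c("chr1", "chr2"), c(1e6, 4e5))
  sites <- genomic_sites(rep(c("chr1", "chr2"), c(10, 5)), rep(100, 15))
  s1 <- shuffle_sites(sites, gn, seed = 42)
  expect_equal(table(s1$chrom), table(sites$chrom))
  expect_identical(s1, shuffle_sites(sites, gn, seed = 42))
  expect_false(identical(s1$pos, shuffle_sites(sites, gn, seed = 43)$pos))
  # law of large numbers: mean position ~ chromosome midpoint
  big <- genomic_sites(rep("chr1", 10000), rep(0, 10000))
  m <- mean(shuffle_sites(big, gn, seed = 7)$pos)
  expect_lt(abs(m - 5e5), 4 * 1e6 / sqrt(12 * 10000))
  gw <- shuffle_sites(sites, gn, seed = 1, mode = "genome_wide")
  expect_equal(nrow(gw), nrow(sites))
  mask <- feature_track("m", gintervals("chr1", 0, 9e5))
  sm <- shuffle_sites(sites, gn, seed = 5, exclude = mask)
  expect_true(all(sm$pos[sm$chrom == "chr1"] > 9e5))
})

test_that("chrom sizes round-trip through the two-column text format", {
  gn <- genome_def(c("chrA", "chrB"), c(12345, 678))
  f <- tempfile()
  write_chrom_sizes(gn, f)
  expect_equal(read_chrom_sizes(f), gn)
  expect_error(genome_def(c("a", "a"), c(1, 2)), "unique")
  expect_error(genome_def("a", 0), "positive")
})
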