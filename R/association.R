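# Anchor-centric integrative analyses: every comparison contrasts a statistic
# computed at the 4C sites with the identical statistic at matched randomly
# shuffled sites (per-chromosome-preserving shuffle, see shuffle_sites()).

.wilcox_p <- function(x, y, alternative) {
  # all-tied samples carry no evidence; wilcox.test would return NaN
  if (length(unique(c(x, y))) == 1L) {
    return(list(statistic = length(x) * length(y) / 2, p.value = 1))
  }
  w <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative))
  list(statistic = unname(w$statistic), p.value = w$p.value)
}

.new_enrichment <- function(track_name, anchor, random, stat, p, direction,
                            extra = list()) {
  structure(c(list(track = track_name, n_anchor = length(anchor),
                   n_random = length(random), anchor_counts = anchor,
                   random_counts = random, statistic = stat, p_value = p,
                   direction = direction), extra),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("<enrichment_result> %s: W = %.1f, p = %.3g (%s; n = %d anchors)\n",
              x$track, x$statistic, x$p_value, x$direction, x$n_anchor))
  cat(sprintf("  mean count: anchors %.2f vs random %.2f\n",
              mean(x$anchor_counts), mean(x$random_counts)))
  invisible(x)
}

#' Feature-count enrichment around sites versus random sites
#'
#' Counts the track features within `+/- flank` of each site and of each
#' matched shuffled site, and compares the two count samples with a Wilcoxon
#' rank-sum test (one-sided "greater" by default, i.e. enrichment at sites).
#'
#' @param sites Sites tibble (at least 2 sites).
#' @param track Peak or point [feature_track()].
#' @param genome A [genome_def()].
#' @param flank Half-window in bp (default 5e5, i.e. +/- 0.5 Mb).
#' @param seed Seed for the random-site shuffle.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @param n_shuffles Number of matched shuffles pooled into the random sample
#'   (default 1).
#' @return An `enrichment_result`.
#' @export
peak_enrichment <- function(sites, track, genome, flank = 5e5, seed = 1L,
                            alternative = c("greater", "two.sided"),
                            n_shuffles = 1) {
  alternative <- match.arg(alternative)
  .assert(nrow(sites) >= 2, "need at least 2 anchor sites")
  anchor <- count_features_in_flank(sites, track, flank, genome)
  random <- unlist(lapply(seq_len(n_shuffles), function(k) {
    rs <- shuffle_sites(sites, genome, seed = seed + k - 1)
    count_features_in_flank(rs, track, flank, genome)
  }))
  w <- .wilcox_p(anchor, random, alternative)
  .new_enrichment(track$name, anchor, random, w$statistic, w$p.value,
                  alternative, list(flank = flank, seed = seed))
}

#' Normalized, background-subtracted ChIP tag enrichment at sites
#'
#' Counts ChIP-seq tags within `+/- flank` (default 1 kb) of each site,
#' scales counts to a common sequencing depth (`norm_total`, default 10
#' million tags), optionally subtracts the identically normalized control
#' (input) count with a floor at 0, and compares against the identical
#' computation at matched shuffled sites by Wilcoxon rank-sum test.
#'
#' @param sites Sites tibble.
#' @param chip_tags Point [feature_track()] of ChIP tag positions.
#' @param genome A [genome_def()].
#' @param control_tags Optional point track of input/control tags.
#' @param chip_total,control_total Library sizes; default to the number of
#'   tags in each track. Must be positive.
#' @param flank Half-window in bp (default 1000).
#' @param norm_total Depth to normalize to (default 1e7).
#' @param seed Seed for the random-site shuffle.
#' @param alternative `"greater"` (default) or `"two.sided"`.
#' @return An `enrichment_result` whose count vectors are normalized
#'   (background-subtracted when a control is given).
#' @export
tf_tag_enrichment <- function(sites, chip_tags, genome, control_tags = NULL,
                              chip_total = NULL, control_total = NULL,
                              flank = 1000, norm_total = 1e7, seed = 1L,
                              alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  .assert(nrow(sites) >= 2, "need at least 2 anchor sites")
  if (is.null(chip_total)) chip_total <- nrow(.track_intervals(chip_tags))
  .assert(chip_total > 0, "chip library size must be positive")
  if (!is.null(control_tags) && is.null(control_total)) {
    control_total <- nrow(.track_intervals(control_tags))
  }
  if (!is.null(control_tags)) {
    .assert(control_total > 0, "control library size must be positive")
  }
  norm_counts <- function(s) {
    x <- count_features_in_flank(s, chip_tags, flank, genome) *
      (norm_total / chip_total)
    if (!is.null(control_tags)) {
      bg <- count_features_in_flank(s, control_tags, flank, genome) *
        (norm_total / control_total)
      x <- pmax(x - bg, 0)
    }
    x
  }
  anchor <- norm_counts(sites)
  random <- norm_counts(shuffle_sites(sites, genome, seed = seed))
  w <- .wilcox_p(anchor, random, alternative)
  .new_enrichment(chip_tags$name, anchor, random, w$statistic, w$p.value,
                  alternative,
                  list(flank = flank, norm_total = norm_total, seed = seed))
}

# length-weighted mean of piecewise-constant segment values over windows
# [lo, hi) on one chromosome; segs sorted, assumed non-overlapping
.window_means_chrom <- function(lo, hi, st, en, val) {
  out <- rep(NA_real_, length(lo))
  for (k in seq_along(lo)) {
    i1 <- .n_leq(lo[k], en) + 1 # first segment with end > lo
    i2 <- .n_less(hi[k], st) # last segment with start < hi
    if (i1 > i2) next
    idx <- i1:i2
    ov <- pmin(en[idx], hi[k]) - pmax(st[idx], lo[k])
    keep <- ov > 0
    if (!any(keep)) next
    out[k] <- sum(val[idx][keep] * ov[keep]) / sum(ov[keep])
  }
  out
}

#' Replication-timing profile around sites
#'
#' Computes, per site, the length-weighted mean log2(early/late) replication
#' timing over `+/- flank` (the exact integral of the piecewise-constant
#' track over the window divided by covered length), and tests for a shift
#' toward early replication (positive values) against a baseline by one-sided
#' Wilcoxon rank-sum test. Sites whose window intersects no segment are
#' skipped and counted. Segments with value > 0 are labelled
#' early-replicating.
#'
#' The default baseline applies the identical window computation at matched
#' shuffled sites (exchangeable with the site sample under the null);
#' `baseline = "segments"` instead uses the genome-wide segment value
#' distribution, length-weighted by replicating each segment's value
#' proportionally to its length.
#'
#' @param sites Sites tibble.
#' @param timing Valued-segment [feature_track()] of log2 early/late ratios.
#' @param genome A [genome_def()].
#' @param flank Half-window in bp (default 5e4, i.e. +/- 50 kb).
#' @param baseline `"shuffle"` (default) or `"segments"`.
#' @param seed Seed for the shuffle baseline.
#' @param alternative Test direction (default `"greater"`: sites earlier than
#'   baseline).
#' @return A `timing_profile` list: `site_means`, `n_skipped`,
#'   `baseline_values`, `statistic`, `p_value`, `early_fraction` (fraction of
#'   site windows with positive mean) and `baseline_early_fraction`.
#' @export
replication_timing_profile <- function(sites, timing, genome, flank = 5e4,
                                       baseline = c("shuffle", "segments"),
                                       seed = 1L,
                                       alternative = c("greater", "two.sided")) {
  baseline <- match.arg(baseline)
  alternative <- match.arg(alternative)
  .assert(inherits(timing, "feature_track") && timing$kind == "valued_segment",
          "timing must be a valued_segment track")
  iv <- timing$intervals
  site_means_of <- function(s) {
    out <- rep(NA_real_, nrow(s))
    for (ch in unique(s$chrom)) {
      i <- which(s$chrom == ch)
      d <- iv[iv$chrom == ch, , drop = FALSE]
      if (nrow(d) == 0) next
      out[i] <- .window_means_chrom(s$pos[i] - flank, s$pos[i] + flank,
                                    d$start, d$end, d$value)
    }
    out
  }
  m <- site_means_of(sites)
  n_skipped <- sum(is.na(m))
  m <- m[!is.na(m)]
  .assert(length(m) > 0, "no site window intersects the timing track")
  base <- if (baseline == "shuffle") {
    bm <- site_means_of(shuffle_sites(sites, genome, seed = seed))
    bm[!is.na(bm)]
  } else {
    unit <- stats::median(iv$end - iv$start)
    rep(iv$value, times = pmax(1L, as.integer(round((iv$end - iv$start) / unit))))
  }
  w <- .wilcox_p(m, base, alternative)
  structure(list(site_means = m, n_skipped = n_skipped,
                 baseline_values = base, statistic = w$statistic,
                 p_value = w$p.value, flank = flank, baseline = baseline,
                 early_fraction = mean(m > 0),
                 baseline_early_fraction = mean(base > 0)),
            class = "timing_profile")
}

#' @export
print.timing_profile <- function(x, ...) {
  cat(sprintf("<timing_profile> mean log2(early/late) at sites: %.3f (baseline %.3f), p = %.3g\n",
              mean(x$site_means), mean(x$baseline_values), x$p_value))
  invisible(x)
}

#' Kernel density of distances from sites to anchor points
#'
#' Computes signed nearest distances from each site to anchor points (TSSs or
#' CpGs) and from matched shuffled sites, clips them to `+/- clip` for
#' display, and returns Gaussian kernel density curves on a common grid.
#' "Steepness" of the site curve around 0 is operationalized as a one-sided
#' Wilcoxon test that absolute site distances are smaller than absolute
#' random distances.
#'
#' @param sites Sites tibble.
#' @param anchors Point [feature_track()] (e.g. TSSs).
#' @param genome A [genome_def()].
#' @param bandwidth Kernel bandwidth in bp; default `stats::bw.nrd0` of the
#'   pooled clipped distances.
#' @param clip Display clip in bp (default 1e6).
#' @param grid_n Number of grid points (default 512).
#' @param seed Seed for the shuffle.
#' @return A `distance_density` list: `site_distances`, `random_distances`,
#'   `density_sites`, `density_random` (tibbles x/y), `p_value`, `bandwidth`.
#' @export
distance_density <- function(sites, anchors, genome, bandwidth = NULL,
                             clip = 1e6, grid_n = 512, seed = 1L) {
  .assert(nrow(.track_intervals(anchors)) > 0, "anchor track is empty")
  ds <- nearest_feature_distance(sites, anchors, genome)
  dr <- nearest_feature_distance(shuffle_sites(sites, genome, seed = seed),
                                 anchors, genome)
  ds <- ds[!is.na(ds)]
  dr <- dr[!is.na(dr)]
  .assert(length(ds) > 0, "no site has an anchor on its chromosome")
  dsc <- pmax(pmin(ds, clip), -clip)
  drc <- pmax(pmin(dr, clip), -clip)
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(c(dsc, drc))
  dens <- function(x) {
    d <- stats::density(x, bw = bandwidth, from = -clip, to = clip, n = grid_n)
    tibble::tibble(x = d$x, y = d$y)
  }
  w <- .wilcox_p(abs(ds), abs(dr), "less")
  structure(list(site_distances = ds, random_distances = dr,
                 density_sites = dens(dsc), density_random = dens(drc),
                 statistic = w$statistic, p_value = w$p.value,
                 bandwidth = bandwidth, clip = clip),
            class = "distance_density")
}

#' Assign genes to sites and compare their expression to random genes
#'
#' Each site is assigned all genes whose interval contains it; a site inside
#' no gene gets its single nearest gene (distance to the gene boundary, ties
#' to the lower coordinate). The deduplicated gene set's FPKM values are
#' compared with an equally sized uniform random draw of genes from the
#' expression table using Welch's two-sample t-test (one-sided "greater" by
#' default). Assigned genes missing from the table are dropped and counted.
#'
#' @param sites Sites tibble.
#' @param genes [feature_track()] of gene intervals whose `name` column
#'   carries gene ids.
#' @param fpkm Tibble/data.frame with columns `gene_id`, `fpkm`.
#' @param genome A [genome_def()].
#' @param seed Seed for the random gene draw.
#' @param alternative Test direction (default `"greater"`).
#' @return A list with `gene_ids` (assigned), `n_missing_fpkm`,
#'   `site_fpkm`, `random_fpkm`, `mean_fpkm`, `mean_random_fpkm`, `p_value`.
#' @export
gene_assignment_and_expression <- function(sites, genes, fpkm, genome,
                                           seed = 1L,
                                           alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  gv <- .track_intervals(genes)
  .assert(nrow(gv) > 0, "gene track is empty")
  .assert(!is.null(gv$name), "gene track needs gene ids in its name column")
  .assert(all(c("gene_id", "fpkm") %in% names(fpkm)),
          "fpkm table needs columns gene_id, fpkm")
  ids <- assign_genes_to_sites(sites, genes)
  have <- ids %in% fpkm$gene_id
  n_missing <- sum(!have)
  ids <- ids[have]
  .assert(length(ids) > 0, "no assigned gene has an FPKM value")
  x <- fpkm$fpkm[match(ids, fpkm$gene_id)]
  y <- with_seed(seed, {
    k <- sample.int(nrow(fpkm), length(ids),
                    replace = length(ids) > nrow(fpkm))
    fpkm$fpkm[k]
  })
  tt <- stats::t.test(x, y, alternative = alternative)
  list(gene_ids = ids, n_missing_fpkm = n_missing, site_fpkm = x,
       random_fpkm = y, mean_fpkm = mean(x), mean_random_fpkm = mean(y),
       statistic = unname(tt$statistic), p_value = tt$p.value)
}

#' Genes overlapping each site, or the nearest gene
#'
#' @inheritParams gene_assignment_and_expression
#' @return Character vector of unique gene ids, in order of first assignment.
#' @export
assign_genes_to_sites <- function(sites, genes) {
  gv <- .track_intervals(genes)
  ids <- character(0)
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    d <- gv[gv$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) next # no gene on this chromosome: sites unassigned
    for (pk in p) {
      ov <- d$name[d$start <= pk & d$end > pk]
      if (length(ov) == 0) {
        dist <- ifelse(pk < d$start, d$start - pk, pk - d$end + 1)
        o <- order(dist, d$start)
        ov <- d$name[o[1]]
      }
      ids <- c(ids, ov)
    }
  }
  unique(ids)
}
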