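#' Configuration for the synthetic 4C study generator
#'
#' The generator emulates the data a sonication-based 4C experiment produces,
#' at the abstraction the pipeline consumes: a small multi-chromosome genome,
#' a planted interactome (hotspot regions of elevated interaction frequency
#' plus uniform background sites), junction-bearing read pairs whose two
#' 20-bp end tags place one tag in the bait and the other near a true site,
#' and feature tracks whose co-localization with true sites is controlled.
#' Everything is deterministic for a fixed config and seed, and a truth table
#' records every planted object.
#'
#' @param genome A [genome_def()]; default three 10 Mb chromosomes.
#' @param bait A [bait_region()]; default a 600-bp bait mid-chr1.
#' @param n_hotspots,hotspot_width,sites_per_hotspot Hotspot regions planted
#'   (default 5 regions of 50 kb with 20 sites each). `n_hotspots = 0` gives
#'   the pure-background null configuration.
#' @param n_background_sites Sites placed uniformly genome-wide (default
#'   1000).
#' @param reads_per_site_mean,reads_per_site_min Read pairs per true site:
#'   shifted geometric with this mean and minimum (defaults 3 and 1).
#' @param read_length,tag_length Read and extracted-tag lengths in bp
#'   (defaults 90 and 20).
#' @param noise_fraction Fraction of all read pairs that are non-junction
#'   noise (both tags outside the bait, or both inside; default 0.1).
#' @param duplicate_rate Probability that a pair gets one exact PCR duplicate
#'   (default 0.05).
#' @param mapq_degraded_fraction Fraction of pairs with one tag's MAPQ forced
#'   to <= 20 so quality filtering is exercised (default 0.05).
#' @param jitter Maximum absolute tag-position offset from its true site
#'   (uniform in `+/- jitter`; default 50 bp so merged clusters stay within
#'   the 100-bp rule).
#' @param min_site_gap Minimum spacing between planted sites (default 250 bp;
#'   must exceed `2*jitter + merge window` so distinct sites can never merge).
#' @param bait_exclusion Minimum distance of planted sites from the bait on
#'   the bait chromosome (default 10300 bp, keeping all sites distal).
#' @param edge_margin Keep-out zone at chromosome ends (default 1000 bp).
#' @param track_enrichment Odds multiplier for placing "active" track
#'   features near true sites (default 10; 1 gives the null track).
#' @param enrichment_flank Near-site window for feature placement (default
#'   5e5, matching the +/- 0.5 Mb counting flank).
#' @param n_features_per_track Features per peak track (default 1000).
#' @param peak_width Range of peak widths in bp (default 200-1000).
#' @param tf_flank Near-site window for TF ChIP tag placement (default 1 kb).
#' @param n_tf_tags,n_input_tags ChIP and input library sizes (default 5e4).
#' @param timing_segment_length Range of replication-timing segment lengths
#'   (default 150-250 kb).
#' @param timing_shift Mean log2(early/late) of segments near true sites
#'   (default 1; 0 gives the null track).
#' @param timing_sd Segment value standard deviation (default 0.4).
#' @param timing_flank Near-site window for timing elevation (default 50 kb).
#' @param n_genes,gene_length Gene count and length range (defaults 300 and
#'   5-50 kb).
#' @param cpg_per_mb CpG point density (default 30 per Mb; 0 gives an empty
#'   track).
#' @param fpkm_meanlog,fpkm_sdlog Lognormal FPKM parameters, named
#'   `interacting` and `background` (defaults meanlog log(50) vs log(5),
#'   sdlog 1; equal values give the null expression table).
#' @param seed Master seed; stage seeds are derived from it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(genome = genome_def(paste0("chr", 1:3), rep(1e7, 3)),
                       bait = bait_region("chr1", 5e6, 5e6 + 600),
                       n_hotspots = 5, hotspot_width = 5e4,
                       sites_per_hotspot = 20, n_background_sites = 1000,
                       reads_per_site_mean = 3, reads_per_site_min = 1,
                       read_length = 90, tag_length = 20,
                       noise_fraction = 0.1, duplicate_rate = 0.05,
                       mapq_degraded_fraction = 0.05, jitter = 50,
                       min_site_gap = 250, bait_exclusion = 10300,
                       edge_margin = 1000, track_enrichment = 10,
                       enrichment_flank = 5e5, n_features_per_track = 1000,
                       peak_width = c(200, 1000), tf_flank = 1000,
                       n_tf_tags = 5e4, n_input_tags = 5e4,
                       timing_segment_length = c(15e4, 25e4),
                       timing_shift = 1, timing_sd = 0.4,
                       timing_flank = 5e4, n_genes = 300,
                       gene_length = c(5e3, 5e4), cpg_per_mb = 30,
                       fpkm_meanlog = c(interacting = log(50),
                                        background = log(5)),
                       fpkm_sdlog = c(interacting = 1, background = 1),
                       seed = 1L) {
  .check_genome(genome)
  .assert(inherits(bait, "bait_region"), "bait must be a bait_region")
  .check_chroms(bait$chrom, genome, "bait")
  for (f in c(noise_fraction, duplicate_rate, mapq_degraded_fraction)) {
    .assert(f >= 0 && f <= 1, "fractions must be in [0, 1]")
  }
  .assert(reads_per_site_min >= 1 &&
            reads_per_site_mean >= reads_per_site_min,
          "reads_per_site_mean must be >= reads_per_site_min >= 1")
  .assert(n_hotspots == 0 || hotspot_width < min(genome$length) / 2,
          "hotspot_width must be small relative to chromosome length")
  .assert(track_enrichment > 0, "track_enrichment must be > 0")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# greedy placement of n positions on [margin, L - margin) that keep >= gap
# from each other and from `existing`, and avoid `forbid` = c(lo, hi) zones
.place_spaced <- function(n, L, gap, margin, existing = numeric(0),
                          forbid = NULL) {
  if (n == 0) return(numeric(0))
  ex <- sort(existing)
  kept <- numeric(0)
  for (iter in 1:100) {
    m <- max(2L * (n - length(kept)), 100L)
    cand <- floor(stats::runif(m, margin, L - margin))
    if (!is.null(forbid)) {
      for (fz in forbid) cand <- cand[cand < fz[1] | cand >= fz[2]]
    }
    allk <- sort(c(ex, kept))
    if (length(allk)) {
      i <- findInterval(cand, allk)
      dl <- ifelse(i >= 1, cand - allk[pmax(i, 1)], Inf)
      dr <- ifelse(i < length(allk), allk[pmin(i + 1, length(allk))] - cand, Inf)
      cand <- cand[pmin(dl, dr) >= gap]
    }
    cand <- sort(unique(cand))
    if (length(cand)) {
      keep <- rep(FALSE, length(cand))
      last <- -Inf
      for (k in seq_along(cand)) {
        if (cand[k] - last >= gap) {
          keep[k] <- TRUE
          last <- cand[k]
        }
      }
      cand <- cand[keep]
      need <- n - length(kept)
      # random subset, not head(): keeps the marginal distribution uniform
      take <- if (length(cand) > need) sort(sample(cand, need)) else cand
      kept <- c(kept, take)
    }
    if (length(kept) >= n) return(sort(kept))
  }
  stop("could not place ", n, " sites with the requested spacing", call. = FALSE)
}

#' Simulate the synthetic genome and its annotation
#'
#' Generates gene intervals (each with a TSS point at its start) and CpG
#' points at the configured densities and, optionally, a random nucleotide
#' sequence per chromosome (needed only for the FASTQ/alignment path).
#' Deterministic per seed: the same config yields byte-identical output.
#'
#' @param config A [sim_config()].
#' @param sequence Also generate random chromosome sequences?
#' @param seed Stage seed (default derived from the config seed).
#' @return A list with `genome`, `genes`, `tss`, `cpg` ([feature_track()]s)
#'   and `seqs` (`Biostrings::DNAStringSet` or `NULL`).
#' @export
simulate_genome <- function(config, sequence = FALSE,
                            seed = config$seed + 1L) {
  gn <- config$genome
  len <- .glen(gn)
  total <- sum(gn$length)
  .assert(config$n_genes * max(config$gene_length) < total,
          "requested gene content exceeds genome size")
  with_seed(seed, {
    chrom <- sample(gn$chrom, config$n_genes, replace = TRUE,
                    prob = gn$length)
    glen <- floor(stats::runif(config$n_genes, config$gene_length[1],
                               config$gene_length[2]))
    start <- floor(stats::runif(config$n_genes, 0, len[chrom] - glen))
    o <- order(chrom, start)
    genes <- gintervals(chrom[o], start[o], start[o] + glen[o],
                        name = sprintf("gene%04d", seq_len(config$n_genes)))
    tss <- point_track("TSS", genes$chrom, genes$start)
    n_cpg <- round(config$cpg_per_mb * total / 1e6)
    cpg <- if (n_cpg > 0) {
      cchrom <- sample(gn$chrom, n_cpg, replace = TRUE, prob = gn$length)
      point_track("CpG", cchrom, floor(stats::runif(n_cpg, 0, len[cchrom])))
    } else {
      point_track("CpG", character(0), numeric(0))
    }
    seqs <- NULL
    if (sequence) {
      seqs <- Biostrings::DNAStringSet(vapply(gn$chrom, function(ch) {
        paste(sample(c("A", "C", "G", "T"), len[[ch]], replace = TRUE),
              collapse = "")
      }, ""))
      names(seqs) <- gn$chrom
    }
    list(genome = gn, genes = feature_track("genes", genes, kind = "peak"),
         tss = tss, cpg = cpg, seqs = seqs)
  })
}

#' Plant the true interactome
#'
#' Places `n_hotspots` non-overlapping hotspot regions, each holding
#' `sites_per_hotspot` sites, plus `n_background_sites` uniform background
#' sites. All sites keep `min_site_gap` spacing (so tag jitter can never
#' bridge two sites across the merge window), stay `bait_exclusion` bp away
#' from the bait on its chromosome (all sites are distal by construction) and
#' `edge_margin` bp from chromosome ends.
#'
#' @param config A [sim_config()].
#' @param seed Stage seed.
#' @return A `truth_table` list: `sites` (tibble with `site_id`, `chrom`,
#'   `pos`, `hotspot`), `hotspots` (interval tibble) and `bait`.
#' @export
simulate_interactome <- function(config, seed = config$seed + 2L) {
  gn <- config$genome
  len <- .glen(gn)
  bait <- config$bait
  gap <- config$min_site_gap
  margin <- config$edge_margin
  bait_zone <- c(bait$start - config$bait_exclusion,
                 bait$end + config$bait_exclusion)
  with_seed(seed, {
    hs <- tibble::tibble(chrom = character(), start = numeric(),
                         end = numeric())
    if (config$n_hotspots > 0) {
      w <- config$hotspot_width
      for (h in seq_len(config$n_hotspots)) {
        placed <- FALSE
        for (try in 1:1000) {
          ch <- sample(gn$chrom, 1, prob = gn$length)
          s <- floor(stats::runif(1, margin, len[[ch]] - w - margin))
          if (ch == bait$chrom &&
              s < bait_zone[2] + w && s + w > bait_zone[1] - w) next
          same <- hs[hs$chrom == ch, , drop = FALSE]
          if (nrow(same) && any(s < same$end + gap & s + w > same$start - gap)) next
          hs <- rbind(hs, tibble::tibble(chrom = ch, start = s, end = s + w))
          placed <- TRUE
          break
        }
        .assert(placed, "could not place non-overlapping hotspots")
      }
      hs <- .sort_intervals(hs)
      hs$hotspot_id <- seq_len(nrow(hs))
    } else {
      hs$hotspot_id <- integer(0)
    }
    sites <- tibble::tibble(chrom = character(), pos = numeric(),
                            hotspot = integer())
    for (h in seq_len(nrow(hs))) {
      k <- config$sites_per_hotspot
      w <- hs$end[h] - hs$start[h]
      u <- sort(stats::runif(k, 0, w - (k - 1) * gap))
      pos <- hs$start[h] + floor(u) + (seq_len(k) - 1) * gap
      sites <- rbind(sites, tibble::tibble(chrom = hs$chrom[h], pos = pos,
                                           hotspot = hs$hotspot_id[h]))
    }
    n_bg <- config$n_background_sites
    counts <- stats::rmultinom(1, n_bg, gn$length)[, 1]
    for (i in seq_len(nrow(gn))) {
      ch <- gn$chrom[i]
      if (counts[i] == 0) next
      forbid <- if (ch == bait$chrom) list(bait_zone) else NULL
      p <- .place_spaced(counts[i], len[[ch]], gap, margin,
                         existing = sites$pos[sites$chrom == ch],
                         forbid = forbid)
      sites <- rbind(sites, tibble::tibble(chrom = ch, pos = p,
                                           hotspot = NA_integer_))
    }
    sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
    sites$site_id <- sprintf("site%05d", seq_len(nrow(sites)))
    structure(list(sites = sites[, c("site_id", "chrom", "pos", "hotspot")],
                   hotspots = hs, bait = bait),
              class = "truth_table")
  })
}

#' @export
print.truth_table <- function(x, ...) {
  cat(sprintf("<truth_table> %d true sites (%d in %d hotspots), bait %s:%d-%d\n",
              nrow(x$sites), sum(!is.na(x$sites$hotspot)), nrow(x$hotspots),
              x$bait$chrom, x$bait$start, x$bait$end))
  invisible(x)
}

#' Simulate junction-bearing read pairs from the planted interactome
#'
#' For each true site, draws a shifted-geometric number of read pairs whose
#' end tags place one tag uniformly inside the bait and the other within
#' `+/- jitter` of the site. Adds non-junction noise pairs (`noise_fraction`
#' of the final pool: both tags outside the bait, or both inside), appends
#' exact PCR duplicates at `duplicate_rate`, and degrades one tag's MAPQ to
#' <= 20 for `mapq_degraded_fraction` of pairs (duplicates inherit their
#' original's quality). A pre-aligned tag-pair table is always produced;
#' FASTQ records are produced when `annotation` carries sequences.
#'
#' @param truth A `truth_table` from [simulate_interactome()].
#' @param config A [sim_config()].
#' @param annotation Optional output of [simulate_genome()]; needed only for
#'   FASTQ output.
#' @param seed Stage seed. Re-running with a different seed resamples a new
#'   replicate library from the same truth.
#' @return A list with `pairs` (tag-pair tibble, see [tag_pairs()]), `reads`
#'   (per-read truth labels: `read_id`, `label`, `site_id`, `duplicate_of`,
#'   `degraded`), `site_read_counts` (tibble `site_id`, `n_read_pairs`,
#'   `n_clean_pairs`), and `fastq1`/`fastq2` (`DNAStringSet` or `NULL`).
#' @export
simulate_read_pairs <- function(truth, config, annotation = NULL,
                                seed = config$seed + 3L) {
  gn <- config$genome
  len <- .glen(gn)
  bait <- config$bait
  tl <- config$tag_length
  rl <- config$read_length
  sites <- truth$sites
  with_seed(seed, {
    p_geom <- 1 / (config$reads_per_site_mean - config$reads_per_site_min + 1)
    n_reads <- config$reads_per_site_min +
      stats::rgeom(nrow(sites), p_geom)
    site_idx <- rep(seq_len(nrow(sites)), n_reads)
    n_jun <- length(site_idx)
    jit <- floor(stats::runif(n_jun, -config$jitter, config$jitter + 1))
    site_tag <- tibble::tibble(chrom = sites$chrom[site_idx],
                               pos = sites$pos[site_idx] + jit)
    bait_tag_pos <- floor(stats::runif(n_jun, bait$start, bait$end - tl + 1))
    nf <- config$noise_fraction
    n_noise <- if (nf > 0) round(nf / (1 - nf) * n_jun) else 0L
    noise1 <- noise2 <- tibble::tibble(chrom = character(), pos = numeric())
    if (n_noise > 0) {
      self_lig <- stats::runif(n_noise) < 0.1
      draw_outside <- function(m) {
        ch <- sample(gn$chrom, m, replace = TRUE, prob = gn$length)
        pos <- floor(stats::runif(m, 0, len[ch] - rl))
        bad <- ch == bait$chrom & pos >= bait$start - tl & pos < bait$end
        while (any(bad)) {
          ch[bad] <- sample(gn$chrom, sum(bad), replace = TRUE,
                            prob = gn$length)
          pos[bad] <- floor(stats::runif(sum(bad), 0, len[ch[bad]] - rl))
          bad <- ch == bait$chrom & pos >= bait$start - tl & pos < bait$end
        }
        tibble::tibble(chrom = ch, pos = pos)
      }
      n_out <- sum(!self_lig)
      o1 <- draw_outside(n_out)
      o2 <- draw_outside(n_out)
      b1 <- tibble::tibble(
        chrom = rep(bait$chrom, sum(self_lig)),
        pos = floor(stats::runif(sum(self_lig), bait$start, bait$end - tl + 1)))
      b2 <- tibble::tibble(
        chrom = rep(bait$chrom, sum(self_lig)),
        pos = floor(stats::runif(sum(self_lig), bait$start, bait$end - tl + 1)))
      noise1 <- rbind(o1, b1)
      noise2 <- rbind(o2, b2)
    }
    n_pairs <- n_jun + n_noise
    end1 <- rbind(tibble::tibble(chrom = bait$chrom, pos = bait_tag_pos),
                  noise1)
    end2 <- rbind(site_tag, noise2)
    swap <- stats::runif(n_pairs) < 0.5
    tmp <- end1[swap, ]
    end1[swap, ] <- end2[swap, ]
    end2[swap, ] <- tmp
    read_id <- sprintf("read%07d", seq_len(n_pairs))
    label <- c(rep("junction", n_jun), rep("noise", n_noise))
    site_id <- c(sites$site_id[site_idx], rep(NA_character_, n_noise))
    mapq1 <- rep(60, n_pairs)
    mapq2 <- rep(60, n_pairs)
    degraded <- stats::runif(n_pairs) < config$mapq_degraded_fraction
    which_end <- stats::runif(n_pairs) < 0.5
    low_q <- floor(stats::runif(n_pairs, 0, 21))
    mapq1[degraded & which_end] <- low_q[degraded & which_end]
    mapq2[degraded & !which_end] <- low_q[degraded & !which_end]
    dup <- stats::runif(n_pairs) < config$duplicate_rate
    idx <- c(seq_len(n_pairs), which(dup))
    is_dup <- c(rep(FALSE, n_pairs), rep(TRUE, sum(dup)))
    dup_ids <- if (any(dup)) paste0(read_id[dup], "_dup") else character(0)
    pairs <- tag_pairs(
      read_id = c(read_id, dup_ids),
      chrom1 = end1$chrom[idx], pos1 = end1$pos[idx], mapq1 = mapq1[idx],
      chrom2 = end2$chrom[idx], pos2 = end2$pos[idx], mapq2 = mapq2[idx]
    )
    reads <- tibble::tibble(
      read_id = pairs$read_id,
      label = label[idx],
      site_id = site_id[idx],
      duplicate_of = ifelse(is_dup, read_id[idx], NA_character_),
      degraded = degraded[idx]
    )
    jun <- reads$label == "junction"
    tab_all <- table(factor(reads$site_id[jun], levels = sites$site_id))
    tab_clean <- table(factor(reads$site_id[jun & !reads$degraded],
                              levels = sites$site_id))
    src <- tibble::tibble(site_id = sites$site_id,
                          n_read_pairs = as.integer(tab_all),
                          n_clean_pairs = as.integer(tab_clean))
    fastq1 <- fastq2 <- NULL
    if (!is.null(annotation) && !is.null(annotation$seqs)) {
      seqs <- as.character(annotation$seqs)
      mk <- function(e) {
        Biostrings::DNAStringSet(substr(seqs[e$chrom[idx]], e$pos[idx] + 1,
                                        e$pos[idx] + rl))
      }
      fastq1 <- mk(end1)
      fastq2 <- mk(end2)
      names(fastq1) <- names(fastq2) <- pairs$read_id
    }
    list(pairs = pairs, reads = reads, site_read_counts = src,
         fastq1 = fastq1, fastq2 = fastq2)
  })
}

# distance from each query position to the nearest true site (same chrom)
.near_site_dist <- function(chrom, pos, site_chrom, site_pos) {
  out <- rep(Inf, length(pos))
  for (ch in unique(chrom)) {
    sp <- sort(site_pos[site_chrom == ch])
    if (length(sp) == 0) next
    i <- which(chrom == ch)
    k <- findInterval(pos[i], sp)
    dl <- ifelse(k >= 1, pos[i] - sp[pmax(k, 1)], Inf)
    dr <- ifelse(k < length(sp), sp[pmin(k + 1, length(sp))] - pos[i], Inf)
    out[i] <- pmin(dl, dr)
  }
  out
}

#' Simulate epigenomic feature tracks around the planted interactome
#'
#' Produces the track families the integrative analyses consume. "Active"
#' peak tracks (H3K4me1/H3K27ac/H3K4me3/H3K9ac-like, DHS, 5-hmC) place
#' features with odds multiplied by `track_enrichment` within
#' `enrichment_flank` of true sites; "repressive" tracks (H3K27me3/H3K9me3)
#' are site-independent. Pluripotency TF ChIP tag tracks are enriched within
#' `tf_flank`, alongside a uniform input tag track and one site-independent
#' TF. Replication-timing segments tile the genome; segments within
#' `timing_flank` of a true site get mean log2 ratio `timing_shift`, others
#' 0. Genes assigned to true sites (overlap-or-nearest) draw FPKM from the
#' `interacting` lognormal, others from `background`.
#'
#' @param truth A `truth_table`.
#' @param config A [sim_config()].
#' @param annotation Output of [simulate_genome()] (for genes).
#' @param seed Stage seed.
#' @return A list with `tracks` (named list of [feature_track()]s, including
#'   `input` tags), `fpkm` (tibble `gene_id`, `fpkm`) and
#'   `interacting_gene_ids`.
#' @export
simulate_feature_tracks <- function(truth, config, annotation,
                                    seed = config$seed + 4L) {
  gn <- config$genome
  len <- .glen(gn)
  sites <- truth$sites
  e <- config$track_enrichment
  with_seed(seed, {
    draw_positions <- function(n, flank, odds) {
      out_ch <- character(0)
      out_pos <- numeric(0)
      while (length(out_pos) < n) {
        m <- max(2L * (n - length(out_pos)), 1000L)
        ch <- sample(gn$chrom, m, replace = TRUE, prob = gn$length)
        pos <- floor(stats::runif(m, 0, len[ch]))
        near <- .near_site_dist(ch, pos, sites$chrom, sites$pos) <= flank
        p_acc <- if (odds >= 1) ifelse(near, 1, 1 / odds) else
          ifelse(near, odds, 1)
        acc <- stats::runif(m) < p_acc
        out_ch <- c(out_ch, ch[acc])
        out_pos <- c(out_pos, pos[acc])
      }
      tibble::tibble(chrom = out_ch[seq_len(n)], pos = out_pos[seq_len(n)])
    }
    peak_track <- function(name, odds) {
      p <- draw_positions(config$n_features_per_track,
                          config$enrichment_flank, odds)
      w <- floor(stats::runif(nrow(p), config$peak_width[1],
                              config$peak_width[2]))
      feature_track(name, gintervals(p$chrom, pmin(p$pos, len[p$chrom] - w - 1),
                                     pmin(p$pos + w, len[p$chrom])),
                    kind = "peak")
    }
    tag_track <- function(name, n, odds) {
      p <- draw_positions(n, config$tf_flank, odds)
      point_track(name, p$chrom, p$pos)
    }
    tracks <- list()
    for (nm in c("H3K4me1", "H3K27ac", "H3K4me3", "H3K9ac", "DHS", "5hmC")) {
      tracks[[nm]] <- peak_track(nm, e)
    }
    for (nm in c("H3K27me3", "H3K9me3")) {
      tracks[[nm]] <- peak_track(nm, 1)
    }
    for (nm in c("Oct4", "Klf4", "Esrrb", "Tcfcp2l1", "Zfx")) {
      tracks[[nm]] <- tag_track(nm, config$n_tf_tags, e)
    }
    tracks[["Suz12"]] <- tag_track("Suz12", config$n_tf_tags, 1)
    tracks[["input"]] <- tag_track("input", config$n_input_tags, 1)
    seg <- lapply(gn$chrom, function(ch) {
      L <- len[[ch]]
      lens <- numeric(0)
      while (sum(lens) < L) {
        lens <- c(lens, floor(stats::runif(32, config$timing_segment_length[1],
                                           config$timing_segment_length[2])))
      }
      en <- pmin(cumsum(lens), L)
      en <- en[seq_len(which(en == L)[1])]
      st <- c(0, en[-length(en)])
      sp <- sort(sites$pos[sites$chrom == ch])
      near <- if (length(sp)) {
        k1 <- .n_leq(en - 1 + config$timing_flank, sp)
        k0 <- .n_less(st - config$timing_flank, sp)
        k1 > k0
      } else {
        rep(FALSE, length(st))
      }
      mu <- ifelse(near, config$timing_shift, 0)
      gintervals(rep(ch, length(st)), st, en,
                 value = stats::rnorm(length(st), mu, config$timing_sd))
    })
    tracks[["timing"]] <- feature_track("timing", do.call(rbind, seg),
                                        kind = "valued_segment")
    genes <- annotation$genes
    interacting <- assign_genes_to_sites(sites, genes)
    gid <- genes$intervals$name
    is_int <- gid %in% interacting
    fpkm <- tibble::tibble(
      gene_id = gid,
      fpkm = stats::rlnorm(
        length(gid),
        ifelse(is_int, config$fpkm_meanlog[["interacting"]],
               config$fpkm_meanlog[["background"]]),
        ifelse(is_int, config$fpkm_sdlog[["interacting"]],
               config$fpkm_sdlog[["background"]])
      )
    )
    list(tracks = tracks, fpkm = fpkm, interacting_gene_ids = interacting)
  })
}

#' Run the full synthetic study generator
#'
#' Orchestrates [simulate_genome()], [simulate_interactome()],
#' [simulate_read_pairs()] and [simulate_feature_tracks()] with stage seeds
#' derived from the config seed. Every artifact is deterministic for a fixed
#' config.
#'
#' @param config A [sim_config()].
#' @param sequence Generate chromosome sequences (and FASTQ reads)?
#' @param reads Generate the read-pair library?
#' @param tracks Generate feature tracks and the expression table?
#' @return A `sim_study` list: `config`, `annotation`, `truth` (with
#'   per-site read counts merged in), `reads`, `tracks`.
#' @export
simulate_4c <- function(config = sim_config(), sequence = FALSE,
                        reads = TRUE, tracks = TRUE) {
  ann <- simulate_genome(config, sequence = sequence)
  truth <- simulate_interactome(config)
  rd <- NULL
  if (reads) {
    rd <- simulate_read_pairs(truth, config, ann)
    truth$sites <- merge(truth$sites, rd$site_read_counts, by = "site_id",
                         sort = FALSE)
    truth$sites <- tibble::as_tibble(truth$sites[order(truth$sites$chrom,
                                                       truth$sites$pos), ])
  }
  tr <- NULL
  if (tracks) {
    tr <- simulate_feature_tracks(truth, config, ann)
    truth$interacting_gene_ids <- tr$interacting_gene_ids
  }
  structure(list(config = config, annotation = ann, truth = truth,
                 reads = rd, tracks = tr),
            class = "sim_study")
}

#' Write a simulated study to disk
#'
#' Writes everything the command-line pipeline consumes: `chrom.sizes`,
#' `genome.fa` (when sequences were simulated), paired FASTQ, the pre-aligned
#' tag-pair table, the truth table (JSON), all feature tracks (BED/bedGraph),
#' the FPKM table and the config (JSON).
#'
#' @param sim A `sim_study` from [simulate_4c()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(dir, ...)
  write_chrom_sizes(sim$config$genome, fp("chrom.sizes"))
  if (!is.null(sim$annotation$seqs)) {
    Biostrings::writeXStringSet(sim$annotation$seqs, fp("genome.fa"))
  }
  if (!is.null(sim$reads)) {
    .write_tsv(sim$reads$pairs, fp("tag_pairs.tsv"))
    .write_tsv(sim$reads$reads, fp("read_truth.tsv"))
    if (!is.null(sim$reads$fastq1)) {
      .write_fastq(sim$reads$fastq1, fp("reads_1.fastq"), "/1")
      .write_fastq(sim$reads$fastq2, fp("reads_2.fastq"), "/2")
    }
  }
  truth <- list(
    sites = as.data.frame(sim$truth$sites),
    hotspots = as.data.frame(sim$truth$hotspots),
    bait = unclass(sim$truth$bait),
    interacting_gene_ids = sim$truth$interacting_gene_ids
  )
  jsonlite::write_json(truth, fp("truth.json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  if (!is.null(sim$tracks)) {
    for (nm in names(sim$tracks$tracks)) {
      tr <- sim$tracks$tracks[[nm]]
      ext <- if (tr$kind == "valued_segment") ".bedgraph" else ".bed"
      write_bed(tr, fp(paste0(nm, ext)))
    }
    .write_tsv(sim$tracks$fpkm, fp("fpkm.tsv"))
  }
  cfg <- sim$config
  cfg$genome <- as.data.frame(cfg$genome)
  cfg$bait <- unclass(cfg$bait)
  jsonlite::write_json(unclass(cfg), fp("config.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

.write_fastq <- function(seqs, path, suffix) {
  q <- Biostrings::BStringSet(vapply(Biostrings::width(seqs),
                                     function(w) strrep("I", w), ""))
  x <- seqs
  names(x) <- paste0(names(seqs), suffix)
  names(q) <- names(x)
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}
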