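#' Construct a table of distal interacting sites
#'
#' A site is a 1-bp representative position of a merged cluster of junction
#' end tags, with its supporting read count.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer-valued 0-based positions.
#' @param read_count Supporting read-pair counts (default 2, the minimum that
#'   survives singleton filtering).
#' @return A tibble with columns `chrom`, `pos`, `read_count`.
#' @export
genomic_sites <- function(chrom, pos, read_count = 2L) {
  n <- max(length(chrom), length(pos))
  .assert(all(c(length(chrom), length(pos)) %in% c(1L, n)) || n == 0,
          "chrom and pos must have equal length (or length 1)")
  tibble::tibble(chrom = as.character(rep_len(chrom, n)),
                 pos = as.numeric(rep_len(pos, n)),
                 read_count = as.integer(rep_len(read_count, n)))
}

.check_sites <- function(sites, genome = NULL, what = "sites") {
  .assert(is.data.frame(sites) && all(c("chrom", "pos") %in% names(sites)),
          what, " must have columns chrom, pos")
  if (!is.null(genome) && nrow(sites) > 0) {
    .check_chroms(sites$chrom, genome, what)
    len <- .glen(genome)
    .assert(all(sites$pos >= 0 & sites$pos < len[sites$chrom]),
            what, " fall outside their chromosomes")
  }
  invisible(sites)
}

#' Read/write distal sites as BED4
#'
#' Sites are stored as width-1 BED intervals whose name column carries the
#' supporting read count.
#'
#' @param path File path.
#' @return `read_sites_bed`: a sites tibble. `write_sites_bed`: `path`,
#'   invisibly.
#' @export
read_sites_bed <- function(path) {
  tr <- read_bed(path, kind = "point")
  x <- tr$intervals
  rc <- if (!is.null(x$name)) suppressWarnings(as.integer(x$name)) else 2L
  genomic_sites(x$chrom, x$start, ifelse(is.na(rc), 2L, rc))
}

#' @rdname read_sites_bed
#' @param sites A sites tibble (see [genomic_sites()]).
#' @export
write_sites_bed <- function(sites, path) {
  .check_sites(sites)
  rc <- if ("read_count" %in% names(sites)) sites$read_count else 2L
  tr <- feature_track("sites",
                      gintervals(sites$chrom, sites$pos, sites$pos + 1,
                                 name = as.character(rep_len(rc, nrow(sites)))),
                      kind = "point")
  write_bed(tr, path)
}

# count, per window [lo, hi] (closed, given as half-open [lo, hi + 1)), the
# intervals of `iv` overlapping it; windows and intervals on one chromosome
.count_overlaps_chrom <- function(lo, hi, starts, ends) {
  ss <- sort(starts)
  se <- sort(ends)
  # overlap <=> start < hi + 1  and  end > lo
  .n_less(hi + 1, ss) - .n_leq(lo, se)
}

#' Count track features around each anchor site
#'
#' For each anchor, counts the track intervals overlapping the closed window
#' `[pos - flank, pos + flank]`. Windows are truncated at chromosome ends
#' (which cannot change counts, since track intervals lie inside their
#' chromosomes); counts are not rescaled. A feature overlapping several
#' anchors' windows contributes to each of them.
#'
#' @param sites Sites tibble (see [genomic_sites()]).
#' @param track A [feature_track()] of kind `"peak"` or `"point"`.
#' @param flank Half-window in bp (> 0).
#' @param genome Optional [genome_def()] used to validate the anchors.
#' @return Integer vector of counts, one per anchor, in input order.
#' @export
count_features_in_flank <- function(sites, track, flank, genome = NULL) {
  .check_sites(sites, genome)
  .assert(is.numeric(flank) && flank > 0, "flank must be > 0")
  iv <- .track_intervals(track)
  if (inherits(track, "feature_track")) {
    .assert(track$kind %in% c("peak", "point"),
            "count_features_in_flank expects a peak or point track")
  }
  n <- nrow(sites)
  counts <- integer(n)
  if (n == 0 || nrow(iv) == 0) return(counts)
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    d <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) next
    counts[si] <- .count_overlaps_chrom(sites$pos[si] - flank,
                                        sites$pos[si] + flank,
                                        d$start, d$end)
  }
  counts
}

#' Signed distance from each anchor to its nearest track feature
#'
#' Distance is 0 when the anchor lies inside a feature. Otherwise it is the
#' gap to the nearest feature boundary, signed by the anchor's position
#' relative to the feature start: positive when the anchor is downstream
#' (to the right) of the feature, negative when upstream. Equidistant ties
#' break to the lower-coordinate feature. Strand is ignored.
#'
#' Anchors on chromosomes with no features get `NA` (an explicit missing
#' value, never a silent 0); their number is returned in attribute
#' `n_missing`.
#'
#' @inheritParams count_features_in_flank
#' @return Numeric vector of signed distances (bp), `NA` where undefined.
#' @export
nearest_feature_distance <- function(sites, track, genome = NULL) {
  .check_sites(sites, genome)
  iv <- .track_intervals(track)
  n <- nrow(sites)
  out <- rep(NA_real_, n)
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    d <- iv[iv$chrom == ch, , drop = FALSE]
    if (nrow(d) == 0) next
    o <- order(d$start, d$end)
    st <- d$start[o]
    rmax <- cummax(d$end[o]) # max end among features starting at or before
    for (k in si) {
      p <- sites$pos[k]
      i <- .n_leq(p, st) # features with start <= p
      if (i >= 1 && rmax[i] > p) {
        out[k] <- 0
        next
      }
      dl <- if (i >= 1) p - (rmax[i] - 1) else Inf
      dr <- if (i < length(st)) st[i + 1] - p else Inf
      out[k] <- if (dl <= dr) dl else -dr
    }
  }
  attr(out, "n_missing") <- sum(is.na(out))
  out
}

#' Randomly shuffle site positions across the genome
#'
#' The null model used by every enrichment comparison: site positions are
#' redrawn i.i.d. uniformly. The default mode preserves the number of sites
#' per chromosome (conditioning the null on the observed chromosomal
#' distribution, which removes chromosome-size confounding);
#' `mode = "genome_wide"` redraws chromosomes with probability proportional
#' to length. An optional exclusion mask (e.g. assembly gaps) rejects draws
#' overlapping its intervals.
#'
#' @param sites Sites tibble.
#' @param genome A [genome_def()].
#' @param seed Integer seed; required, every call is deterministic.
#' @param mode `"per_chromosome"` (default) or `"genome_wide"`.
#' @param exclude Optional [feature_track()] of regions sites may not land in.
#' @return A sites tibble with the same number of rows (and, in the default
#'   mode, the same per-chromosome counts) as the input.
#' @export
shuffle_sites <- function(sites, genome, seed,
                          mode = c("per_chromosome", "genome_wide"),
                          exclude = NULL) {
  mode <- match.arg(mode)
  .check_genome(genome)
  .check_sites(sites, genome)
  n <- nrow(sites)
  len <- .glen(genome)
  with_seed(seed, {
    chrom <- if (mode == "per_chromosome") {
      sites$chrom
    } else {
      sample(genome$chrom, n, replace = TRUE, prob = genome$length)
    }
    pos <- floor(stats::runif(n, 0, len[chrom]))
    if (!is.null(exclude)) {
      for (iter in 1:1000) {
        bad <- count_features_in_flank(genomic_sites(chrom, pos), exclude, 1) > 0
        if (!any(bad)) break
        pos[bad] <- floor(stats::runif(sum(bad), 0, len[chrom[bad]]))
      }
      .assert(!any(bad), "could not place shuffled sites outside the mask")
    }
    out <- genomic_sites(chrom, pos,
                         if ("read_count" %in% names(sites)) sites$read_count else 2L)
    out
  })
}
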