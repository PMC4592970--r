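#' Count sites in fixed genomic bins
#'
#' Tiles every chromosome with half-open bins of `bin_size` bp (the last bin
#' truncated) and counts the sites whose position falls in each bin. All bins
#' are reported, including empty ones; the counts sum to the number of sites.
#'
#' @param sites Sites tibble.
#' @param genome A [genome_def()].
#' @param bin_size Bin width in bp (default 2e6).
#' @return A `bin_vector` tibble with columns `chrom`, `bin`, `start`, `end`,
#'   `count`; attributes `bin_size` and `genome`.
#' @export
bin_site_counts <- function(sites, genome, bin_size = 2e6) {
  .assert(bin_size > 0, "bin_size must be > 0")
  .check_genome(genome)
  .check_sites(sites, genome)
  out <- lapply(seq_len(nrow(genome)), function(i) {
    L <- genome$length[i]
    nb <- ceiling(L / bin_size)
    bin <- seq_len(nb) - 1
    p <- sites$pos[sites$chrom == genome$chrom[i]]
    cnt <- tabulate(floor(p / bin_size) + 1, nbins = nb)
    tibble::tibble(chrom = genome$chrom[i], bin = bin,
                   start = bin * bin_size, end = pmin(L, (bin + 1) * bin_size),
                   count = cnt)
  })
  out <- do.call(rbind, out)
  attr(out, "bin_size") <- bin_size
  attr(out, "genome") <- genome
  out
}

#' Pearson correlation of binned site counts between replicates
#'
#' Correlates two bin vectors over all aligned bins (zeros included by
#' default; set `nonzero_only = TRUE` to restrict to bins non-empty in either
#' replicate). Returns `NA` with a warning if either vector has zero
#' variance.
#'
#' @param a,b `bin_vector` tibbles from [bin_site_counts()] over the same
#'   genome and bin size.
#' @param nonzero_only Drop bins empty in both replicates?
#' @return A list with `r` (Pearson correlation, `NA` if undefined) and
#'   `data` (tibble of paired bin counts for scatter plots).
#' @export
replicate_correlation <- function(a, b, nonzero_only = FALSE) {
  .assert(identical(attr(a, "bin_size"), attr(b, "bin_size")),
          "bin sizes differ")
  .assert(nrow(a) == nrow(b) && all(a$chrom == b$chrom) && all(a$bin == b$bin),
          "bin vectors are not aligned (different genome or bin size)")
  d <- tibble::tibble(chrom = a$chrom, bin = a$bin,
                      count_a = a$count, count_b = b$count)
  if (nonzero_only) d <- d[d$count_a > 0 | d$count_b > 0, , drop = FALSE]
  r <- if (nrow(d) < 2 || stats::sd(d$count_a) == 0 || stats::sd(d$count_b) == 0) {
    warning("zero variance in a bin vector; correlation undefined")
    NA_real_
  } else {
    stats::cor(d$count_a, d$count_b)
  }
  list(r = r, data = d)
}

#' Relative-distance distribution between two site sets
#'
#' For each query site, its distance to the nearest reference site divided by
#' the distance between the two reference sites flanking it - a value in
#' `[0, 0.5]` that is uniform when the two sets are spatially independent and
#' piles up near 0 when they co-localize. Query sites not flanked on both
#' sides (before the first or after the last reference site on a chromosome,
#' or on chromosomes with fewer than two reference sites) are skipped and
#' counted, except that a query coinciding exactly with a reference site is
#' always 0. Uniformity is assessed with a Kolmogorov-Smirnov test against
#' Uniform(0, 0.5).
#'
#' @param a Query sites tibble.
#' @param b Reference sites tibble.
#' @param bin_width Histogram bin width on `[0, 0.5]` (default 0.01).
#' @return A list with `values`, `n_skipped`, `histogram` (tibble of bin
#'   midpoints and counts) and `ks_p`.
#' @export
relative_distance_distribution <- function(a, b, bin_width = 0.01) {
  .check_sites(a, what = "a")
  .check_sites(b, what = "b")
  .assert(nrow(b) > 0, "reference site set is empty")
  vals <- numeric(0)
  n_skipped <- 0L
  for (ch in unique(a$chrom)) {
    p <- a$pos[a$chrom == ch]
    bp <- sort(b$pos[b$chrom == ch])
    if (length(bp) == 0) {
      n_skipped <- n_skipped + length(p)
      next
    }
    k <- .n_leq(p, bp)
    dl <- ifelse(k >= 1, p - bp[pmax(k, 1)], Inf)
    dr <- ifelse(k < length(bp), bp[pmin(k + 1, length(bp))] - p, Inf)
    v <- rep(NA_real_, length(p))
    v[dl == 0] <- 0 # exact coincidence needs no flanking pair
    flanked <- is.na(v) & is.finite(dl) & is.finite(dr)
    v[flanked] <- pmin(dl, dr)[flanked] / (dl + dr)[flanked]
    n_skipped <- n_skipped + sum(is.na(v))
    vals <- c(vals, v[!is.na(v)])
  }
  .assert(length(vals) > 0,
          "no query site is flanked by reference sites on any shared chromosome")
  nb <- ceiling(0.5 / bin_width)
  idx <- pmin(floor(vals / bin_width) + 1L, nb)
  cnt <- tabulate(idx, nbins = nb)
  ks <- suppressWarnings(stats::ks.test(vals, stats::punif, min = 0, max = 0.5))
  list(values = vals, n_skipped = n_skipped,
       histogram = tibble::tibble(mid = (seq_len(nb) - 0.5) * bin_width,
                                  count = cnt,
                                  density = cnt / (length(vals) * bin_width)),
       ks_p = ks$p.value)
}
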