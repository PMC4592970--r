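#' Parameters for enriched-domain calling
#'
#' Defaults follow the published procedure: site density scored in a 2 Mb
#' window, significance by 100 position permutations per chromosome at
#' FDR <= 0.05, and all sites within +/- 1 Mb of significant sites merged
#' into enriched domains.
#'
#' @param window_length Scoring window length `lw` in bp (default 2e6; window
#'   is `pos +/- lw/2`).
#' @param n_permutations Number of per-chromosome position permutations
#'   (default 100).
#' @param fdr_cutoff FDR threshold for significant sites (default 0.05).
#' @param merge_flank Flank in bp merged around each significant site
#'   (default 1e6).
#' @param seed Integer seed for the permutations.
#' @param z_model `"poisson"` (default): `z = (C - mu)/sqrt(mu)`; or
#'   `"binomial"`: `z = (C - mu)/sqrt(mu (1 - lw/L_W))`. The permutation FDR
#'   is invariant to this (monotone) choice.
#' @return A `domain_params` list.
#' @export
domain_params <- function(window_length = 2e6, n_permutations = 100,
                          fdr_cutoff = 0.05, merge_flank = 1e6, seed = 1L,
                          z_model = c("poisson", "binomial")) {
  z_model <- match.arg(z_model)
  .assert(window_length > 0, "window_length must be > 0")
  .assert(n_permutations >= 1, "n_permutations must be >= 1")
  .assert(fdr_cutoff > 0 && fdr_cutoff < 1, "fdr_cutoff must be in (0,1)")
  .assert(merge_flank >= 0, "merge_flank must be >= 0")
  structure(list(window_length = window_length,
                 n_permutations = as.integer(n_permutations),
                 fdr_cutoff = fdr_cutoff, merge_flank = merge_flank,
                 seed = as.integer(seed), z_model = z_model),
            class = "domain_params")
}

# window counts for sorted positions on one chromosome: number of positions
# within +/- h (closed: boundary sites at exactly h are included)
.window_counts_sorted <- function(sp, h) {
  .n_leq(sp + h, sp) - .n_less(sp - h, sp)
}

.zscores_chrom <- function(pos, L, lw, z_model = "poisson") {
  n <- length(pos)
  mu <- n * lw / L
  o <- order(pos)
  C <- integer(n)
  C[o] <- .window_counts_sorted(pos[o], lw / 2)
  v <- if (z_model == "binomial") {
    .assert(lw < L, "binomial z model requires window_length < chromosome length")
    mu * (1 - lw / L)
  } else {
    mu
  }
  list(C = C, mu = mu, z = (C - mu) / sqrt(v))
}

#' Count interacting sites in a window around each site
#'
#' For each site, the number of sites on the same chromosome (itself
#' included) within `lw/2` bp, i.e. in a window of total length `lw` centred
#' on the site. Windows are truncated at chromosome ends without rescaling.
#'
#' @param sites Sites tibble.
#' @param genome A [genome_def()].
#' @param lw Window length in bp.
#' @return Integer vector of counts `C`, in input order (each >= 1).
#' @export
window_counts <- function(sites, genome, lw) {
  .check_genome(genome)
  .check_sites(sites, genome)
  C <- integer(nrow(sites))
  for (ch in unique(sites$chrom)) {
    i <- which(sites$chrom == ch)
    o <- order(sites$pos[i])
    C[i[o]] <- .window_counts_sorted(sort(sites$pos[i]), lw / 2)
  }
  C
}

#' Score each site's local interaction density as a z-score
#'
#' Under a uniform background, the expected number of sites in a length-`lw`
#' window on chromosome `W` is `mu = N_W lw / L_W`, where `N_W` is the number
#' of sites on that chromosome. Each site's observed window count `C` is
#' standardized to `z = (C - mu)/sqrt(mu)` (Poisson variance; a binomial
#' variant is available, see [domain_params()]).
#'
#' @inheritParams window_counts
#' @param z_model See [domain_params()].
#' @return A `site_scores` tibble: the input sites plus columns `C`, `mu`,
#'   `z`.
#' @export
site_zscores <- function(sites, genome, lw = 2e6,
                         z_model = c("poisson", "binomial")) {
  z_model <- match.arg(z_model)
  .check_genome(genome)
  .check_sites(sites, genome)
  len <- .glen(genome)
  out <- tibble::as_tibble(sites)
  out$C <- NA_integer_
  out$mu <- NA_real_
  out$z <- NA_real_
  for (ch in unique(out$chrom)) {
    i <- which(out$chrom == ch)
    zs <- .zscores_chrom(out$pos[i], len[[ch]], lw, z_model)
    out$C[i] <- zs$C
    out$mu[i] <- zs$mu
    out$z[i] <- zs$z
  }
  attr(out, "lw") <- lw
  attr(out, "z_model") <- z_model
  out
}

#' Permutation-based FDR for site z-scores
#'
#' For each of `n_permutations` rounds, site positions are redrawn uniformly
#' per chromosome (preserving each chromosome's site count) and z-scores are
#' recomputed with the same model, giving a pooled null z distribution. The
#' raw FDR at an observed score `z*` is the mean per-permutation count of
#' null scores `>= z*` divided by the number of observed scores `>= z*`
#' (clipped to `[0, 1]`), then monotonized so that significance is a
#' threshold on z (each site gets the best raw FDR achievable by any
#' threshold at or below its z). Sites with FDR at or below the cutoff are
#' flagged significant. Deterministic for a fixed seed.
#'
#' @param scores A `site_scores` tibble from [site_zscores()].
#' @param genome A [genome_def()].
#' @param params A [domain_params()].
#' @return `scores` with columns `fdr` and `significant` added.
#' @export
permutation_fdr <- function(scores, genome, params = domain_params()) {
  .assert(all(c("chrom", "pos", "z") %in% names(scores)),
          "scores must come from site_zscores()")
  .check_genome(genome)
  lw <- attr(scores, "lw")
  .assert(!is.null(lw), "scores are missing the window-length attribute")
  z_model <- attr(scores, "z_model")
  len <- .glen(genome)
  B <- params$n_permutations
  n_by_chrom <- table(scores$chrom)
  null_z <- with_seed(params$seed, {
    acc <- vector("list", B)
    for (b in seq_len(B)) {
      acc[[b]] <- unlist(lapply(names(n_by_chrom), function(ch) {
        nW <- n_by_chrom[[ch]]
        p <- floor(stats::runif(nW, 0, len[[ch]]))
        .zscores_chrom(p, len[[ch]], lw, z_model)$z
      }), use.names = FALSE)
    }
    unlist(acc, use.names = FALSE)
  })
  sn <- sort(null_z)
  so <- sort(scores$z)
  null_ge <- length(sn) - .n_less(scores$z, sn)
  obs_ge <- length(so) - .n_less(scores$z, so)
  raw <- pmin(1, (null_ge / B) / obs_ge)
  # monotonize: each site gets the best FDR over thresholds <= its z
  q <- numeric(length(raw))
  o <- order(scores$z)
  q[o] <- cummin(raw[o])
  scores$fdr <- q
  scores$significant <- q <= params$fdr_cutoff
  scores
}

#' Merge significant sites into enriched interacting domains
#'
#' Each significant site seeds the interval `pos +/- merge_flank` (truncated
#' to its chromosome); overlapping or book-ended seeds are merged
#' transitively, and every site (significant or not) falling inside a merged
#' interval becomes a member. Output domains never overlap and are invariant
#' to site input order.
#'
#' @param scores Output of [permutation_fdr()].
#' @param genome A [genome_def()].
#' @param params A [domain_params()] (only `merge_flank` is used).
#' @return An `enriched_domains` tibble: `chrom`, `start`, `end`, `n_sites`,
#'   `n_significant`, `peak_z`, `min_fdr`.
#' @export
call_enriched_domains <- function(scores, genome, params = domain_params()) {
  .assert(all(c("chrom", "pos", "z", "fdr", "significant") %in% names(scores)),
          "scores must come from permutation_fdr()")
  .check_genome(genome)
  empty <- tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n_sites = integer(),
                          n_significant = integer(), peak_z = numeric(),
                          min_fdr = numeric())
  sig <- scores[scores$significant, , drop = FALSE]
  if (nrow(sig) == 0) return(empty)
  len <- .glen(genome)
  seeds <- gintervals(sig$chrom,
                      pmax(0, sig$pos - params$merge_flank),
                      pmin(len[sig$chrom], sig$pos + params$merge_flank + 1))
  doms <- merge_overlapping(seeds, bookended = TRUE)
  out <- doms[, c("chrom", "start", "end")]
  out$n_sites <- 0L
  out$n_significant <- 0L
  out$peak_z <- NA_real_
  out$min_fdr <- NA_real_
  for (k in seq_len(nrow(out))) {
    m <- scores$chrom == out$chrom[k] & scores$pos >= out$start[k] &
      scores$pos < out$end[k]
    out$n_sites[k] <- sum(m)
    out$n_significant[k] <- sum(m & scores$significant)
    out$peak_z[k] <- max(scores$z[m])
    out$min_fdr[k] <- min(scores$fdr[m])
  }
  out
}

#' Count overlap events between two domain lists
#'
#' Two regions overlap when they share at least one base. Overlaps are
#' reported as merged events: a connected component of the bipartite overlap
#' graph counts once, matching Venn-diagram semantics.
#'
#' @param a,b Interval tibbles (e.g. from [call_enriched_domains()]), each
#'   internally non-overlapping.
#' @return A list with `n_overlap` (number of components containing regions
#'   from both lists) and `components` (tibble with the merged extent and
#'   per-list member counts).
#' @export
overlap_regions <- function(a, b) {
  .check_intervals(a, what = "a")
  .check_intervals(b, what = "b")
  for (nm in c("a", "b")) {
    x <- .sort_intervals(get(nm))
    if (nrow(x) > 1) {
      .assert(all(x$start[-1] >= cummax(x$end)[-nrow(x)] |
                    x$chrom[-1] != x$chrom[-nrow(x)]),
              "list '", nm, "' contains overlapping regions")
    }
  }
  all <- rbind(
    tibble::tibble(chrom = a$chrom, start = a$start, end = a$end, src = "a"),
    tibble::tibble(chrom = b$chrom, start = b$start, end = b$end, src = "b")
  )
  if (nrow(all) == 0) {
    return(list(n_overlap = 0L,
                components = tibble::tibble(chrom = character(),
                                            start = numeric(), end = numeric(),
                                            n_a = integer(), n_b = integer())))
  }
  all <- all[order(all$chrom, all$start, all$end), , drop = FALSE]
  comp <- lapply(split(all, all$chrom), function(d) {
    hi <- cummax(d$end)
    prev_hi <- c(-Inf, hi[-length(hi)])
    grp <- cumsum(d$start >= prev_hi) # strict overlap joins; book-ended does not
    tibble::tibble(
      chrom = d$chrom[1],
      start = as.numeric(tapply(d$start, grp, min)),
      end = as.numeric(tapply(d$end, grp, max)),
      n_a = as.integer(tapply(d$src == "a", grp, sum)),
      n_b = as.integer(tapply(d$src == "b", grp, sum))
    )
  })
  comp <- do.call(rbind, comp)
  rownames(comp) <- NULL
  comp <- .sort_intervals(comp)
  list(n_overlap = sum(comp$n_a > 0 & comp$n_b > 0), components = comp)
}
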