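# Independent brute-force oracles: plain O(N*M) scans and explicit loops,
# deliberately sharing no code with the package internals.

brute_count_flank <- function(sites, intervals, flank) {
  vapply(seq_len(nrow(sites)), function(i) {
    lo <- sites$pos[i] - flank
    hi <- sites$pos[i] + flank
    sum(intervals$chrom == sites$chrom[i] &
          intervals$start <= hi & intervals$end > lo)
  }, 0L)
}

brute_nearest <- function(sites, intervals) {
  vapply(seq_len(nrow(sites)), function(i) {
    d <- intervals[intervals$chrom == sites$chrom[i], , drop = FALSE]
    if (nrow(d) == 0) return(NA_real_)
    p <- sites$pos[i]
    signed <- ifelse(p >= d$start & p < d$end, 0,
                     ifelse(p >= d$end, p - d$end + 1, -(d$start - p)))
    best <- which(abs(signed) == min(abs(signed)))
    if (length(best) > 1) best <- best[which.min(d$start[best])]
    signed[best]
  }, 0)
}

brute_window_counts <- function(sites, lw) {
  vapply(seq_len(nrow(sites)), function(i) {
    sum(sites$chrom == sites$chrom[i] &
          abs(sites$pos - sites$pos[i]) <= lw / 2)
  }, 0L)
}

brute_zscores <- function(sites, genome, lw) {
  C <- brute_window_counts(sites, lw)
  nW <- table(sites$chrom)[sites$chrom]
  LW <- stats::setNames(genome$length, genome$chrom)[sites$chrom]
  mu <- as.numeric(nW) * lw / LW
  unname((C - mu) / sqrt(mu))
}

brute_call_sites <- function(tags, merge_window = 100, min_reads = 2) {
  out <- NULL
  for (ch in sort(unique(tags$chrom))) {
    p <- sort(tags$pos[tags$chrom == ch])
    cluster <- p[1]
    flush <- function(cl, acc) {
      if (length(cl) >= min_reads) {
        rbind(acc, data.frame(chrom = ch, pos = floor(stats::median(cl)),
                              read_count = length(cl)))
      } else acc
    }
    acc <- NULL
    for (x in p[-1]) {
      if (x - cluster[length(cluster)] <= merge_window) {
        cluster <- c(cluster, x)
      } else {
        acc <- flush(cluster, acc)
        cluster <- x
      }
    }
    acc <- flush(cluster, acc)
    out <- rbind(out, acc)
  }
  if (is.null(out)) data.frame(chrom = character(), pos = numeric(),
                               read_count = integer())
  else out[order(out$chrom, out$pos), , drop = FALSE]
}

brute_domains <- function(scores, genome, flank) {
  len <- stats::setNames(genome$length, genome$chrom)
  sig <- scores[scores$significant, , drop = FALSE]
  if (nrow(sig) == 0) {
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      n_sites = integer()))
  }
  seeds <- data.frame(chrom = sig$chrom,
                      start = pmax(0, sig$pos - flank),
                      end = pmin(len[sig$chrom], sig$pos + flank + 1))
  # repeated pairwise merging until a fixed point (book-ended included)
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(seeds)) {
      j <- i + 1
      while (j <= nrow(seeds)) {
        same <- seeds$chrom[i] == seeds$chrom[j]
        if (same && seeds$start[j] <= seeds$end[i] &&
            seeds$end[j] >= seeds$start[i]) {
          seeds$start[i] <- min(seeds$start[i], seeds$start[j])
          seeds$end[i] <- max(seeds$end[i], seeds$end[j])
          seeds <- seeds[-j, , drop = FALSE]
          merged <- TRUE
        } else j <- j + 1
      }
      i <- i + 1
    }
    if (!merged) break
  }
  seeds$n_sites <- vapply(seq_len(nrow(seeds)), function(k) {
    sum(scores$chrom == seeds$chrom[k] & scores$pos >= seeds$start[k] &
          scores$pos < seeds$end[k])
  }, 0L)
  seeds <- seeds[order(seeds$chrom, seeds$start), , drop = FALSE]
  rownames(seeds) <- NULL
  seeds
}

random_instance <- function(seed, n_sites = 200, n_iv = 200,
                            genome = genome_def(c("cA", "cB"), c(1e6, 5e5))) {
  set.seed(seed)
  len <- stats::setNames(genome$length, genome$chrom)
  sc <- sample(genome$chrom, n_sites, replace = TRUE)
  sites <- genomic_sites(sc, floor(runif(n_sites, 0, len[sc])))
  ic <- sample(genome$chrom, n_iv, replace = TRUE)
  st <- floor(runif(n_iv, 0, len[ic] - 1000))
  iv <- gintervals(ic, st, st + 1 + floor(runif(n_iv, 0, 999)))
  list(genome = genome, sites = sites, intervals = iv)
}
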