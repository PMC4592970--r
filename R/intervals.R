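#' Construct a table of genomic intervals
#'
#' Intervals are 0-based, half-open (`start` inclusive, `end` exclusive), the
#' BED convention. `value` carries an optional signal (e.g. a log2 replication
#' timing ratio); `name` an optional label.
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer-valued vectors, `0 <= start < end`.
#' @param name Optional character vector of labels.
#' @param value Optional numeric vector of per-interval values.
#' @return A tibble with columns `chrom`, `start`, `end` and, when supplied,
#'   `name` and `value`.
#' @export
gintervals <- function(chrom, start, end, name = NULL, value = NULL) {
  n <- max(length(chrom), length(start), length(end))
  .assert(all(c(length(chrom), length(start), length(end)) %in% c(1L, n)) ||
            n == 0,
          "chrom, start, end must have equal length (or length 1)")
  x <- tibble::tibble(chrom = as.character(rep_len(chrom, n)),
                      start = as.numeric(rep_len(start, n)),
                      end = as.numeric(rep_len(end, n)))
  if (!is.null(name)) x$name <- as.character(rep_len(name, n))
  if (!is.null(value)) x$value <- as.numeric(rep_len(value, n))
  if (n > 0) {
    .assert(all(x$start >= 0), "interval starts must be >= 0")
    .assert(all(x$start < x$end), "intervals must satisfy start < end")
  }
  x
}

.check_intervals <- function(x, genome = NULL, what = "intervals") {
  .assert(is.data.frame(x) && all(c("chrom", "start", "end") %in% names(x)),
          what, " must have columns chrom, start, end")
  if (nrow(x) == 0) return(invisible(x))
  .assert(all(x$start >= 0) && all(x$start < x$end),
          what, " must satisfy 0 <= start < end")
  if (!is.null(genome)) {
    .check_chroms(x$chrom, genome, what)
    len <- .glen(genome)
    .assert(all(x$end <= len[x$chrom]), what, " extend past chromosome ends")
  }
  invisible(x)
}

.sort_intervals <- function(x) {
  x[order(x$chrom, x$start, x$end), , drop = FALSE]
}

#' Merge overlapping genomic intervals
#'
#' Collapses a set of intervals to its union. With `bookended = TRUE`
#' (the default), intervals that touch end-to-start (`end == start`) are also
#' merged; with `FALSE` only intervals sharing at least one base are merged.
#'
#' The operation is idempotent and conserves the total number of covered
#' bases.
#'
#' @param x Interval tibble (see [gintervals()]).
#' @param bookended Merge book-ended intervals?
#' @return A sorted tibble of pairwise non-overlapping intervals with a column
#'   `n` giving the number of input intervals merged into each.
#' @examples
#' merge_overlapping(gintervals("chr1", c(0, 5, 30), c(10, 20, 40)))
#' @export
merge_overlapping <- function(x, bookended = TRUE) {
  .check_intervals(x)
  if (nrow(x) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(),
                          end = numeric(), n = integer()))
  }
  x <- .sort_intervals(x)
  out <- lapply(split(x, x$chrom), function(d) {
    # a new run starts where this start lies beyond the running max end
    hi <- cummax(d$end)
    prev_hi <- c(-Inf, hi[-length(hi)])
    new_run <- if (bookended) d$start > prev_hi else d$start >= prev_hi
    grp <- cumsum(new_run)
    tibble::tibble(
      chrom = d$chrom[1],
      start = as.numeric(tapply(d$start, grp, min)),
      end = as.numeric(tapply(d$end, grp, max)),
      n = as.integer(tapply(d$start, grp, length))
    )
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  .sort_intervals(out)
}
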