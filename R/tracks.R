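#' Build a named feature track
#'
#' A feature track is a named, sorted collection of genomic intervals of one
#' of three kinds: `"peak"` (plain intervals, e.g. histone-mark or DHS peaks),
#' `"point"` (1-bp positions, e.g. TSSs, CpGs or ChIP-seq tag starts) and
#' `"valued_segment"` (intervals carrying a numeric value, e.g. log2
#' early/late replication timing segments).
#'
#' @param name Track label.
#' @param intervals Interval tibble (see [gintervals()]).
#' @param kind One of `"peak"`, `"point"`, `"valued_segment"`.
#' @return A `feature_track` object.
#' @export
feature_track <- function(name, intervals,
                          kind = c("peak", "point", "valued_segment")) {
  kind <- match.arg(kind)
  .check_intervals(intervals, what = sprintf("track '%s'", name))
  if (kind == "valued_segment") {
    .assert("value" %in% names(intervals) && !anyNA(intervals$value),
            "valued_segment tracks need a complete 'value' column")
  }
  if (kind == "point" && nrow(intervals) > 0) {
    .assert(all(intervals$end - intervals$start == 1),
            "point tracks must contain width-1 intervals")
  }
  structure(list(name = name, kind = kind,
                 intervals = .sort_intervals(intervals)),
            class = "feature_track")
}

#' Build a point track from positions
#'
#' @param name Track label.
#' @param chrom,pos Chromosome and 0-based position vectors.
#' @return A `feature_track` of kind `"point"`.
#' @export
point_track <- function(name, chrom, pos) {
  feature_track(name, gintervals(chrom, pos, pos + 1), kind = "point")
}

#' @export
print.feature_track <- function(x, ...) {
  cat(sprintf("<feature_track> %s (%s): %d intervals on %d chromosome(s)\n",
              x$name, x$kind, nrow(x$intervals),
              length(unique(x$intervals$chrom))))
  invisible(x)
}

.track_intervals <- function(track) {
  if (inherits(track, "feature_track")) track$intervals else track
}

#' Read a BED or bedGraph file into a feature track
#'
#' Accepts BED3/BED4/BED6 (for `kind = "peak"` or `"point"`) or bedGraph
#' (4th column numeric, `kind = "valued_segment"`). Tab-separated, no header;
#' `track` and `browser` lines and comments are skipped. Coordinates are kept
#' in the file's native 0-based half-open convention.
#'
#' @param path File path.
#' @param kind Track kind, see [feature_track()].
#' @param genome Optional [genome_def()]; when supplied, lines on unknown
#'   chromosomes are rejected (`strict = TRUE`) or skipped (`strict = FALSE`).
#' @param strict Error on unknown chromosomes instead of skipping them.
#' @param name Track name; defaults to the file name.
#' @return A [feature_track()], sorted by (chrom, start).
#' @export
read_bed <- function(path, kind = c("peak", "point", "valued_segment"),
                     genome = NULL, strict = FALSE,
                     name = sub("\\.(bed|bedgraph)$", "", basename(path),
                                ignore.case = TRUE)) {
  kind <- match.arg(kind)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(feature_track(name, gintervals(character(), numeric(), numeric()),
                         kind = kind))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields", lineno[which(nf < 3)[1]]),
         call. = FALSE)
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: non-integer coordinates", lineno[bad[1]]),
         call. = FALSE)
  }
  bad <- which(start < 0 | start >= end)
  if (length(bad)) {
    stop(sprintf("malformed BED line %d: start >= end", lineno[bad[1]]),
         call. = FALSE)
  }
  x <- tibble::tibble(chrom = chrom, start = start, end = end)
  if (kind == "valued_segment") {
    if (any(nf < 4)) {
      stop(sprintf("malformed bedGraph line %d: missing value field",
                   lineno[which(nf < 4)[1]]), call. = FALSE)
    }
    val <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 4L)))
    if (anyNA(val)) {
      stop(sprintf("malformed bedGraph line %d: non-numeric value",
                   lineno[which(is.na(val))[1]]), call. = FALSE)
    }
    x$value <- val
  } else if (any(nf >= 4)) {
    x$name <- vapply(fields, function(f) {
      if (length(f) >= 4) f[[4]] else NA_character_
    }, "")
  }
  if (!is.null(genome)) {
    known <- x$chrom %in% genome$chrom
    if (!all(known)) {
      if (strict) {
        stop(sprintf("line %d: unknown chromosome '%s'",
                     lineno[which(!known)[1]], x$chrom[which(!known)[1]]),
             call. = FALSE)
      }
      x <- x[known, , drop = FALSE]
    }
    .check_intervals(x, genome, what = basename(path))
  }
  feature_track(name, x, kind = kind)
}

#' Write a feature track as BED or bedGraph
#'
#' Peak and point tracks are written as BED3 (plus a 4th name column when
#' present); valued-segment tracks as 4-column bedGraph.
#'
#' @param track A [feature_track()] or interval tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(track, path) {
  x <- .track_intervals(track)
  kind <- if (inherits(track, "feature_track")) track$kind else "peak"
  x <- .sort_intervals(x)
  out <- data.frame(chrom = x$chrom,
                    start = format(x$start, scientific = FALSE, trim = TRUE),
                    end = format(x$end, scientific = FALSE, trim = TRUE))
  if (kind == "valued_segment") {
    out$value <- x$value
  } else if ("name" %in% names(x)) {
    out$name <- x$name
  }
  .write_tsv(out, path, col.names = FALSE)
  invisible(path)
}
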