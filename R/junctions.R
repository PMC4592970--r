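#' Define the 4C bait region
#'
#' The bait is the ~0.6 kb region around the nested-PCR primer sites
#' (including a 300-bp extension) whose interaction partners the 4C library
#' captures.
#'
#' @param chrom Chromosome name.
#' @param start,end 0-based half-open interval.
#' @param source `"endogenous"` or `"transgenic"` bait.
#' @return A `bait_region` object.
#' @export
bait_region <- function(chrom, start, end,
                        source = c("endogenous", "transgenic")) {
  source <- match.arg(source)
  .assert(start >= 0 && start < end, "bait must satisfy 0 <= start < end")
  width <- end - start
  if (width < 100 || width > 5000) {
    warning("bait width ", width, " bp is far from the expected ~600 bp")
  }
  structure(list(chrom = chrom, start = as.numeric(start),
                 end = as.numeric(end), source = source),
            class = "bait_region")
}

#' @export
print.bait_region <- function(x, ...) {
  cat(sprintf("<bait_region> %s:%d-%d (%s, %d bp)\n", x$chrom, x$start,
              x$end, x$source, x$end - x$start))
  invisible(x)
}

#' Parse a bait from "chrom:start-end" notation
#'
#' @param spec String like `"chr1:5000000-5000600"` (0-based half-open).
#' @inheritParams bait_region
#' @export
parse_bait <- function(spec, source = "endogenous") {
  m <- regmatches(spec, regexec("^([^:]+):([0-9]+)-([0-9]+)$", spec))[[1]]
  .assert(length(m) == 4, "bait must be given as chrom:start-end")
  bait_region(m[2], as.numeric(m[3]), as.numeric(m[4]), source)
}

#' Extract fixed-length end tags from paired reads
#'
#' Takes the first `tag_length` bases (the 5' end) of each mate. Pairs in
#' which either read is shorter than `tag_length` are dropped and counted.
#'
#' @param reads1,reads2 Character vectors (or `Biostrings::DNAStringSet`s) of
#'   forward and reverse read sequences, parallel to each other.
#' @param tag_length Tag length in bp (default 20).
#' @return A list with `tags1`, `tags2` (character vectors of kept tags),
#'   `kept` (indices of surviving pairs) and `n_dropped`.
#' @export
extract_end_tags <- function(reads1, reads2, tag_length = 20) {
  reads1 <- as.character(reads1)
  reads2 <- as.character(reads2)
  .assert(length(reads1) == length(reads2), "read vectors must be paired")
  ok <- nchar(reads1) >= tag_length & nchar(reads2) >= tag_length
  list(tags1 = substr(reads1[ok], 1, tag_length),
       tags2 = substr(reads2[ok], 1, tag_length),
       kept = which(ok),
       n_dropped = sum(!ok))
}

#' Build a tag-pair table
#'
#' One row per read pair, with the alignment of each 20-bp end tag:
#' chromosome, 0-based start position, strand, mapping quality and a
#' uniquely-mapped flag.
#'
#' @param read_id Read identifiers.
#' @param chrom1,pos1,strand1,mapq1,unique1 Alignment of the first tag.
#' @param chrom2,pos2,strand2,mapq2,unique2 Alignment of the second tag.
#' @return A tibble of tag pairs.
#' @export
tag_pairs <- function(read_id, chrom1, pos1, mapq1, chrom2, pos2, mapq2,
                      strand1 = "+", strand2 = "+",
                      unique1 = TRUE, unique2 = TRUE) {
  n <- length(read_id)
  tibble::tibble(
    read_id = as.character(read_id),
    chrom1 = as.character(chrom1), pos1 = as.numeric(pos1),
    strand1 = rep_len(strand1, n), mapq1 = as.numeric(mapq1),
    unique1 = rep_len(as.logical(unique1), n),
    chrom2 = as.character(chrom2), pos2 = as.numeric(pos2),
    strand2 = rep_len(strand2, n), mapq2 = as.numeric(mapq2),
    unique2 = rep_len(as.logical(unique2), n)
  )
}

.check_pairs <- function(pairs) {
  need <- c("read_id", "chrom1", "pos1", "mapq1", "unique1",
            "chrom2", "pos2", "mapq2", "unique2")
  .assert(all(need %in% names(pairs)),
          "tag pairs must have columns ", paste(need, collapse = ", "))
  invisible(pairs)
}

#' Filter tag pairs on mapping quality and uniqueness
#'
#' Keeps a pair only if both tags are uniquely mapped and both have
#' MAPQ strictly greater than `mapq_min`.
#'
#' @param pairs Tag-pair tibble (see [tag_pairs()]).
#' @param mapq_min MAPQ threshold; pairs must exceed it (default 20).
#' @return The surviving rows of `pairs`.
#' @export
filter_tag_pairs <- function(pairs, mapq_min = 20) {
  .check_pairs(pairs)
  keep <- pairs$unique1 & pairs$unique2 &
    pairs$mapq1 > mapq_min & pairs$mapq2 > mapq_min
  pairs[keep, , drop = FALSE]
}

# distance from a tag start to the nearest bait boundary; 0 inside the bait
.bait_distance <- function(chrom, pos, bait) {
  d <- rep(Inf, length(pos))
  same <- chrom == bait$chrom
  p <- pos[same]
  d[same] <- ifelse(p < bait$start, bait$start - p,
                    ifelse(p >= bait$end, p - bait$end + 1, 0))
  d
}

#' Classify tag pairs against the bait
#'
#' A junction pair has exactly one tag inside the bait. The non-bait tag then
#' decides the class: a different chromosome gives `inter`; the same
#' chromosome more than `distal_cutoff` (10 kb) from the bait gives
#' `distal_intra`; more than `junction_cutoff` (300 bp) but at most 10 kb
#' gives `junction_proximal` (recorded but excluded from all downstream
#' statistics). Everything else - both tags in the bait, neither in the bait,
#' or within 300 bp - is `non_junction`. Distances are measured from the tag
#' start to the nearest bait boundary. The four classes partition the input.
#'
#' @param pairs Filtered tag-pair tibble.
#' @param bait A [bait_region()].
#' @param distal_cutoff Same-chromosome distance beyond which the partner is
#'   distal (default 10000).
#' @param junction_cutoff Minimum distance from the bait for a junction
#'   (default 300).
#' @return `pairs` with columns `class` (factor: non_junction,
#'   junction_proximal, distal_intra, inter), and `other_chrom`/`other_pos`
#'   (the non-bait tag, `NA` for non-junctions).
#' @export
classify_junctions <- function(pairs, bait, distal_cutoff = 10000,
                               junction_cutoff = 300) {
  .check_pairs(pairs)
  .assert(inherits(bait, "bait_region"), "bait must be a bait_region")
  in1 <- pairs$chrom1 == bait$chrom & pairs$pos1 >= bait$start &
    pairs$pos1 < bait$end
  in2 <- pairs$chrom2 == bait$chrom & pairs$pos2 >= bait$start &
    pairs$pos2 < bait$end
  one_in <- xor(in1, in2)
  other_chrom <- ifelse(in1, pairs$chrom2, pairs$chrom1)
  other_pos <- ifelse(in1, pairs$pos2, pairs$pos1)
  d <- .bait_distance(other_chrom, other_pos, bait)
  cls <- rep("non_junction", nrow(pairs))
  cls[one_in & other_chrom != bait$chrom] <- "inter"
  same <- one_in & other_chrom == bait$chrom
  cls[same & d > distal_cutoff] <- "distal_intra"
  cls[same & d > junction_cutoff & d <= distal_cutoff] <- "junction_proximal"
  pairs$class <- factor(cls, levels = c("non_junction", "junction_proximal",
                                        "distal_intra", "inter"))
  pairs$other_chrom <- ifelse(one_in, other_chrom, NA_character_)
  pairs$other_pos <- ifelse(one_in, other_pos, NA_real_)
  pairs
}

#' Merge distal junction tags into unique interacting sites
#'
#' Tags on one chromosome are chained by single linkage while consecutive
#' (sorted) positions are at most `merge_window` apart; each chain is one
#' PCR-deduplicated ligation event, represented by the median tag position
#' (rounded down) and supported by the chain size. Chains with fewer than
#' `min_reads` tags (singletons, by default) are discarded as background
#' noise. The result is invariant to input order and re-merging is a no-op.
#'
#' @param tags Tibble with columns `chrom`, `pos`: the non-bait tags of
#'   distal (intra > 10 kb or inter-chromosomal) junction pairs.
#' @param merge_window Maximum gap chained into one site (default 100 bp).
#' @param min_reads Minimum reads per retained site (default 2).
#' @return A sites tibble (see [genomic_sites()]), sorted by (chrom, pos).
#' @export
call_distal_sites <- function(tags, merge_window = 100, min_reads = 2) {
  .assert(all(c("chrom", "pos") %in% names(tags)),
          "tags must have columns chrom, pos")
  if (nrow(tags) == 0) return(genomic_sites(character(), numeric(), integer()))
  out <- lapply(split(tags$pos, tags$chrom), function(p) {
    p <- sort(p)
    grp <- cumsum(c(TRUE, diff(p) > merge_window))
    tibble::tibble(pos = as.numeric(tapply(p, grp, function(v) floor(stats::median(v)))),
                   read_count = as.integer(tapply(p, grp, length)))
  })
  chrom <- rep(names(out), vapply(out, nrow, 0L))
  out <- do.call(rbind, out)
  sites <- genomic_sites(chrom, out$pos, out$read_count)
  sites <- sites[sites$read_count >= min_reads, , drop = FALSE]
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  sites
}

#' Full site-calling pipeline from a tag-pair table
#'
#' Applies [filter_tag_pairs()], [classify_junctions()] and
#' [call_distal_sites()] and reports per-class read-pair counts.
#'
#' @inheritParams classify_junctions
#' @inheritParams filter_tag_pairs
#' @inheritParams call_distal_sites
#' @param genome Optional [genome_def()] for validation.
#' @return A list with `sites`, `class_counts` (named integer vector over the
#'   four junction classes plus `filtered_out`), and the classified pair
#'   table `pairs`.
#' @export
call_sites <- function(pairs, bait, genome = NULL, mapq_min = 20,
                       distal_cutoff = 10000, junction_cutoff = 300,
                       merge_window = 100, min_reads = 2) {
  .check_pairs(pairs)
  kept <- filter_tag_pairs(pairs, mapq_min)
  cls <- classify_junctions(kept, bait, distal_cutoff, junction_cutoff)
  distal <- cls[cls$class %in% c("distal_intra", "inter"), , drop = FALSE]
  sites <- call_distal_sites(
    tibble::tibble(chrom = distal$other_chrom, pos = distal$other_pos),
    merge_window = merge_window, min_reads = min_reads
  )
  if (!is.null(genome)) .check_sites(sites, genome)
  counts <- c(table(cls$class), filtered_out = nrow(pairs) - nrow(kept))
  list(sites = sites, class_counts = counts, pairs = cls)
}
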