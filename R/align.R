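# Exact-match tag alignment against the synthetic genome.
#
# Real libraries are aligned with an external short-read aligner (e.g. BWA)
# and consumed as a pre-aligned tag-pair table; the exact-match lookup here
# is valid only for the simulator's error-free genome, where every 20-bp tag
# is a verbatim substring of the forward strand.

#' Align fixed-length tags to a genome by exact matching
#'
#' Finds all exact forward-strand occurrences of each tag. Tags with exactly
#' one genome-wide hit are uniquely mapped (MAPQ 60); multi-hit tags are
#' flagged non-unique (MAPQ 0); unmatched tags are unmapped.
#'
#' @param tags Character vector of equal-length tag sequences.
#' @param seqs Named `Biostrings::DNAStringSet` of chromosome sequences.
#' @return A tibble (one row per input tag): `chrom`, `pos` (0-based start,
#'   `NA` if unmapped), `mapq`, `unique`, `n_hits`.
#' @export
align_tags_exact <- function(tags, seqs) {
  .assert(length(unique(nchar(tags))) <= 1, "tags must have equal length")
  utags <- unique(tags)
  pd <- Biostrings::PDict(utags)
  hit_chrom <- rep(NA_character_, length(utags))
  hit_pos <- rep(NA_real_, length(utags))
  n_hits <- integer(length(utags))
  for (ch in names(seqs)) {
    m <- Biostrings::matchPDict(pd, seqs[[ch]])
    starts <- Biostrings::startIndex(m)
    k <- lengths(starts) > 0
    first <- vapply(starts[k], `[[`, 0L, 1L)
    # record the first hit; uniqueness judged from the total count
    new <- k & n_hits == 0
    hit_chrom[new] <- ch
    hit_pos[new] <- first[n_hits[k] == 0] - 1
    n_hits <- n_hits + lengths(starts)
  }
  i <- match(tags, utags)
  tibble::tibble(chrom = hit_chrom[i], pos = hit_pos[i],
                 mapq = ifelse(n_hits[i] == 1, 60, 0),
                 unique = n_hits[i] == 1, n_hits = n_hits[i])
}

#' Build a tag-pair table from paired reads via exact-match alignment
#'
#' Extracts end tags with [extract_end_tags()] and aligns both tags with
#' [align_tags_exact()]. Pairs with an unmapped tag are dropped and counted;
#' non-uniquely mapped tags are kept with `unique = FALSE` so that
#' [filter_tag_pairs()] removes them.
#'
#' @param reads1,reads2 Paired read sequences (character or `DNAStringSet`).
#' @param seqs Named `DNAStringSet` of chromosome sequences.
#' @param read_id Optional read identifiers (default `names(reads1)` or a
#'   running index).
#' @param tag_length Tag length in bp (default 20).
#' @return A list with `pairs` (tag-pair tibble), `n_short` (pairs dropped at
#'   tag extraction) and `n_unmapped` (pairs with an unmatched tag).
#' @export
align_tag_pairs <- function(reads1, reads2, seqs, read_id = NULL,
                            tag_length = 20) {
  if (is.null(read_id)) {
    read_id <- names(reads1)
    if (is.null(read_id)) read_id <- sprintf("read%07d", seq_along(reads1))
  }
  et <- extract_end_tags(reads1, reads2, tag_length)
  a1 <- align_tags_exact(et$tags1, seqs)
  a2 <- align_tags_exact(et$tags2, seqs)
  mapped <- !is.na(a1$chrom) & !is.na(a2$chrom)
  pairs <- tag_pairs(
    read_id = read_id[et$kept][mapped],
    chrom1 = a1$chrom[mapped], pos1 = a1$pos[mapped], mapq1 = a1$mapq[mapped],
    chrom2 = a2$chrom[mapped], pos2 = a2$pos[mapped], mapq2 = a2$mapq[mapped],
    unique1 = a1$unique[mapped], unique2 = a2$unique[mapped]
  )
  list(pairs = pairs, n_short = et$n_dropped, n_unmapped = sum(!mapped))
}
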