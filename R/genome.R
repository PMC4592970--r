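#' Define a genome as named chromosomes with lengths
#'
#' A genome definition is the reference frame for every interval operation in
#' the package: all coordinates are 0-based, half-open, and must fall inside
#' the chromosome they are on.
#'
#' @param chroms Character vector of unique chromosome names.
#' @param lengths Numeric vector of chromosome lengths in base pairs,
#'   strictly positive, same length as `chroms`.
#' @return A `genome_def`: a tibble with columns `chrom` and `length`.
#' @examples
#' genome_def(c("chr1", "chr2"), c(2e6, 1e6))
#' @export
genome_def <- function(chroms, lengths) {
  .assert(length(chroms) == length(lengths),
          "chroms and lengths must have the same length")
  .assert(!anyDuplicated(chroms), "chromosome names must be unique")
  .assert(all(is.finite(lengths)) && all(lengths > 0),
          "chromosome lengths must be strictly positive")
  g <- tibble::tibble(chrom = as.character(chroms),
                      length = as.numeric(lengths))
  class(g) <- c("genome_def", class(g))
  g
}

#' Read chromosome sizes from a two-column text file
#'
#' @param path Path to a tab-separated "chrom<TAB>length" file (no header).
#' @return A [genome_def()].
#' @export
read_chrom_sizes <- function(path) {
  x <- utils::read.table(path, sep = "\t", header = FALSE,
                         col.names = c("chrom", "length"),
                         stringsAsFactors = FALSE)
  genome_def(x$chrom, x$length)
}

#' Write chromosome sizes as a two-column text file
#'
#' @param genome A [genome_def()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(genome, path) {
  .check_genome(genome)
  .write_tsv(genome[, c("chrom", "length")], path, col.names = FALSE)
  invisible(path)
}

.check_genome <- function(genome) {
  .assert(inherits(genome, "genome_def") ||
            (is.data.frame(genome) && all(c("chrom", "length") %in% names(genome))),
          "expected a genome_def (see genome_def())")
  invisible(genome)
}

# named vector of chromosome lengths
.glen <- function(genome) {
  stats::setNames(genome$length, genome$chrom)
}

.check_chroms <- function(chrom, genome, what = "input") {
  bad <- setdiff(unique(chrom), genome$chrom)
  .assert(length(bad) == 0,
          what, " uses chromosomes absent from the genome: ",
          paste(bad, collapse = ", "))
}
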