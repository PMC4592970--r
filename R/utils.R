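# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. Every randomized operation in the package funnels through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
}

.write_tsv <- function(x, path, col.names = TRUE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
}

.read_tsv <- function(path, ...) {
  tibble::as_tibble(utils::read.table(path, sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE, ...))
}

# number of elements of sorted vector `v` that are < x (vectorized over x)
.n_less <- function(x, v) findInterval(x, v, left.open = TRUE)
# number of elements of sorted vector `v` that are <= x
.n_leq <- function(x, v) findInterval(x, v)
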