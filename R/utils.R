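#' @importFrom rlang %||% abort warn .data
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join n distinct
#' @importFrom tibble tibble as_tibble
#' @importFrom purrr map map2 pmap map_dbl map_int
#' @importFrom stats median rbeta rbinom rgamma rgeom rmultinom runif setNames
#' @importFrom utils packageVersion
NULL

# reverse complement of plain character vectors (delegates to Biostrings)
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# 0-based substring of a sequence: bases [start, end)
seq_slice <- function(seq, start, end) {
  substr(seq, start + 1L, end)
}

assert_probability <- function(x, what, tol = 1e-9) {
  bad <- !is.finite(x) | x < -tol | x > 1 + tol
  if (any(bad)) {
    abort(sprintf(
      "%s must lie in [0, 1]; offending value(s): %s",
      what, paste(format(x[bad]), collapse = ", ")
    ))
  }
  pmin(pmax(x, 0), 1)
}

# midpoint-convention median reported as a percentage, one decimal
percent1 <- function(x) round(100 * x, 1)
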