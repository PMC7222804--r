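#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames
#' @importFrom utils read.table write.table
NULL

# Round half away from zero at `digits` decimal places (table-style rounding;
# base round() rounds half to even).
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random state.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Character vector of single bases for a sequence string.
seq_chars <- function(sequence) {
  strsplit(sequence, "", fixed = TRUE)[[1]]
}

# Positions (1-based, at the C) of CG dinucleotides fully inside `sequence`.
cpg_starts <- function(sequence) {
  hits <- gregexpr("CG", sequence, fixed = TRUE)[[1]]
  if (length(hits) == 1L && hits[1] == -1L) integer(0) else as.integer(hits)
}

count_cg_bases <- function(sequence) {
  chars <- seq_chars(sequence)
  sum(chars == "C" | chars == "G")
}
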