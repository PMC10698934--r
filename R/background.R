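# Background sampling: the n x m matrix before any bicluster is planted.

# format numeric values for storage in character matrices (heterogeneous
# data) and for TSV output; 15 significant digits round-trips doubles in
# practice and is stable across runs.
fmt_num <- function(x) {
  out <- format(x, digits = 15, trim = TRUE, scientific = FALSE)
  out[is.na(x)] <- NA_character_
  out
}

#' Assign per-column attribute types
#'
#' For heterogeneous datasets, exactly `round(pct_numeric_columns/100 *
#' n_cols)` columns are numeric and the rest symbolic, at randomized
#' positions. Homogeneous datasets map every column to the alphabet's kind.
#'
#' @param spec a validated [generator_spec()].
#' @return character vector of length `n_cols` with entries
#'   `"numeric-real"`, `"numeric-integer"` or `"symbolic"`.
#' @export
assign_column_types <- function(spec) {
  m <- spec$n_cols
  if (spec$data_type == "symbolic") return(rep("symbolic", m))
  if (spec$data_type == "numeric") return(rep(spec$alphabet$kind, m))
  k <- round(spec$pct_numeric_columns / 100 * m)
  types <- rep("symbolic", m)
  if (k > 0) types[sample.int(m, k)] <- spec$alphabet$kind
  types
}

sample_numeric_cells <- function(k, alphabet, background) {
  a <- alphabet
  x <- switch(background$kind,
    uniform = if (a$kind == "numeric-integer") {
      rsample(seq(a$min, a$max), k)
    } else {
      stats::runif(k, a$min, a$max)
    },
    normal = {
      z <- stats::rnorm(k, background$mean, background$sd)
      if (a$kind == "numeric-integer") z <- round(z)
      pmin(pmax(z, a$min), a$max)   # clipped, not resampled
    },
    missing = rep(NA_real_, k)
  )
  as.numeric(x)
}

sample_symbolic_cells <- function(k, alphabet, background) {
  switch(background$kind,
    uniform = rsample(alphabet$symbols, k),
    discrete = alphabet$symbols[sample.int(length(alphabet$symbols), k,
                                           replace = TRUE,
                                           prob = alphabet$symbol_probabilities)],
    missing = rep(NA_character_, k)
  )
}

#' Sample the background matrix
#'
#' Generates every cell of the dataset from the configured background
#' distribution, before any bicluster is planted: `uniform` draws i.i.d.
#' uniformly over the alphabet, `normal` draws Gaussian values clipped to
#' the alphabet range (rounded first for integer alphabets), `discrete`
#' draws symbols with the user probabilities, and `missing` leaves every
#' cell at the missing marker (`NA`).
#'
#' Numeric datasets yield a numeric matrix; symbolic and heterogeneous
#' datasets a character matrix (numeric cells rendered as decimal strings).
#'
#' @param spec a validated [generator_spec()].
#' @param column_types per-column types from [assign_column_types()].
#' @return an `n_rows` x `n_cols` matrix.
#' @export
sample_background <- function(spec, column_types = assign_column_types(spec)) {
  n <- spec$n_rows; m <- spec$n_cols
  bg <- spec$background
  if (spec$data_type == "numeric") {
    return(matrix(sample_numeric_cells(n * m, spec$alphabet, bg), n, m))
  }
  if (spec$data_type == "symbolic") {
    return(matrix(sample_symbolic_cells(n * m, spec$alphabet, bg), n, m))
  }
  # heterogeneous: one numeric and one symbolic alphabet, applied per column
  out <- matrix(NA_character_, n, m)
  for (j in seq_len(m)) {
    if (column_types[j] == "symbolic") {
      bgj <- if (bg$kind == "normal") background_spec("uniform") else bg
      out[, j] <- sample_symbolic_cells(n, spec$symbolic_alphabet, bgj)
    } else {
      bgj <- if (bg$kind == "discrete") background_spec("uniform") else bg
      out[, j] <- fmt_num(sample_numeric_cells(n, spec$alphabet, bgj))
    }
  }
  out
}
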