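# Small spec builders shared across the suite.

real_alpha <- function(min = -100, max = 100)
  alphabet_spec("numeric-real", min = min, max = max)

int_alpha <- function(min = 0, max = 100)
  alphabet_spec("numeric-integer", min = min, max = max)

sym_alpha <- function(symbols = c("a", "b", "c", "d", "e"), probs = NULL)
  alphabet_spec("symbolic", symbols = symbols, symbol_probabilities = probs)

tiny_spec <- function(...) {
  args <- list(...)
  defaults <- list(n_rows = 30, n_cols = 20,
                   alphabet = real_alpha(),
                   background = background_spec("uniform"),
                   n_biclusters = 2,
                   row_size = size_dist("uniform", low = 3, high = 6),
                   col_size = size_dist("uniform", low = 3, high = 6),
                   seed = 1)
  do.call(generator_spec, utils::modifyList(defaults, args))
}

# brute-force plaid oracle over membership indicators (sum / product / mean
# of the covering biclusters' contributions, background kept when uncovered)
brute_force_compose <- function(background, bics, mode) {
  n <- nrow(background); m <- ncol(background)
  out <- background
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      theta <- numeric(0)
      for (b in bics) {
        ri <- match(i, b$rows); cj <- match(j, b$cols)
        if (!is.na(ri) && !is.na(cj)) theta <- c(theta, b$values[ri, cj])
      }
      if (length(theta) > 0) {
        out[i, j] <- switch(mode,
          additive = sum(theta),
          multiplicative = prod(theta),
          interpoled = mean(theta),
          none = theta[length(theta)])
      }
    }
  }
  out
}

# all cells of a dataset conform to the alphabet(s); NA allowed everywhere
expect_alphabet_closure <- function(d) {
  spec <- d$spec
  if (spec$data_type == "numeric") {
    v <- d$data[!is.na(d$data)]
    expect_true(all(v >= spec$alphabet$min - 1e-9 & v <= spec$alphabet$max + 1e-9))
    if (spec$alphabet$kind == "numeric-integer")
      expect_true(all(v == round(v)))
  } else if (spec$data_type == "symbolic") {
    v <- d$data[!is.na(d$data)]
    expect_true(all(v %in% spec$alphabet$symbols))
  } else {
    for (j in seq_len(ncol(d$data))) {
      v <- d$data[, j]; v <- v[!is.na(v)]
      if (length(v) == 0) next
      if (d$column_types[j] == "symbolic") {
        expect_true(all(v %in% spec$symbolic_alphabet$symbols))
      } else {
        num <- suppressWarnings(as.numeric(v))
        expect_false(anyNA(num))
        expect_true(all(num >= spec$alphabet$min - 1e-9 &
                        num <= spec$alphabet$max + 1e-9))
      }
    }
  }
  invisible(TRUE)
}

# a minimal constant bic_def for composer-level tests
const_bic <- function(rows, cols, value) {
  structure(list(rows = rows, cols = cols, contiguous = FALSE,
                 values = matrix(value, length(rows), length(cols)),
                 pattern = pattern_spec("constant", "constant"),
                 type = "numeric", mu = value,
                 alpha = rep(0, length(rows)), beta = rep(0, length(cols)),
                 permutation = NULL),
            class = "bic_def")
}
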