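# Pattern planting: fill a frame with values obeying its (row, column)
# coherency, including order-preserving layouts and time profiles.

FACTOR_BUDGET <- 1000L

# Evaluate the closed-form coherency grid from stored factors. Constant
# dimensions contribute the neutral element (0 additive, 1 multiplicative);
# a "none" dimension carries i.i.d. factors drawn at planting time.
pattern_grid <- function(mu, alpha, beta, rows_coh, cols_coh, nr, nc) {
  if (rows_coh == "multiplicative" || cols_coh == "multiplicative") {
    outer(alpha, beta) * mu
  } else if (rows_coh == "none" && cols_coh == "constant") {
    matrix(alpha, nr, nc)                      # b_ij = alpha_i
  } else if (rows_coh == "constant" && cols_coh == "none") {
    matrix(beta, nr, nc, byrow = TRUE)         # b_ij = beta_j
  } else {
    outer(alpha, beta, `+`) + mu               # additive family / constant
  }
}

draw_alphabet_values <- function(k, alphabet) {
  if (alphabet$kind == "numeric-integer")
    rsample(seq(alphabet$min, alphabet$max), k)
  else stats::runif(k, alphabet$min, alphabet$max)
}

sample_constant_family <- function(p, alphabet, nr, nc) {
  a <- alphabet
  integerish <- a$kind == "numeric-integer"
  rnd <- function(x) if (integerish) round(x) else x
  mu <- 0; alpha <- rep(0, nr); beta <- rep(0, nc)
  if (p$rows == "none" && p$cols == "constant") {
    alpha <- draw_alphabet_values(nr, a)
  } else if (p$rows == "constant" && p$cols == "none") {
    beta <- draw_alphabet_values(nc, a)
  } else if (p$rows == "constant" && p$cols == "constant") {
    mu <- draw_alphabet_values(1, a)
  } else if (p$rows %in% c("additive", "constant") && p$cols %in% c("additive", "constant")) {
    mu <- draw_alphabet_values(1, a)
    lo <- a$min - mu; hi <- a$max - mu
    both <- p$rows == "additive" && p$cols == "additive"
    share <- if (both) 2 else 1
    draw_factor <- function(k) {
      if (integerish) rsample(seq(ceiling(lo / share), floor(hi / share)), k)
      else stats::runif(k, lo / share, hi / share)
    }
    if (p$rows == "additive") alpha <- draw_factor(nr)
    if (p$cols == "additive") beta <- draw_factor(nc)
  }
  if (p$rows == "multiplicative" || p$cols == "multiplicative") {
    mu <- 0
    for (try in seq_len(FACTOR_BUDGET)) {
      cand <- draw_alphabet_values(1, a)
      thr <- if (integerish) 1 else 0.001 * (a$max - a$min)
      if (abs(cand) >= thr) { mu <- cand; break }
    }
    if (mu == 0)
      stop("multiplicative factor sampling failed: could not draw a seed ",
           "value away from zero within [", a$min, ", ", a$max, "]",
           call. = FALSE)
    cap <- if (mu > 0) a$max else abs(a$min)
    both <- p$rows == "multiplicative" && p$cols == "multiplicative"
    s <- if (both) sqrt(cap / abs(mu)) else cap / abs(mu)
    alpha <- rep(1, nr); beta <- rep(1, nc)
    if (p$rows == "multiplicative")
      alpha <- if (integerish) rsample(seq_len(max(1, floor(s))), nr)
               else stats::runif(nr, 1, s)
    if (p$cols == "multiplicative")
      beta <- if (integerish) rsample(seq_len(max(1, floor(s))), nc)
              else stats::runif(nc, 1, s)
  }
  list(mu = mu, alpha = alpha, beta = beta)
}

profile_permutation <- function(profile, nc) {
  switch(profile,
    "monotonically-increasing" = seq_len(nc),
    "monotonically-decreasing" = rev(seq_len(nc)),
    "random" = sample.int(nc),
    "none" = sample.int(nc)
  )
}

# Row-sorted distinct values, one row at a time; symbolic alphabets sample
# distinct symbols and order by rank in the symbol list.
op_sorted_rows <- function(nr, nc, alphabet) {
  draw_row <- if (alphabet$kind == "symbolic") {
    ns <- length(alphabet$symbols)
    if (nc > ns)
      stop("order-preserving pattern over ", nc, " columns needs at least ",
           nc, " distinct symbols, alphabet has ", ns, call. = FALSE)
    function() sort(sample.int(ns, nc))
  } else if (alphabet$kind == "numeric-integer") {
    nv <- alphabet$max - alphabet$min + 1
    # strictly increasing rows need nc distinct integers; alphabets too
    # coarse for that degrade to non-decreasing rows (ties allowed)
    if (nc > nv)
      function() sort(rsample(seq(alphabet$min, alphabet$max), nc))
    else
      function() sort(resample(seq(alphabet$min, alphabet$max), nc))
  } else {
    function() {
      for (try in seq_len(FACTOR_BUDGET)) {
        v <- stats::runif(nc, alphabet$min, alphabet$max)
        if (!anyDuplicated(v)) return(sort(v))
      }
      sort(stats::runif(nc, alphabet$min, alphabet$max))
    }
  }
  matrix(unlist(lapply(seq_len(nr), function(i) draw_row())),
         nr, nc, byrow = TRUE)
}

op_grid_from_sorted <- function(sorted_rows, perm, symbols = NULL) {
  nr <- nrow(sorted_rows); nc <- ncol(sorted_rows)
  grid <- sorted_rows
  grid[, perm] <- sorted_rows
  if (!is.null(symbols)) {
    grid <- matrix(symbols[grid], nr, nc)
  }
  grid
}

#' Plant a coherency pattern into a frame
#'
#' Fills the frame with values obeying the declared (row, column) coherency:
#' constant/additive/multiplicative grids are built from a seed value `mu`,
#' row factors `alpha_i` and column factors `beta_j` sampled so every value
#' stays inside the alphabet; a `none` dimension draws free i.i.d. values.
#' Order-preserving patterns sample strictly distinct values per row and
#' arrange them so one shared column permutation sorts every row ascending
#' (transposed for row-side order preservation); symbolic order is rank
#' order in the symbol list.
#'
#' @param frame a frame from [place_frames()] (fields `rows`, `cols`,
#'   `contiguous`).
#' @param pattern a [pattern_spec()] legal for `alphabet`.
#' @param alphabet an [alphabet_spec()].
#' @return an object of class `bic_def`: the frame plus `values`
#'   (`|I|` x `|J|` grid), coherency metadata, factors `mu`, `alpha`,
#'   `beta`, and (order-preserving only) the shared `permutation`.
#' @export
plant_pattern <- function(frame, pattern, alphabet) {
  p <- pattern
  nr <- length(frame$rows); nc <- length(frame$cols)
  if (!pattern_is_legal(p))
    stop("illegal coherency combination (", p$rows, ", ", p$cols, ")", call. = FALSE)
  if (pattern_numeric_only(p) && alphabet$kind == "symbolic")
    stop(p$rows, "/", p$cols, " coherency requires a numeric alphabet", call. = FALSE)
  symbolic <- alphabet$kind == "symbolic"

  if (p$cols == "order-preserving") {
    sorted <- op_sorted_rows(nr, nc, alphabet)
    perm <- profile_permutation(p$time_profile, nc)
    values <- op_grid_from_sorted(sorted, perm,
                                  symbols = if (symbolic) alphabet$symbols)
    out <- list(mu = NULL, alpha = NULL, beta = NULL, permutation = perm)
  } else if (p$rows == "order-preserving") {
    sorted <- op_sorted_rows(nc, nr, alphabet)   # build on the transpose
    perm <- profile_permutation("none", nr)
    values <- t(op_grid_from_sorted(sorted, perm,
                                    symbols = if (symbolic) alphabet$symbols))
    out <- list(mu = NULL, alpha = NULL, beta = NULL, permutation = perm)
  } else if (symbolic) {
    sym <- alphabet$symbols
    values <- if (p$rows == "constant" && p$cols == "constant") {
      matrix(resample(sym, 1), nr, nc)
    } else if (p$rows == "none" && p$cols == "constant") {
      matrix(sym[sample.int(length(sym), nr, replace = TRUE)], nr, nc)
    } else { # constant rows / none cols: one symbol per column
      matrix(sym[sample.int(length(sym), nc, replace = TRUE)], nr, nc,
             byrow = TRUE)
    }
    out <- list(mu = NULL, alpha = NULL, beta = NULL, permutation = NULL)
  } else {
    f <- sample_constant_family(p, alphabet, nr, nc)
    values <- pattern_grid(f$mu, f$alpha, f$beta, p$rows, p$cols, nr, nc)
    if (alphabet$kind == "numeric-integer") values <- round(values)
    if (any(values < alphabet$min - 1e-9) || any(values > alphabet$max + 1e-9))
      stop("factor sampling produced values outside [", alphabet$min, ", ",
           alphabet$max, "] for ", p$rows, "/", p$cols, call. = FALSE)
    out <- list(mu = f$mu, alpha = f$alpha, beta = f$beta, permutation = NULL)
  }
  structure(c(list(rows = frame$rows, cols = frame$cols,
                   contiguous = isTRUE(frame$contiguous),
                   values = values, pattern = p,
                   type = if (symbolic) "symbolic" else "numeric"),
              out),
            class = "bic_def")
}

#' Re-apply a time profile to an order-preserving bicluster
#'
#' Rewrites the shared column permutation of a planted order-preserving
#' C-bicluster: `monotonically-increasing` makes every row strictly increase
#' in real column order, `monotonically-decreasing` strictly decrease, and
#' `random` draws one shared random permutation. Only column-side
#' order-preserving patterns on contiguous frames carry a time profile.
#'
#' @param bic a `bic_def` from [plant_pattern()].
#' @param profile one of `"monotonically-increasing"`,
#'   `"monotonically-decreasing"`, `"random"`.
#' @return the modified `bic_def`.
#' @export
apply_time_profile <- function(bic, profile) {
  if (!inherits(bic, "bic_def") || bic$pattern$cols != "order-preserving")
    stop("time profiles apply only to column-side order-preserving biclusters",
         call. = FALSE)
  if (!isTRUE(bic$contiguous))
    stop("time profiles require a contiguous (C-bicluster) frame", call. = FALSE)
  if (!profile %in% setdiff(TIME_PROFILES, "none"))
    stop("unknown time profile '", profile, "'", call. = FALSE)
  nc <- length(bic$cols)
  # recover the row-sorted grid (grid[, perm] == sorted, so sorted ==
  # grid[, perm]) and lay it out under the new permutation
  sorted <- bic$values[, bic$permutation, drop = FALSE]
  perm <- profile_permutation(profile, nc)
  new_vals <- sorted
  new_vals[, perm] <- sorted
  bic$values <- new_vals
  bic$permutation <- perm
  bic$pattern$time_profile <- profile
  bic
}
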