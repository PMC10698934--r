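# Plaid composition: merge planted biclusters into the background and
# record the ground-truth solution.

cell_index <- function(rows, cols, n) {
  as.vector(outer(rows, (cols - 1L) * n, `+`))
}

#' Compose planted biclusters with the background under a plaid model
#'
#' Cells covered by no bicluster keep their background value. Covered cells
#' combine the contributions of all covering biclusters according to the
#' plaid coherency: `additive` sums them, `multiplicative` multiplies them,
#' `interpoled` averages them over the covering biclusters, and `none`
#' keeps the value of the last-generated covering bicluster. The background
#' does not contribute a layer to covered cells. Results are clipped to the
#' alphabet (integers rounded first); clipped cells are flagged.
#'
#' @param background matrix from [sample_background()].
#' @param bics list of `bic_def` objects from [plant_pattern()].
#' @param mode plaid coherency (`"additive"`, `"multiplicative"`,
#'   `"interpoled"`, `"none"`; `"no-overlap"` behaves as `"none"`).
#' @param alphabet numeric [alphabet_spec()] (ignored for symbolic data).
#' @return an object of class `bic_composition`: list with `values` (the
#'   composed matrix), `coverage` (integer matrix of covering-bicluster
#'   counts), `mode`, and `clipped` (linear indices of clipped cells).
#' @export
compose <- function(background, bics, mode = "none", alphabet = NULL) {
  n <- nrow(background); m <- ncol(background)
  q <- length(bics)
  if (mode == "no-overlap") mode <- "none"
  coverage <- matrix(0L, n, m)
  values <- background
  numeric_data <- is.numeric(background)
  if (mode %in% c("additive", "multiplicative", "interpoled") && !numeric_data)
    stop("arithmetic plaid coherency on symbolic overlap regions is ",
         "rejected (use mode 'none')", call. = FALSE)

  if (numeric_data) {
    acc_sum <- matrix(0, n, m)
    acc_prod <- matrix(1, n, m)
    acc_last <- matrix(NA_real_, n, m)
    for (b in bics) {
      idx <- cell_index(b$rows, b$cols, n)
      coverage[idx] <- coverage[idx] + 1L
      v <- as.numeric(b$values)
      acc_sum[idx] <- acc_sum[idx] + v
      acc_prod[idx] <- acc_prod[idx] * v
      acc_last[idx] <- v
    }
    cov_idx <- which(coverage > 0L)
    values[cov_idx] <- switch(mode,
      additive = acc_sum[cov_idx],
      multiplicative = acc_prod[cov_idx],
      interpoled = acc_sum[cov_idx] / coverage[cov_idx],
      none = acc_last[cov_idx]
    )
    if (!is.null(alphabet) && alphabet$kind == "numeric-integer")
      values[cov_idx] <- round(values[cov_idx])
    clipped <- integer(0)
    if (!is.null(alphabet)) {
      out_of_range <- cov_idx[values[cov_idx] < alphabet$min |
                              values[cov_idx] > alphabet$max]
      if (length(out_of_range) > 0) {
        values[out_of_range] <- pmin(pmax(values[out_of_range], alphabet$min),
                                     alphabet$max)
        clipped <- out_of_range
      }
    }
  } else {
    # symbolic / heterogeneous matrices: last-writer-wins only
    for (b in bics) {
      idx <- cell_index(b$rows, b$cols, n)
      coverage[idx] <- coverage[idx] + 1L
      v <- b$values
      values[idx] <- if (is.character(v)) as.vector(v) else fmt_num(as.numeric(v))
    }
    clipped <- integer(0)
  }
  structure(list(values = values, coverage = coverage, mode = mode,
                 clipped = clipped),
            class = "bic_composition")
}

#' Membership indicators of a plaid composition
#'
#' Returns the row-membership and column-membership boolean matrices of the
#' plaid model: entry `(i, t)` of `rho` is `TRUE` when row `i` belongs to
#' bicluster `t`, and likewise `kappa` for columns, so a cell `(i, j)`
#' belongs to bicluster `t` exactly when `rho[i, t] && kappa[j, t]`.
#'
#' @param bics list of `bic_def` objects.
#' @param n_rows,n_cols dataset dimensions.
#' @return list with logical matrices `rho` (`n_rows` x `q`) and `kappa`
#'   (`n_cols` x `q`).
#' @export
plaid_membership <- function(bics, n_rows, n_cols) {
  q <- length(bics)
  rho <- matrix(FALSE, n_rows, q)
  kappa <- matrix(FALSE, n_cols, q)
  for (t in seq_len(q)) {
    rho[bics[[t]]$rows, t] <- TRUE
    kappa[bics[[t]]$cols, t] <- TRUE
  }
  list(rho = rho, kappa = kappa)
}

#' Assemble the ground-truth solution record
#'
#' Lists, per planted bicluster, its row and column indices, its final
#' (post-composition, pre-quality) value grid, its coherency metadata, and
#' which of its cells were clipped during composition.
#'
#' @param bics list of `bic_def` objects.
#' @param composition a [compose()] result.
#' @return an object of class `bic_solution`.
#' @export
ground_truth <- function(bics, composition) {
  n <- nrow(composition$values)
  m <- ncol(composition$values)
  clipped <- composition$clipped
  recs <- lapply(seq_along(bics), function(t) {
    b <- bics[[t]]
    idx <- cell_index(b$rows, b$cols, n)
    final <- matrix(composition$values[idx], length(b$rows), length(b$cols))
    list(id = t, rows = b$rows, cols = b$cols,
         n_rows = length(b$rows), n_cols = length(b$cols),
         values = final,
         row_coherency = b$pattern$rows, col_coherency = b$pattern$cols,
         time_profile = b$pattern$time_profile,
         type = b$type, contiguous = b$contiguous,
         clipped_cells = intersect(idx, clipped))
  })
  structure(list(n_rows = n, n_cols = m, plaid = composition$mode,
                 biclusters = recs, quality = NULL),
            class = "bic_solution")
}

#' @export
print.bic_solution <- function(x, ...) {
  cat("Planted biclustering solution:", length(x$biclusters), "bicluster(s)",
      "in a", x$n_rows, "x", x$n_cols, "matrix\n")
  for (b in x$biclusters)
    cat(sprintf("  #%d: %dx%d (%s/%s)%s\n", b$id, b$n_rows, b$n_cols,
                b$row_coherency, b$col_coherency,
                if (!is.null(b$time_profile) && b$time_profile != "none")
                  paste0(", ", b$time_profile) else ""))
  invisible(x)
}
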