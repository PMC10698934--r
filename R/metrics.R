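# Internal homogeneity metric (virtual error) and element-level Jaccard.

#' Virtual error of a numeric submatrix
#'
#' Standardizes each row to zero mean and unit (population) standard
#' deviation, `b^_ij = (b_ij - mu_i) / sigma_i`; constant rows
#' (`sigma_i = 0`) standardize to all zeros. The virtual pattern
#' `rho^_j` is the column mean of the standardized grid, and the virtual
#' error is the mean absolute deviation from it:
#' `VE = 1/(|I||J|) * sum_ij |b^_ij - rho^_j|`.
#'
#' VE is zero (to machine precision) for noise-free constant, additive and
#' multiplicative biclusters with positive row scaling, and is invariant to
#' per-row affine maps `b_ij -> a_i * b_ij + c_i` with `a_i > 0`.
#' Order-preserving biclusters need not reach zero but score well below
#' non-homogeneous submatrices.
#'
#' @param values numeric matrix with at least 1 row, 2 columns, and no
#'   missing cells (mask or impute beforehand).
#' @return an object of class `bic_ve`: list with `standardized`,
#'   `row_means`, `row_sds`, `virtual_pattern`, and the scalar `ve`.
#' @examples
#' virtual_error(matrix(c(1, 2, 2, 1), 2, 2))$ve  # 1
#' @export
virtual_error <- function(values) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("virtual_error expects a numeric matrix", call. = FALSE)
  if (anyNA(values))
    stop("virtual_error expects no missing cells; mask or impute first",
         call. = FALSE)
  if (nrow(values) < 1 || ncol(values) < 2)
    stop("virtual_error needs at least 1 row and 2 columns", call. = FALSE)
  mu <- rowMeans(values)
  centered <- values - mu
  sigma <- sqrt(rowMeans(centered^2))      # population standard deviation
  bhat <- centered / ifelse(sigma == 0, 1, sigma)
  bhat[sigma == 0, ] <- 0
  rho <- colMeans(bhat)
  ve <- mean(abs(sweep(bhat, 2, rho)))
  structure(list(standardized = bhat, row_means = mu, row_sds = sigma,
                 virtual_pattern = rho, ve = ve),
            class = "bic_ve")
}

#' @export
print.bic_ve <- function(x, ...) {
  cat(sprintf("Virtual error: %.6g (%d x %d submatrix)\n", x$ve,
              nrow(x$standardized), ncol(x$standardized)))
  invisible(x)
}

solution_cells <- function(sol) {
  if (inherits(sol, "bic_solution")) {
    n <- sol$n_rows
    bics <- sol$biclusters
  } else if (is.list(sol) && !is.null(attr(sol, "n_rows"))) {
    n <- attr(sol, "n_rows")
    bics <- sol
  } else stop("expected a bic_solution object", call. = FALSE)
  unique(unlist(lapply(bics, function(b) cell_index(b$rows, b$cols, n))))
}

#' Element-level Jaccard score between two biclustering solutions
#'
#' Compares the unions of bicluster cell sets:
#' `|cells(found) intersect cells(planted)| / |cells(found) union cells(planted)|`.
#' Two empty solutions score 0 by convention.
#'
#' @param found,planted `bic_solution` objects referring to the same matrix
#'   dimensions.
#' @return a score in `[0, 1]`.
#' @export
element_jaccard <- function(found, planted) {
  if (inherits(found, "bic_solution") && inherits(planted, "bic_solution") &&
      (found$n_rows != planted$n_rows || found$n_cols != planted$n_cols))
    stop("solutions reference different matrix dimensions", call. = FALSE)
  a <- solution_cells(found)
  b <- solution_cells(planted)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}
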