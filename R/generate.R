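# Full generation pipeline: one seeded run from spec to benchmark dataset.

pattern_for <- function(spec, t) {
  spec$patterns[[(t - 1L) %% length(spec$patterns) + 1L]]
}

# Heterogeneous data: each bicluster spans columns of a single attribute
# type. Patterns needing numeric data force numeric columns; symbolic
# order-preserving biclusters need enough distinct symbols for their width.
assign_bic_types <- function(spec, sizes, column_types) {
  q <- spec$n_biclusters
  if (spec$data_type != "heterogeneous")
    return(rep(if (spec$data_type == "symbolic") "symbolic" else "numeric", q))
  n_sym <- length(spec$symbolic_alphabet$symbols)
  vapply(seq_len(q), function(t) {
    p <- pattern_for(spec, t)
    if (pattern_numeric_only(p)) return("numeric")
    sym_ok <- TRUE
    if (p$cols == "order-preserving" && sizes$cols[t] > n_sym) sym_ok <- FALSE
    if (p$rows == "order-preserving" && sizes$rows[t] > n_sym) sym_ok <- FALSE
    if (!sym_ok) return("numeric")
    if (stats::runif(1) < spec$pct_numeric_columns / 100) "numeric" else "symbolic"
  }, "")
}

#' Generate a benchmark dataset with planted biclusters
#'
#' Runs the full pipeline under a single seeded random stream: sample the
#' background, draw bicluster sizes, build the overlap plan, place frames,
#' plant coherency patterns (with time profiles where configured), compose
#' overlapping biclusters under the plaid coherency, record the ground
#' truth, and inject missing/noise/error cells.
#'
#' Identical `(spec, seed)` pairs produce identical datasets.
#'
#' @param spec a [generator_spec()] or preset name (see [list_presets()]).
#' @param seed integer seed; defaults to the seed stored in the spec.
#' @return an object of class `bic_dataset`: list with `data` (the final
#'   matrix; `NA` marks missing), `column_types`, `biclusters` (planted
#'   `bic_def`s), `solution` (ground truth, a `bic_solution`),
#'   `composition` (plaid mode, coverage counts, clipped cells), `quality`
#'   (the injection mask), `spec` and `seed`.
#' @examples
#' d <- generate_dataset(preset_spec("illustrative-1"), seed = 7)
#' summary(d)
#' @export
generate_dataset <- function(spec, seed = NULL) {
  if (is.character(spec)) spec <- preset_spec(spec)
  spec <- validate_spec(spec)
  if (is.null(seed)) seed <- spec$seed
  spec$seed <- as.integer(seed)
  set.seed(spec$seed)

  column_types <- assign_column_types(spec)
  background <- sample_background(spec, column_types)
  sizes <- sample_sizes(spec)
  plan <- build_overlap_plan(spec)
  bic_types <- assign_bic_types(spec, sizes, column_types)

  col_pools <- NULL
  if (spec$data_type == "heterogeneous") {
    num_cols <- which(column_types != "symbolic")
    sym_cols <- which(column_types == "symbolic")
    col_pools <- lapply(bic_types, function(ty)
      if (ty == "symbolic") sym_cols else num_cols)
    short <- vapply(seq_len(spec$n_biclusters),
                    function(t) length(col_pools[[t]]) < sizes$cols[t], TRUE)
    sizes$cols[short] <- pmax(1L, vapply(col_pools[short], length, 1L))
  }

  frames <- place_frames(sizes, plan, spec, col_pools = col_pools)

  bics <- lapply(seq_len(spec$n_biclusters), function(t) {
    alpha <- if (bic_types[t] == "symbolic") {
      if (spec$data_type == "heterogeneous") spec$symbolic_alphabet else spec$alphabet
    } else spec$alphabet
    plant_pattern(frames[[t]], pattern_for(spec, t), alpha)
  })

  mode <- if (spec$overlap$plaid == "no-overlap") "none" else spec$overlap$plaid
  numeric_alpha <- if (spec$data_type == "symbolic") NULL else spec$alphabet
  comp <- compose(background, bics, mode = mode, alphabet = numeric_alpha)
  solution <- ground_truth(bics, comp)

  inj <- inject_quality(comp, bics, spec$quality,
                        alphabet = if (spec$data_type == "symbolic") spec$alphabet
                                   else spec$alphabet,
                        column_types = if (spec$data_type == "heterogeneous")
                                         column_types else NULL,
                        symbolic_alphabet = spec$symbolic_alphabet)
  solution$quality <- inj$mask

  structure(list(data = inj$values, column_types = column_types,
                 biclusters = bics, solution = solution,
                 composition = list(mode = comp$mode,
                                    coverage = comp$coverage,
                                    clipped = comp$clipped),
                 quality = inj$mask, spec = spec, seed = spec$seed),
            class = "bic_dataset")
}

#' @export
print.bic_dataset <- function(x, ...) {
  cat(sprintf("Synthetic biclustering benchmark: %d x %d %s matrix, %d planted bicluster(s)\n",
              nrow(x$data), ncol(x$data), x$spec$data_type,
              length(x$biclusters)))
  cat(sprintf("  plaid mode: %s | seed: %d\n", x$composition$mode, x$seed))
  nm <- length(x$quality$missing); nn <- length(x$quality$noisy)
  ne <- length(x$quality$error)
  if (nm + nn + ne > 0)
    cat(sprintf("  quality: %d missing, %d noisy, %d erroneous cells (threshold %g)\n",
                nm, nn, ne, x$quality$noise_threshold))
  invisible(x)
}

#' @export
summary.bic_dataset <- function(object, ...) {
  x <- object
  print(x)
  cat("\nPlanted biclusters:\n")
  for (b in x$solution$biclusters)
    cat(sprintf("  #%d: %dx%d (%s/%s) rows [%d..%d] cols [%d..%d]%s\n",
                b$id, b$n_rows, b$n_cols, b$row_coherency, b$col_coherency,
                min(b$rows), max(b$rows), min(b$cols), max(b$cols),
                if (b$time_profile != "none") paste0(" ", b$time_profile) else ""))
  covered <- sum(x$composition$coverage > 0)
  cat(sprintf("\nCoverage: %d / %d cells (%.1f%%) inside biclusters\n",
              covered, length(x$data), 100 * covered / length(x$data)))
  invisible(x)
}
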