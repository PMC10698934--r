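#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

COHERENCIES <- c("constant", "additive", "multiplicative", "order-preserving", "none")
TIME_PROFILES <- c("monotonically-increasing", "monotonically-decreasing", "random", "none")
PLAID_MODES <- c("additive", "multiplicative", "interpoled", "none", "no-overlap")

# Legal (row, column) coherency pairs and the alphabets they admit.
LEGAL_PATTERNS <- data.frame(
  rows = c("order-preserving", "none",
           "constant", "none", "constant",
           "additive", "constant", "additive",
           "multiplicative", "constant", "multiplicative"),
  cols = c("none", "order-preserving",
           "constant", "constant", "none",
           "additive", "additive", "constant",
           "multiplicative", "multiplicative", "constant"),
  numeric_only = c(FALSE, FALSE,
                   FALSE, FALSE, FALSE,
                   TRUE, TRUE, TRUE,
                   TRUE, TRUE, TRUE),
  stringsAsFactors = FALSE
)

#' Define the value domain of a dataset's attributes
#'
#' An alphabet is either a numeric interval (real or integer valued) or an
#' ordered list of symbols. Symbolic alphabets are ordered: rank distance in
#' the symbol list is used both by order-preserving patterns and by symbolic
#' noise/error injection.
#'
#' @param kind one of `"numeric-real"`, `"numeric-integer"`, `"symbolic"`.
#' @param min,max numeric bounds (numeric kinds only), `min < max`.
#' @param symbols character vector of distinct tokens (symbolic only).
#' @param symbol_probabilities optional probability vector over `symbols`,
#'   used by the discrete background; must be non-negative and sum to 1.
#' @return an object of class `bic_alphabet`.
#' @examples
#' alphabet_spec("numeric-real", min = -100, max = 100)
#' alphabet_spec("symbolic", symbols = letters[1:5])
#' @export
alphabet_spec <- function(kind = c("numeric-real", "numeric-integer", "symbolic"),
                          min = NULL, max = NULL, symbols = NULL,
                          symbol_probabilities = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, min = min, max = max, symbols = symbols,
                 symbol_probabilities = symbol_probabilities),
            class = "bic_alphabet")
}

#' Background distribution of a dataset
#'
#' The background generates every cell not covered by a planted bicluster:
#' `uniform` over the alphabet, `normal` (numeric alphabets; values are
#' clipped to the alphabet range, integers rounded), `discrete` (symbols
#' drawn with the alphabet's `symbol_probabilities`), or `missing` (a null
#' background: every cell is the missing marker).
#'
#' @param kind one of `"uniform"`, `"normal"`, `"discrete"`, `"missing"`.
#' @param mean,sd Gaussian parameters (`kind = "normal"` only), `sd > 0`.
#' @return an object of class `bic_background`.
#' @export
background_spec <- function(kind = c("uniform", "normal", "discrete", "missing"),
                            mean = NULL, sd = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, mean = mean, sd = sd), class = "bic_background")
}

#' Distribution of bicluster row or column counts
#'
#' @param kind `"fixed"`, `"uniform"` (integer-uniform on `[low, high]`) or
#'   `"normal"` (draws rounded to the nearest integer). Realized sizes are
#'   clamped to `[1, dataset dimension]`.
#' @param value fixed size (`kind = "fixed"`).
#' @param low,high inclusive bounds (`kind = "uniform"`), `low <= high`.
#' @param mean,sd Gaussian parameters (`kind = "normal"`).
#' @return an object of class `bic_sizedist`.
#' @examples
#' size_dist("uniform", low = 3, high = 12)
#' size_dist("fixed", value = 50)
#' @export
size_dist <- function(kind = c("fixed", "uniform", "normal"),
                      value = NULL, low = NULL, high = NULL,
                      mean = NULL, sd = NULL) {
  kind <- match.arg(kind)
  structure(list(kind = kind, value = value, low = low, high = high,
                 mean = mean, sd = sd), class = "bic_sizedist")
}

#' Coherency pattern of a planted bicluster
#'
#' The coherency named on a dimension describes how values change along that
#' dimension. `constant`/`constant` gives `b_ij = mu`; `none`/`constant`
#' gives `b_ij = alpha_i` (flat across columns, free across rows);
#' additive combinations give `b_ij = mu + alpha_i + beta_j` (with the
#' factor for a `constant` dimension fixed at 0), multiplicative
#' `b_ij = mu * alpha_i * beta_j` (constant dimension factor 1).
#' Order-preserving on the column side means one shared column permutation
#' sorts every row ascending; on the row side, transposed. Additive and
#' multiplicative coherencies require a numeric alphabet.
#'
#' @param rows,cols row/column coherency; one of `"constant"`, `"additive"`,
#'   `"multiplicative"`, `"order-preserving"`, `"none"`.
#' @param time_profile only for column-side order-preserving patterns on
#'   contiguous (time-series) biclusters: `"monotonically-increasing"`,
#'   `"monotonically-decreasing"`, `"random"`, or `"none"`.
#' @return an object of class `bic_pattern`.
#' @export
pattern_spec <- function(rows = "constant", cols = "constant",
                         time_profile = "none") {
  structure(list(rows = rows, cols = cols, time_profile = time_profile),
            class = "bic_pattern")
}

#' Overlap plan between planted biclusters
#'
#' Controls how many biclusters overlap, how strongly, and how overlapping
#' contributions combine (the plaid coherency). With `plaid = "no-overlap"`
#' every bicluster is placed cell-disjoint from every other and all other
#' fields are ignored.
#'
#' @param plaid plaid coherency: `"additive"`, `"multiplicative"`,
#'   `"interpoled"` (average of covering biclusters), `"none"`
#'   (last-generated bicluster wins) or `"no-overlap"`.
#' @param pct_biclusters percentage of biclusters placed in overlap groups.
#' @param max_interactions maximum biclusters sharing a single cell (>= 2).
#' @param pct_rows,pct_cols percentage of rows/columns shared between
#'   consecutive biclusters of a group, taken relative to the smaller one.
#' @param pct_elements cap on shared cells between consecutive biclusters,
#'   as a percentage of the smaller bicluster's area.
#' @return an object of class `bic_overlap`.
#' @export
overlap_spec <- function(plaid = "no-overlap", pct_biclusters = 0,
                         max_interactions = 2, pct_rows = 0, pct_cols = 0,
                         pct_elements = 100) {
  structure(list(plaid = plaid, pct_biclusters = pct_biclusters,
                 max_interactions = max_interactions, pct_rows = pct_rows,
                 pct_cols = pct_cols, pct_elements = pct_elements),
            class = "bic_overlap")
}

#' Data-quality degradation plan
#'
#' Missing values, noise and errors are injected independently into the
#' background and into the planted biclusters. For numeric alphabets the
#' noise threshold `delta` separates the two perturbation classes: a noisy
#' cell is shifted by `0 < |u| <= delta`, an erroneous cell by `|e| > delta`
#' (clipped to the alphabet range). For symbolic alphabets noise replaces a
#' symbol by an adjacent-rank symbol and an error by a symbol at rank
#' distance >= 2.
#'
#' @param pct_missing_background,pct_missing_biclusters percentage of region
#'   cells set to the missing marker.
#' @param pct_noise_background,pct_noise_biclusters percentage of region
#'   cells perturbed within the noise threshold.
#' @param pct_error_background,pct_error_biclusters percentage of region
#'   cells perturbed beyond the noise threshold.
#' @param noise_threshold non-negative deviation bound `delta` (numeric
#'   alphabets).
#' @return an object of class `bic_quality`.
#' @export
quality_spec <- function(pct_missing_background = 0, pct_missing_biclusters = 0,
                         pct_noise_background = 0, pct_noise_biclusters = 0,
                         pct_error_background = 0, pct_error_biclusters = 0,
                         noise_threshold = 0) {
  structure(list(pct_missing_background = pct_missing_background,
                 pct_missing_biclusters = pct_missing_biclusters,
                 pct_noise_background = pct_noise_background,
                 pct_noise_biclusters = pct_noise_biclusters,
                 pct_error_background = pct_error_background,
                 pct_error_biclusters = pct_error_biclusters,
                 noise_threshold = noise_threshold),
            class = "bic_quality")
}

#' Full parameter set of one generation run
#'
#' Collects every knob of a benchmark generation run: dataset shape and
#' alphabet(s), background, number/size/contiguity of planted biclusters,
#' their coherency patterns, the overlap plan, the quality plan and the
#' random seed. Heterogeneous datasets carry one numeric and one symbolic
#' alphabet, applied per column type.
#'
#' @param n_rows,n_cols dataset dimensions (positive integers).
#' @param data_type `"numeric"`, `"symbolic"` or `"heterogeneous"`.
#' @param alphabet a [alphabet_spec()]; the numeric alphabet for
#'   heterogeneous data.
#' @param symbolic_alphabet symbolic [alphabet_spec()] (heterogeneous only).
#' @param pct_numeric_columns percentage of numeric columns (heterogeneous
#'   only).
#' @param background a [background_spec()].
#' @param n_biclusters number of planted biclusters.
#' @param row_size,col_size [size_dist()] objects.
#' @param contiguity logical; if `TRUE` every bicluster's columns form a run
#'   of consecutive indices (C-biclusters for time-series data).
#' @param patterns a [pattern_spec()] or a list of them; a list is assigned
#'   round-robin across biclusters.
#' @param overlap an [overlap_spec()].
#' @param quality a [quality_spec()].
#' @param seed integer seed governing all randomness of the run.
#' @param relax_placement logical; if `TRUE`, a bicluster that cannot be
#'   placed without unplanned overlap (over-packed configurations) is placed
#'   anyway instead of aborting.
#' @return an object of class `bic_spec` (not yet validated; see
#'   [validate_spec()]).
#' @seealso [preset_spec()] for ready-made configurations,
#'   [generate_dataset()] to run the generator.
#' @examples
#' sp <- generator_spec(100, 100,
#'   alphabet = alphabet_spec("numeric-real", min = -100, max = 100),
#'   background = background_spec("normal", mean = 0, sd = 30),
#'   n_biclusters = 1,
#'   row_size = size_dist("fixed", value = 50),
#'   col_size = size_dist("fixed", value = 50))
#' validate_spec(sp)
#' @export
generator_spec <- function(n_rows, n_cols,
                           data_type = c("numeric", "symbolic", "heterogeneous"),
                           alphabet = alphabet_spec("numeric-real", min = -100, max = 100),
                           symbolic_alphabet = NULL,
                           pct_numeric_columns = NULL,
                           background = background_spec("uniform"),
                           n_biclusters = 1,
                           row_size = size_dist("fixed", value = 50),
                           col_size = size_dist("fixed", value = 50),
                           contiguity = FALSE,
                           patterns = pattern_spec("constant", "constant"),
                           overlap = overlap_spec("no-overlap"),
                           quality = quality_spec(),
                           seed = 1L,
                           relax_placement = FALSE) {
  data_type <- match.arg(data_type)
  if (inherits(patterns, "bic_pattern")) patterns <- list(patterns)
  structure(list(n_rows = n_rows, n_cols = n_cols, data_type = data_type,
                 alphabet = alphabet, symbolic_alphabet = symbolic_alphabet,
                 pct_numeric_columns = pct_numeric_columns,
                 background = background, n_biclusters = n_biclusters,
                 row_size = row_size, col_size = col_size,
                 contiguity = contiguity, patterns = patterns,
                 overlap = overlap, quality = quality,
                 seed = as.integer(seed), relax_placement = relax_placement),
            class = "bic_spec")
}

is_pct <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 100

check_alphabet <- function(a, path) {
  v <- character(0)
  if (!inherits(a, "bic_alphabet")) return(paste0(path, ": not an alphabet_spec"))
  if (a$kind %in% c("numeric-real", "numeric-integer")) {
    if (!is.numeric(a$min) || !is.numeric(a$max))
      v <- c(v, paste0(path, ": numeric alphabet requires min and max"))
    else if (!(a$min < a$max))
      v <- c(v, paste0(path, ": min must be < max"))
  } else {
    if (length(a$symbols) == 0)
      v <- c(v, paste0(path, ": symbolic alphabet requires a non-empty symbol list"))
    else if (anyDuplicated(a$symbols))
      v <- c(v, paste0(path, ": symbols must be distinct"))
    if (!is.null(a$symbol_probabilities)) {
      p <- a$symbol_probabilities
      if (length(p) != length(a$symbols) || any(p < 0) || abs(sum(p) - 1) > 1e-8)
        v <- c(v, paste0(path, ".symbol_probabilities: must be non-negative, ",
                         "match the symbol count, and sum to 1"))
    }
  }
  v
}

check_sizedist <- function(s, path, dim_size) {
  v <- character(0)
  if (!inherits(s, "bic_sizedist")) return(paste0(path, ": not a size_dist"))
  if (s$kind == "fixed") {
    if (!is.numeric(s$value) || s$value < 1)
      v <- c(v, paste0(path, ".value: must be a positive size"))
    else if (s$value > dim_size)
      v <- c(v, paste0(path, ".value: fixed size ", s$value,
                       " exceeds dataset dimension ", dim_size))
  } else if (s$kind == "uniform") {
    if (!is.numeric(s$low) || !is.numeric(s$high) || s$low > s$high)
      v <- c(v, paste0(path, ": requires low <= high"))
    else if (s$low > dim_size)
      v <- c(v, paste0(path, ".low: exceeds dataset dimension ", dim_size))
  } else {
    if (!is.numeric(s$mean) || !is.numeric(s$sd) || s$sd < 0)
      v <- c(v, paste0(path, ": requires mean and sd >= 0"))
  }
  v
}

pattern_is_legal <- function(p) {
  any(LEGAL_PATTERNS$rows == p$rows & LEGAL_PATTERNS$cols == p$cols)
}

pattern_numeric_only <- function(p) {
  hit <- LEGAL_PATTERNS$rows == p$rows & LEGAL_PATTERNS$cols == p$cols
  any(LEGAL_PATTERNS$numeric_only[hit])
}

check_pattern <- function(p, path, spec) {
  v <- character(0)
  if (!inherits(p, "bic_pattern")) return(paste0(path, ": not a pattern_spec"))
  if (!(p$rows %in% COHERENCIES) || !(p$cols %in% COHERENCIES)) {
    return(paste0(path, ": unknown coherency (", p$rows, ", ", p$cols, ")"))
  }
  if (!pattern_is_legal(p))
    v <- c(v, paste0(path, ": (", p$rows, ", ", p$cols,
                     ") is not a legal row/column coherency combination"))
  if (pattern_numeric_only(p) && spec$data_type == "symbolic")
    v <- c(v, paste0(path, ": ", p$rows, "/", p$cols,
                     " coherency requires a numeric alphabet"))
  if (!(p$time_profile %in% TIME_PROFILES))
    v <- c(v, paste0(path, ".time_profile: unknown profile '", p$time_profile, "'"))
  else if (p$time_profile != "none") {
    if (p$cols != "order-preserving")
      v <- c(v, paste0(path, ".time_profile: requires column-side ",
                       "order-preserving coherency"))
    if (!isTRUE(spec$contiguity))
      v <- c(v, paste0(path, ".time_profile: requires contiguity = TRUE"))
  }
  v
}

#' List every invariant violated by a generator spec
#'
#' Structural problems are reported all at once (one message per violated
#' invariant, each naming the offending field), not first-failure.
#'
#' @param spec a [generator_spec()].
#' @return a character vector of violation messages; empty when the spec is
#'   valid.
#' @export
spec_violations <- function(spec) {
  v <- character(0)
  if (!inherits(spec, "bic_spec")) return("not a generator_spec object")
  num1 <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x)
  if (!num1(spec$n_rows) || spec$n_rows < 1) v <- c(v, "n_rows: must be a positive integer")
  if (!num1(spec$n_cols) || spec$n_cols < 1) v <- c(v, "n_cols: must be a positive integer")
  if (!num1(spec$n_biclusters) || spec$n_biclusters < 1)
    v <- c(v, "n_biclusters: must be a positive integer")
  if (isTRUE(spec$contiguity) && spec$data_type == "heterogeneous")
    v <- c(v, "contiguity: contiguous column runs are not supported on heterogeneous data")

  # alphabets vs data type
  if (spec$data_type == "numeric") {
    if (!spec$alphabet$kind %in% c("numeric-real", "numeric-integer"))
      v <- c(v, "alphabet: numeric data_type requires a numeric alphabet")
    v <- c(v, check_alphabet(spec$alphabet, "alphabet"))
  } else if (spec$data_type == "symbolic") {
    if (spec$alphabet$kind != "symbolic")
      v <- c(v, "alphabet: symbolic data_type requires a symbolic alphabet")
    v <- c(v, check_alphabet(spec$alphabet, "alphabet"))
  } else { # heterogeneous
    if (!spec$alphabet$kind %in% c("numeric-real", "numeric-integer"))
      v <- c(v, "alphabet: heterogeneous data requires a numeric alphabet here")
    else v <- c(v, check_alphabet(spec$alphabet, "alphabet"))
    if (is.null(spec$symbolic_alphabet) ||
        !inherits(spec$symbolic_alphabet, "bic_alphabet") ||
        spec$symbolic_alphabet$kind != "symbolic")
      v <- c(v, "symbolic_alphabet: heterogeneous data requires a symbolic alphabet")
    else v <- c(v, check_alphabet(spec$symbolic_alphabet, "symbolic_alphabet"))
    if (!is_pct(spec$pct_numeric_columns %||% NA))
      v <- c(v, "pct_numeric_columns: heterogeneous data requires a percentage in [0,100]")
  }

  # background
  bg <- spec$background
  if (!inherits(bg, "bic_background")) {
    v <- c(v, "background: not a background_spec")
  } else {
    if (bg$kind == "normal") {
      if (spec$data_type != "numeric")
        v <- c(v, "background: normal background is rejected on symbolic columns")
      if (!is.numeric(bg$mean) || !is.numeric(bg$sd) || !(bg$sd > 0))
        v <- c(v, "background: normal background requires mean and sd > 0")
    }
    if (bg$kind == "discrete") {
      symb <- if (spec$data_type == "heterogeneous") spec$symbolic_alphabet else spec$alphabet
      if (is.null(symb) || !identical(symb$kind, "symbolic") ||
          is.null(symb$symbol_probabilities))
        v <- c(v, "background: discrete background requires a symbolic alphabet with symbol_probabilities")
    }
  }

  v <- c(v, check_sizedist(spec$row_size, "row_size", spec$n_rows))
  v <- c(v, check_sizedist(spec$col_size, "col_size", spec$n_cols))

  # patterns
  if (!is.list(spec$patterns) || length(spec$patterns) == 0) {
    v <- c(v, "patterns: must be a pattern_spec or non-empty list of them")
  } else {
    for (k in seq_along(spec$patterns))
      v <- c(v, check_pattern(spec$patterns[[k]], paste0("patterns[", k, "]"), spec))
  }

  # overlap
  ov <- spec$overlap
  if (!inherits(ov, "bic_overlap")) {
    v <- c(v, "overlap: not an overlap_spec")
  } else if (ov$plaid != "no-overlap") {
    if (!(ov$plaid %in% PLAID_MODES))
      v <- c(v, paste0("overlap.plaid: unknown plaid coherency '", ov$plaid, "'"))
    for (f in c("pct_biclusters", "pct_rows", "pct_cols", "pct_elements"))
      if (!is_pct(ov[[f]]))
        v <- c(v, paste0("overlap.", f, ": percentage must be in [0,100]"))
    if (!num1(ov$max_interactions) || ov$max_interactions < 2)
      v <- c(v, "overlap.max_interactions: must be an integer >= 2")
    if (ov$plaid %in% c("additive", "multiplicative", "interpoled") &&
        spec$data_type != "numeric")
      v <- c(v, "overlap.plaid: arithmetic plaid coherency on symbolic overlap regions is rejected (use 'none')")
  }

  # quality
  q <- spec$quality
  if (!inherits(q, "bic_quality")) {
    v <- c(v, "quality: not a quality_spec")
  } else {
    for (f in c("pct_missing_background", "pct_missing_biclusters",
                "pct_noise_background", "pct_noise_biclusters",
                "pct_error_background", "pct_error_biclusters"))
      if (!is_pct(q[[f]]))
        v <- c(v, paste0("quality.", f, ": percentage must be in [0,100]"))
    if (is_pct(q$pct_missing_background %||% NA) && is_pct(q$pct_noise_background %||% NA) &&
        is_pct(q$pct_error_background %||% NA) &&
        q$pct_missing_background + q$pct_noise_background + q$pct_error_background > 100)
      v <- c(v, "quality: background missing + noise + error percentages exceed 100")
    if (is_pct(q$pct_missing_biclusters %||% NA) && is_pct(q$pct_noise_biclusters %||% NA) &&
        is_pct(q$pct_error_biclusters %||% NA) &&
        q$pct_missing_biclusters + q$pct_noise_biclusters + q$pct_error_biclusters > 100)
      v <- c(v, "quality: bicluster missing + noise + error percentages exceed 100")
    if (!is.numeric(q$noise_threshold) || q$noise_threshold < 0)
      v <- c(v, "quality.noise_threshold: must be a non-negative number")
    numeric_data <- spec$data_type != "symbolic"
    noise_req <- (is_pct(q$pct_noise_background %||% NA) && q$pct_noise_background > 0) ||
      (is_pct(q$pct_noise_biclusters %||% NA) && q$pct_noise_biclusters > 0)
    error_req <- (is_pct(q$pct_error_background %||% NA) && q$pct_error_background > 0) ||
      (is_pct(q$pct_error_biclusters %||% NA) && q$pct_error_biclusters > 0)
    if (numeric_data && is.numeric(q$noise_threshold) && q$noise_threshold == 0 && noise_req)
      v <- c(v, "quality.noise_threshold: noise requested but threshold is 0 (no non-zero |u| <= 0 exists)")
    if (numeric_data && noise_req && is.numeric(q$noise_threshold) && q$noise_threshold < 1 &&
        q$noise_threshold > 0 && identical(spec$alphabet$kind, "numeric-integer"))
      v <- c(v, "quality.noise_threshold: integer-alphabet noise requires a threshold >= 1")
    if (numeric_data && error_req && is.numeric(q$noise_threshold) &&
        inherits(spec$alphabet, "bic_alphabet") && is.numeric(spec$alphabet$min) &&
        is.numeric(spec$alphabet$max) &&
        q$noise_threshold >= (spec$alphabet$max - spec$alphabet$min) / 2)
      v <- c(v, "quality.noise_threshold: errors require a threshold below half the alphabet span")
    if (spec$data_type == "symbolic" && inherits(spec$alphabet, "bic_alphabet")) {
      ns <- length(spec$alphabet$symbols)
      if (ns < 2 && ((q$pct_noise_background %||% 0) > 0 || (q$pct_noise_biclusters %||% 0) > 0))
        v <- c(v, "quality: symbolic noise requires at least 2 symbols")
      if (ns < 3 && ((q$pct_error_background %||% 0) > 0 || (q$pct_error_biclusters %||% 0) > 0))
        v <- c(v, "quality: symbolic errors require at least 3 symbols")
    }
  }

  if (!num1(spec$seed)) v <- c(v, "seed: must be a single integer")
  v
}

#' Validate and normalize a generator spec
#'
#' Checks every invariant of the configuration (alphabet bounds, legal
#' row/column coherency combinations, percentage ranges, per-region quality
#' budgets, plaid legality on symbolic data, ...). All violations are
#' collected and reported together.
#'
#' @param spec a [generator_spec()].
#' @return the normalized spec, invisibly classed `bic_spec`; on failure an
#'   error listing every violated invariant with its field path.
#' @export
validate_spec <- function(spec) {
  v <- spec_violations(spec)
  if (length(v) > 0)
    stop("invalid generator spec:\n", paste0("  - ", v, collapse = "\n"), call. = FALSE)
  spec$n_rows <- as.integer(spec$n_rows)
  spec$n_cols <- as.integer(spec$n_cols)
  spec$n_biclusters <- as.integer(spec$n_biclusters)
  spec
}

#' @export
print.bic_spec <- function(x, ...) {
  cat("Bicluster benchmark generator spec\n")
  cat(sprintf("  dataset:    %d x %d (%s)\n", x$n_rows, x$n_cols, x$data_type))
  a <- x$alphabet
  if (a$kind == "symbolic") {
    cat(sprintf("  alphabet:   {%s}\n", paste(a$symbols, collapse = ",")))
  } else {
    cat(sprintf("  alphabet:   [%g, %g] (%s)\n", a$min, a$max, a$kind))
  }
  if (!is.null(x$symbolic_alphabet))
    cat(sprintf("  symbolic:   {%s} (%g%% numeric columns)\n",
                paste(x$symbolic_alphabet$symbols, collapse = ","),
                x$pct_numeric_columns))
  cat(sprintf("  background: %s\n", x$background$kind))
  pat <- vapply(x$patterns, function(p) paste0(p$rows, "/", p$cols), "")
  cat(sprintf("  biclusters: %d, patterns %s%s\n", x$n_biclusters,
              paste(unique(pat), collapse = " + "),
              if (isTRUE(x$contiguity)) ", contiguous" else ""))
  cat(sprintf("  overlap:    %s\n", x$overlap$plaid))
  cat(sprintf("  seed:       %d\n", x$seed))
  invisible(x)
}
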