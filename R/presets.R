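PRESET_NAMES <- c("illustrative-1", "illustrative-2", "illustrative-3",
                  "baseline-R", "baseline-S", "baseline-B", "baseline-I",
                  "baseline-C", "baseline-H",
                  "sim-geneexpr", "sim-recsys", "sim-textmining",
                  "sim-clinical", "sim-spatiotemporal",
                  "dlblc-mimic")

real100 <- function() alphabet_spec("numeric-real", min = -100, max = 100)
abcde <- function() alphabet_spec("symbolic", symbols = c("a", "b", "c", "d", "e"))

#' Names of the shipped preset configurations
#'
#' @return character vector of preset names accepted by [preset_spec()].
#' @export
list_presets <- function() PRESET_NAMES

#' Ready-made benchmark generator configurations
#'
#' Returns a validated [generator_spec()] for one of the shipped scenarios:
#'
#' * `illustrative-1/2/3` — small didactic datasets (100x100, N(0,30)
#'   background on \[-100,100\]): a single 50x50 constant bicluster; two
#'   fully-overlapping 50x50 constant biclusters composed with the additive
#'   plaid; ten contiguous order-preserving biclusters with a monotonically
#'   decreasing time profile.
#' * `baseline-R/S/B/I/C/H` — 1000x100 single-bicluster baselines per data
#'   type: Real-valued, Symbolic, Binary, Integer, Contiguous, and
#'   Heterogeneous (50% real / 50% symbolic).
#' * `sim-geneexpr`, `sim-recsys`, `sim-textmining`, `sim-clinical`,
#'   `sim-spatiotemporal` — domain-mimicking configurations (microarray
#'   expression, ratings, term-document, clinical records, fMRI windows).
#'   The two largest (`sim-recsys`, `sim-textmining`) describe matrices far
#'   beyond interactive scale; they validate and serialize but are intended
#'   as documentation of the published settings rather than for direct
#'   generation.
#' * `dlblc-mimic` — a 660x180 expression-like matrix with 52 planted
#'   constant-row biclusters of 4 columns each, N(0,45) background, 40%
#'   bicluster noise under threshold 9 and 10% bicluster errors. The quality
#'   figures in the source table are typeset ambiguously; this preset fixes
#'   one reading (noise deviation 9, bicluster errors 10%, background
#'   clean), which is an interpretation, not a reported fact.
#'
#' @param name one of [list_presets()].
#' @param seed integer seed stored in the returned spec.
#' @return a validated `bic_spec`.
#' @examples
#' preset_spec("illustrative-1")
#' @export
preset_spec <- function(name, seed = 1L) {
  if (!is.character(name) || length(name) != 1 || !(name %in% PRESET_NAMES))
    stop("unknown preset '", paste(name, collapse = ","), "'; available presets: ",
         paste(PRESET_NAMES, collapse = ", "), call. = FALSE)
  spec <- switch(name,
    "illustrative-1" = generator_spec(
      100, 100, alphabet = real100(),
      background = background_spec("normal", mean = 0, sd = 30),
      n_biclusters = 1,
      row_size = size_dist("fixed", value = 50),
      col_size = size_dist("fixed", value = 50),
      patterns = pattern_spec("constant", "constant"),
      seed = seed),
    "illustrative-2" = generator_spec(
      100, 100, alphabet = real100(),
      background = background_spec("normal", mean = 0, sd = 30),
      n_biclusters = 2,
      row_size = size_dist("fixed", value = 50),
      col_size = size_dist("fixed", value = 50),
      patterns = pattern_spec("constant", "constant"),
      overlap = overlap_spec("additive", pct_biclusters = 100,
                             max_interactions = 2, pct_rows = 50,
                             pct_cols = 50, pct_elements = 50),
      seed = seed),
    "illustrative-3" = generator_spec(
      100, 100, alphabet = real100(),
      background = background_spec("normal", mean = 0, sd = 30),
      n_biclusters = 10,
      row_size = size_dist("uniform", low = 3, high = 12),
      col_size = size_dist("uniform", low = 10, high = 20),
      contiguity = TRUE,
      patterns = pattern_spec("none", "order-preserving",
                              time_profile = "monotonically-decreasing"),
      seed = seed),
    "baseline-R" = generator_spec(
      1000, 100, alphabet = real100(),
      background = background_spec("normal", mean = 0, sd = 30),
      n_biclusters = 1,
      row_size = size_dist("fixed", value = 50),
      col_size = size_dist("fixed", value = 50),
      seed = seed),
    "baseline-S" = generator_spec(
      1000, 100, data_type = "symbolic", alphabet = abcde(),
      background = background_spec("missing"),
      n_biclusters = 1,
      row_size = size_dist("fixed", value = 50),
      col_size = size_dist("fixed", value = 50),
      seed = seed),
    "baseline-B" = generator_spec(
      1000, 100, alphabet = alphabet_spec("numeric-integer", min = 0, max = 1),
      background = background_spec("missing"),
      n_biclusters = 1,
      row_size = size_dist("fixed", value = 50),
      col_size = size_dist("fixed", value = 50),
      seed = seed),
    "baseline-I" = generator_spec(
      1000, 100, alphabet = alphabet_spec("numeric-integer", min = 0, max = 100),
      background = background_spec("uniform"),
      n_biclusters = 1,
      row_size = size_dist("fixed", value = 50),
      col_size = size_dist("fixed", value = 50),
      seed = seed),
    "baseline-C" = generator_spec(
      1000, 100, alphabet = real100(),
      background = background_spec("uniform"),
      n_biclusters = 1,
      row_size = size_dist("fixed", value = 50),
      col_size = size_dist("fixed", value = 50),
      contiguity = TRUE,
      seed = seed),
    "baseline-H" = generator_spec(
      1000, 100, data_type = "heterogeneous", alphabet = real100(),
      symbolic_alphabet = abcde(), pct_numeric_columns = 50,
      background = background_spec("missing"),
      n_biclusters = 1,
      row_size = size_dist("fixed", value = 50),
      col_size = size_dist("fixed", value = 50),
      seed = seed),
    "sim-geneexpr" = generator_spec(
      10000, 100, alphabet = real100(),
      background = background_spec("normal", mean = 0, sd = 30),
      n_biclusters = 500,
      row_size = size_dist("uniform", low = 80, high = 400),
      col_size = size_dist("uniform", low = 20, high = 40),
      patterns = list(pattern_spec("additive", "additive"),
                      pattern_spec("none", "order-preserving")),
      overlap = overlap_spec("additive", pct_biclusters = 10,
                             max_interactions = 2, pct_rows = 25,
                             pct_cols = 25, pct_elements = 100),
      quality = quality_spec(pct_noise_background = 10, noise_threshold = 10),
      relax_placement = TRUE,
      seed = seed),
    "sim-recsys" = generator_spec(
      200000, 30000, alphabet = alphabet_spec("numeric-integer", min = 1, max = 5),
      background = background_spec("uniform"),
      n_biclusters = 3000,
      row_size = size_dist("uniform", low = 30, high = 70),
      col_size = size_dist("uniform", low = 3, high = 7),
      patterns = pattern_spec("none", "order-preserving"),
      quality = quality_spec(pct_missing_background = 95.5),
      relax_placement = TRUE,
      seed = seed),
    "sim-textmining" = generator_spec(
      30000, 20000, alphabet = alphabet_spec("numeric-integer", min = 0, max = 100),
      background = background_spec("uniform"),
      n_biclusters = 70,
      row_size = size_dist("uniform", low = 1000, high = 10000),
      col_size = size_dist("uniform", low = 600, high = 6000),
      patterns = list(pattern_spec("constant", "constant"),
                      pattern_spec("none", "order-preserving")),
      quality = quality_spec(pct_missing_background = 99.8),
      relax_placement = TRUE,
      seed = seed),
    "sim-clinical" = generator_spec(
      50000, 8000, data_type = "heterogeneous", alphabet = real100(),
      symbolic_alphabet = abcde(), pct_numeric_columns = 50,
      background = background_spec("uniform"),
      n_biclusters = 30,
      row_size = size_dist("uniform", low = 20, high = 100),
      col_size = size_dist("uniform", low = 5, high = 15),
      patterns = pattern_spec("none", "order-preserving"),
      quality = quality_spec(pct_missing_background = 99.8),
      seed = seed),
    "sim-spatiotemporal" = generator_spec(
      30, 150, alphabet = real100(),
      background = background_spec("uniform"),
      n_biclusters = 20,
      row_size = size_dist("uniform", low = 2, high = 4),
      col_size = size_dist("uniform", low = 7, high = 10),
      contiguity = TRUE,
      patterns = list(pattern_spec("additive", "additive"),
                      pattern_spec("multiplicative", "multiplicative")),
      quality = quality_spec(pct_noise_background = 50,
                             pct_error_background = 20,
                             noise_threshold = 10),
      relax_placement = TRUE,
      seed = seed),
    "dlblc-mimic" = generator_spec(
      660, 180, alphabet = real100(),
      background = background_spec("normal", mean = 0, sd = 45),
      n_biclusters = 52,
      row_size = size_dist("normal", mean = 73, sd = 3),
      col_size = size_dist("fixed", value = 4),
      patterns = pattern_spec("constant", "none"),
      overlap = overlap_spec("additive", pct_biclusters = 10,
                             max_interactions = 5, pct_rows = 10,
                             pct_cols = 10, pct_elements = 100),
      quality = quality_spec(pct_noise_biclusters = 40,
                             pct_error_biclusters = 10,
                             noise_threshold = 9),
      seed = seed)
  )
  validate_spec(spec)
}
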