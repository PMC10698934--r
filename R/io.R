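# Output bundle: dataset .tsv, solution/settings .json, human-readable
# .txt listing, plus parsers for the settings and solution documents.

SCHEMA_VERSION <- "1.0"

drop_null <- function(x) x[!vapply(x, is.null, TRUE)]

#' Serialize a generator spec to a plain list (settings document)
#'
#' The returned structure is the JSON settings dialect written by
#' [write_bundle()] and read back by [read_settings()];
#' `spec_from_list(spec_to_list(spec))` is the identity on validated specs.
#'
#' @param spec a validated [generator_spec()].
#' @return a nested plain list ready for JSON serialization.
#' @export
spec_to_list <- function(spec) {
  alpha_list <- function(a) if (is.null(a)) NULL else
    drop_null(list(kind = a$kind, min = a$min, max = a$max,
                   symbols = if (length(a$symbols)) as.list(a$symbols),
                   symbol_probabilities = a$symbol_probabilities))
  sd_list <- function(s) drop_null(list(kind = s$kind, value = s$value,
                                        low = s$low, high = s$high,
                                        mean = s$mean, sd = s$sd))
  drop_null(list(
    schema_version = SCHEMA_VERSION,
    n_rows = spec$n_rows, n_cols = spec$n_cols, data_type = spec$data_type,
    alphabet = alpha_list(spec$alphabet),
    symbolic_alphabet = alpha_list(spec$symbolic_alphabet),
    pct_numeric_columns = spec$pct_numeric_columns,
    background = drop_null(list(kind = spec$background$kind,
                                mean = spec$background$mean,
                                sd = spec$background$sd)),
    n_biclusters = spec$n_biclusters,
    row_size = sd_list(spec$row_size), col_size = sd_list(spec$col_size),
    contiguity = spec$contiguity,
    patterns = lapply(spec$patterns, function(p)
      list(rows = p$rows, cols = p$cols, time_profile = p$time_profile)),
    overlap = unclass(spec$overlap),
    quality = unclass(spec$quality),
    seed = spec$seed,
    relax_placement = spec$relax_placement))
}

sc <- function(x) if (is.null(x)) NULL else unlist(x)[1]

#' Rebuild a generator spec from its settings document
#'
#' @param x a list as produced by [spec_to_list()] (or parsed from the
#'   settings JSON).
#' @return a validated `bic_spec`.
#' @export
spec_from_list <- function(x) {
  alpha <- function(a) if (is.null(a)) NULL else
    alphabet_spec(sc(a$kind), min = sc(a$min), max = sc(a$max),
                  symbols = if (length(a$symbols)) as.character(unlist(a$symbols)),
                  symbol_probabilities = if (length(a$symbol_probabilities))
                    as.numeric(unlist(a$symbol_probabilities)))
  sdist <- function(s) size_dist(sc(s$kind), value = sc(s$value),
                                 low = sc(s$low), high = sc(s$high),
                                 mean = sc(s$mean), sd = sc(s$sd))
  pats <- x$patterns
  if (!is.null(pats$rows)) pats <- list(pats)   # single pattern object
  validate_spec(generator_spec(
    n_rows = sc(x$n_rows), n_cols = sc(x$n_cols), data_type = sc(x$data_type),
    alphabet = alpha(x$alphabet),
    symbolic_alphabet = alpha(x$symbolic_alphabet),
    pct_numeric_columns = sc(x$pct_numeric_columns),
    background = background_spec(sc(x$background$kind),
                                 mean = sc(x$background$mean),
                                 sd = sc(x$background$sd)),
    n_biclusters = sc(x$n_biclusters),
    row_size = sdist(x$row_size), col_size = sdist(x$col_size),
    contiguity = isTRUE(sc(x$contiguity)),
    patterns = lapply(pats, function(p)
      pattern_spec(sc(p$rows), sc(p$cols),
                   time_profile = sc(p$time_profile) %||% "none")),
    overlap = overlap_spec(sc(x$overlap$plaid) %||% "no-overlap",
                           pct_biclusters = sc(x$overlap$pct_biclusters) %||% 0,
                           max_interactions = sc(x$overlap$max_interactions) %||% 2,
                           pct_rows = sc(x$overlap$pct_rows) %||% 0,
                           pct_cols = sc(x$overlap$pct_cols) %||% 0,
                           pct_elements = sc(x$overlap$pct_elements) %||% 100),
    quality = quality_spec(
      pct_missing_background = sc(x$quality$pct_missing_background) %||% 0,
      pct_missing_biclusters = sc(x$quality$pct_missing_biclusters) %||% 0,
      pct_noise_background = sc(x$quality$pct_noise_background) %||% 0,
      pct_noise_biclusters = sc(x$quality$pct_noise_biclusters) %||% 0,
      pct_error_background = sc(x$quality$pct_error_background) %||% 0,
      pct_error_biclusters = sc(x$quality$pct_error_biclusters) %||% 0,
      noise_threshold = sc(x$quality$noise_threshold) %||% 0),
    seed = sc(x$seed),
    relax_placement = isTRUE(sc(x$relax_placement))))
}

dataset_lines <- function(data) {
  n <- nrow(data); m <- ncol(data)
  chr <- if (is.numeric(data)) {
    mm <- matrix(fmt_num(data), n, m)
    mm
  } else data
  chr[is.na(chr)] <- ""                    # empty field = missing
  header <- paste(c("", paste0("col_", seq_len(m) - 1)), collapse = "\t")
  body <- paste(paste0("row_", seq_len(n) - 1),
                apply(chr, 1, paste, collapse = "\t"), sep = "\t")
  c(header, body)
}

idx_to_rc0 <- function(idx, n) {
  if (length(idx) == 0) return(list())
  lapply(idx, function(i) c(((i - 1L) %% n), ((i - 1L) %/% n)))
}

solution_to_list <- function(sol) {
  list(
    dataset = list(n_rows = sol$n_rows, n_cols = sol$n_cols,
                   plaid_coherency = sol$plaid),
    biclusters = lapply(sol$biclusters, function(b) {
      vals <- b$values
      drop_null(list(
        id = b$id, n_rows = b$n_rows, n_cols = b$n_cols,
        rows = as.list(b$rows - 1L), cols = as.list(b$cols - 1L),
        values = lapply(seq_len(nrow(vals)), function(i) as.list(vals[i, ])),
        row_coherency = b$row_coherency, col_coherency = b$col_coherency,
        time_profile = b$time_profile, type = b$type,
        contiguous = b$contiguous,
        clipped_cells = idx_to_rc0(b$clipped_cells, sol$n_rows)))
    }),
    quality = if (is.null(sol$quality)) NULL else list(
      noise_threshold = sol$quality$noise_threshold,
      missing = idx_to_rc0(sol$quality$missing, sol$n_rows),
      noisy = idx_to_rc0(sol$quality$noisy, sol$n_rows),
      error = idx_to_rc0(sol$quality$error, sol$n_rows)))
}

listing_lines <- function(sol) {
  out <- character(0)
  for (b in sol$biclusters) {
    out <- c(out,
      sprintf("Bicluster #%d (%d rows x %d cols)", b$id, b$n_rows, b$n_cols),
      paste("Rows:", paste(b$rows - 1L, collapse = " ")),
      paste("Cols:", paste(b$cols - 1L, collapse = " ")),
      sprintf("Pattern: %s/%s (time profile: %s)", b$row_coherency,
              b$col_coherency, b$time_profile),
      "Values:",
      if (is.numeric(b$values))
        apply(matrix(fmt_num(b$values), b$n_rows, b$n_cols), 1, paste,
              collapse = "\t")
      else apply(b$values, 1, paste, collapse = "\t"),
      "")
  }
  out
}

#' Write the three-file benchmark bundle
#'
#' Emits the dataset as tab-separated values with `row_i`/`col_j` headers
#' and empty fields for missing cells (`<name>.tsv`), the machine-readable
#' settings + solution document (`<name>.json`), and a human-readable
#' bicluster listing (`<name>.txt`). Re-running the generator on the
#' emitted settings with the same seed reproduces the dataset byte for
#' byte.
#'
#' @param x a `bic_dataset` from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @param name file stem for the three files.
#' @return named character vector of the three paths (`tsv`, `json`,
#'   `txt`), invisibly.
#' @export
write_bundle <- function(x, dir, name = "dataset") {
  if (!inherits(x, "bic_dataset"))
    stop("write_bundle expects a bic_dataset", call. = FALSE)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop("cannot create output directory '", dir, "'", call. = FALSE)
  paths <- c(tsv = file.path(dir, paste0(name, ".tsv")),
             json = file.path(dir, paste0(name, ".json")),
             txt = file.path(dir, paste0(name, ".txt")))
  for (p in paths) {
    if (file.exists(p) && file.access(p, 2) != 0)
      stop("cannot write to '", p, "'", call. = FALSE)
  }
  writeLines(dataset_lines(x$data), paths[["tsv"]])
  doc <- c(list(schema_version = SCHEMA_VERSION,
                settings = spec_to_list(x$spec)),
           solution_to_list(x$solution))
  jsonlite::write_json(doc, paths[["json"]], auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  writeLines(listing_lines(x$solution), paths[["txt"]])
  invisible(paths)
}

fail_schema <- function(path_str) {
  stop("solution document schema violation: missing or malformed ",
       path_str, call. = FALSE)
}

rc0_to_idx <- function(pairs, n) {
  if (length(pairs) == 0) return(integer(0))
  vapply(pairs, function(p) {
    p <- unlist(p)
    as.integer(p[1] + 1 + p[2] * n)
  }, 1L)
}

#' Read a solution document
#'
#' Parses a `.json` bundle written by [write_bundle()] (or any
#' schema-conformant document) back into a ground-truth solution record.
#' Structural violations are reported with a path into the document.
#'
#' @param path path to the `.json` file.
#' @return a `bic_solution` object (1-based indices in memory).
#' @export
read_solution <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  doc <- tryCatch(jsonlite::read_json(path),
                  error = function(e) stop("malformed solution document '",
                                           path, "': ", conditionMessage(e),
                                           call. = FALSE))
  if (!is.null(doc$schema_version) &&
      !identical(as.character(doc$schema_version), SCHEMA_VERSION))
    stop("solution document schema version '", doc$schema_version,
         "' does not match supported version '", SCHEMA_VERSION, "'",
         call. = FALSE)
  if (is.null(doc$dataset)) fail_schema("$.dataset")
  n <- sc(doc$dataset$n_rows); m <- sc(doc$dataset$n_cols)
  if (is.null(n) || is.null(m)) fail_schema("$.dataset.n_rows/n_cols")
  if (is.null(doc$biclusters)) fail_schema("$.biclusters")
  recs <- lapply(seq_along(doc$biclusters), function(t) {
    b <- doc$biclusters[[t]]
    at <- function(f) paste0("$.biclusters[", t, "].", f)
    if (is.null(b$rows)) fail_schema(at("rows"))
    if (is.null(b$cols)) fail_schema(at("cols"))
    if (is.null(b$values)) fail_schema(at("values"))
    rows <- as.integer(unlist(b$rows)) + 1L
    cols <- as.integer(unlist(b$cols)) + 1L
    if (any(rows < 1) || any(rows > n) || any(cols < 1) || any(cols > m))
      fail_schema(paste0(at("rows/cols"), " (indices out of bounds)"))
    raw <- lapply(b$values, unlist)
    if (length(raw) != length(rows) ||
        any(vapply(raw, length, 1L) != length(cols)))
      fail_schema(paste0(at("values"), " (grid does not match rows x cols)"))
    vals <- do.call(rbind, raw)
    if (!any(is.na(suppressWarnings(as.numeric(vals)))) &&
        !identical(sc(b$type), "symbolic"))
      vals <- matrix(as.numeric(vals), nrow(vals), ncol(vals))
    list(id = sc(b$id) %||% t, rows = rows, cols = cols,
         n_rows = length(rows), n_cols = length(cols), values = vals,
         row_coherency = sc(b$row_coherency) %||% NA_character_,
         col_coherency = sc(b$col_coherency) %||% NA_character_,
         time_profile = sc(b$time_profile) %||% "none",
         type = sc(b$type) %||% "numeric",
         contiguous = isTRUE(sc(b$contiguous)),
         clipped_cells = rc0_to_idx(b$clipped_cells, n))
  })
  qual <- NULL
  if (!is.null(doc$quality)) {
    qual <- structure(list(missing = rc0_to_idx(doc$quality$missing, n),
                           noisy = rc0_to_idx(doc$quality$noisy, n),
                           error = rc0_to_idx(doc$quality$error, n),
                           noise_threshold = sc(doc$quality$noise_threshold) %||% 0,
                           region_counts = NULL),
                      class = "bic_qmask")
  }
  structure(list(n_rows = as.integer(n), n_cols = as.integer(m),
                 plaid = sc(doc$dataset$plaid_coherency) %||% "none",
                 biclusters = recs, quality = qual),
            class = "bic_solution")
}

#' Read a settings document back into a generator spec
#'
#' Accepts either a full bundle `.json` (whose `settings` block is used) or
#' a bare settings document; the result regenerates an identical dataset
#' under the same seed.
#'
#' @param path path to the `.json` file.
#' @return a validated `bic_spec`.
#' @export
read_settings <- function(path) {
  if (!file.exists(path)) stop("no such file: '", path, "'", call. = FALSE)
  doc <- jsonlite::read_json(path)
  if (!is.null(doc$settings)) doc <- doc$settings
  if (is.null(doc$n_rows))
    stop("settings document schema violation: missing $.n_rows", call. = FALSE)
  spec_from_list(doc)
}

#' Read a dataset TSV written by the bundle writer
#'
#' @param path path to the `.tsv` file.
#' @param numeric parse cells as numbers (default guesses from content).
#' @return a matrix with `NA` for empty (missing) fields.
#' @export
read_dataset_tsv <- function(path, numeric = NULL) {
  lines <- readLines(path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  m <- length(header) - 1
  cells <- strsplit(lines[-1], "\t", fixed = TRUE)
  mat <- t(vapply(cells, function(r) {
    r <- c(r, rep("", m + 1 - length(r)))[-1]
    r
  }, character(m)))
  mat[mat == ""] <- NA
  if (is.null(numeric))
    numeric <- !any(is.na(suppressWarnings(as.numeric(stats::na.omit(as.vector(mat))))))
  if (numeric) mat <- matrix(as.numeric(mat), nrow(mat), m)
  mat
}
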