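# Quality injection: missing values, within-threshold noise and
# beyond-threshold errors, applied to background and biclusters
# independently.

# noisy numeric cells: value + u with 0 < |u| <= delta, never leaving the
# alphabet range (direction flipped toward the interior when needed)
perturb_noise_numeric <- function(x, delta, amin, amax, integerish) {
  k <- length(x)
  out <- numeric(k)
  room_up <- amax - x
  room_dn <- x - amin
  up <- stats::runif(k) < 0.5
  up[room_up <= 0] <- FALSE
  up[room_dn <= 0] <- TRUE
  room <- ifelse(up, room_up, room_dn)
  if (integerish) {
    mag <- vapply(pmin(floor(delta), room),
                  function(r) as.numeric(resample(seq_len(max(1, r)), 1)),
                  numeric(1))
  } else {
    mag <- stats::runif(k, 0, pmin(delta, room))
    mag[mag == 0] <- pmin(delta, room)[mag == 0] / 2
  }
  out <- x + ifelse(up, mag, -mag)
  out
}

# erroneous numeric cells: value + e with |e| > delta after clipping; at
# least one direction always has room > delta when delta < span/2
perturb_error_numeric <- function(x, delta, amin, amax, integerish) {
  k <- length(x)
  room_up <- amax - x
  room_dn <- x - amin
  can_up <- room_up > delta
  can_dn <- room_dn > delta
  up <- stats::runif(k) < 0.5
  up[!can_dn] <- TRUE
  up[!can_up] <- FALSE
  room <- ifelse(up, room_up, room_dn)
  if (integerish) {
    lo <- floor(delta) + 1
    mag <- vapply(room, function(r) as.numeric(resample(seq(lo, max(lo, r)), 1)),
                  numeric(1))
  } else {
    mag <- stats::runif(k, delta, room)
    mag[mag <= delta] <- (delta + room[mag <= delta]) / 2
  }
  x + ifelse(up, mag, -mag)
}

perturb_symbolic <- function(sym, symbols, role) {
  ns <- length(symbols)
  r <- match(sym, symbols)
  vapply(r, function(ri) {
    cand <- if (role == "noise") {
      intersect(c(ri - 1, ri + 1), seq_len(ns))   # adjacent rank
    } else {
      setdiff(seq_len(ns), seq(max(1, ri - 1), min(ns, ri + 1)))  # rank distance >= 2
    }
    symbols[resample(cand, 1)]
  }, "")
}

#' Inject missing values, noise and errors
#'
#' Degrades the composed matrix per region (the background, then each
#' bicluster in index order; a cell shared by overlapping biclusters is
#' eligible once, charged to the first). In each region,
#' `round(pct/100 * region_size)` cells per role are drawn without
#' replacement, with mutually exclusive roles: missing cells become `NA`,
#' noisy numeric cells move by `0 < |u| <= delta`, erroneous numeric cells
#' by `|e| > delta` (clipped to the alphabet, direction chosen so the
#' deviation survives clipping). Symbolic noise replaces a symbol by an
#' adjacent-rank one; symbolic errors draw from ranks at distance >= 2.
#'
#' @param composition a [compose()] result (or plain matrix plus coverage).
#' @param bics list of `bic_def` objects (for region definitions).
#' @param quality a [quality_spec()].
#' @param alphabet numeric or symbolic [alphabet_spec()] of the dataset;
#'   for heterogeneous data the numeric alphabet.
#' @param column_types per-column types (heterogeneous data); `NULL` for
#'   homogeneous datasets.
#' @param symbolic_alphabet symbolic alphabet (heterogeneous data).
#' @return list with `values` (degraded matrix) and `mask`, an object of
#'   class `bic_qmask`: integer cell indices `missing`, `noisy`, `error`,
#'   the `noise_threshold`, and per-region counts.
#' @export
inject_quality <- function(composition, bics, quality, alphabet,
                           column_types = NULL, symbolic_alphabet = NULL) {
  values <- composition$values
  n <- nrow(values); m <- ncol(values)
  covered <- composition$coverage > 0L
  delta <- quality$noise_threshold

  regions <- list(list(name = "background", idx = which(!covered),
                       pm = quality$pct_missing_background,
                       pn = quality$pct_noise_background,
                       pe = quality$pct_error_background))
  claimed <- logical(n * m)
  for (t in seq_along(bics)) {
    idx <- cell_index(bics[[t]]$rows, bics[[t]]$cols, n)
    eligible <- idx[!claimed[idx]]
    claimed[idx] <- TRUE
    regions <- c(regions, list(list(name = paste0("bicluster_", t),
                                    idx = eligible,
                                    pm = quality$pct_missing_biclusters,
                                    pn = quality$pct_noise_biclusters,
                                    pe = quality$pct_error_biclusters)))
  }

  all_missing <- integer(0); all_noisy <- integer(0); all_error <- integer(0)
  counts <- data.frame(region = character(0), size = integer(0),
                       missing = integer(0), noisy = integer(0),
                       error = integer(0))
  numeric_data <- is.numeric(values)
  integerish <- !is.null(alphabet) && identical(alphabet$kind, "numeric-integer")

  perturb_cells <- function(idx, role) {
    if (length(idx) == 0) return(invisible(NULL))
    if (numeric_data) {
      x <- values[idx]
      fun <- if (role == "noise") perturb_noise_numeric else perturb_error_numeric
      values[idx] <<- fun(x, delta, alphabet$min, alphabet$max, integerish)
    } else if (is.null(column_types)) {
      values[idx] <<- perturb_symbolic(values[idx], alphabet$symbols, role)
    } else {
      cols <- ((idx - 1L) %/% n) + 1L
      sym_cells <- column_types[cols] == "symbolic"
      if (any(sym_cells))
        values[idx[sym_cells]] <<- perturb_symbolic(values[idx[sym_cells]],
                                                    symbolic_alphabet$symbols, role)
      if (any(!sym_cells)) {
        ii <- idx[!sym_cells]
        x <- as.numeric(values[ii])
        fun <- if (role == "noise") perturb_noise_numeric else perturb_error_numeric
        values[ii] <<- fmt_num(fun(x, delta, alphabet$min, alphabet$max,
                                   identical(alphabet$kind, "numeric-integer")))
      }
    }
    invisible(NULL)
  }

  for (reg in regions) {
    len <- length(reg$idx)
    n_miss <- min(round(reg$pm / 100 * len), len)
    n_noise <- min(round(reg$pn / 100 * len), len - n_miss)
    n_err <- min(round(reg$pe / 100 * len), len - n_miss - n_noise)
    if (n_miss + n_noise + n_err > 0) {
      picked <- resample(reg$idx, n_miss + n_noise + n_err)
      miss <- picked[seq_len(n_miss)]
      noisy <- picked[n_miss + seq_len(n_noise)]
      errs <- picked[n_miss + n_noise + seq_len(n_err)]
      # skip perturbation of cells that are already missing (null background)
      if (numeric_data) {
        noisy <- noisy[!is.na(values[noisy])]
        errs <- errs[!is.na(values[errs])]
      } else {
        noisy <- noisy[!is.na(values[noisy])]
        errs <- errs[!is.na(values[errs])]
      }
      values[miss] <- if (numeric_data) NA_real_ else NA_character_
      perturb_cells(noisy, "noise")
      perturb_cells(errs, "error")
      all_missing <- c(all_missing, miss)
      all_noisy <- c(all_noisy, noisy)
      all_error <- c(all_error, errs)
    }
    counts <- rbind(counts, data.frame(region = reg$name, size = len,
                                       missing = n_miss, noisy = n_noise,
                                       error = n_err))
  }
  mask <- structure(list(missing = sort(all_missing), noisy = sort(all_noisy),
                         error = sort(all_error), noise_threshold = delta,
                         region_counts = counts),
                    class = "bic_qmask")
  list(values = values, mask = mask)
}
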