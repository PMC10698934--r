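# Bicluster shape and position sampling: sizes, overlap plan, frame placement.

# sample() guards against length-1 x; always index-sample.
resample <- function(x, k) x[sample.int(length(x), k)]
rsample <- function(x, k) x[sample.int(length(x), k, replace = TRUE)]

PLACEMENT_BUDGET <- 1000L

#' Sample bicluster dimensions
#'
#' Draws each bicluster's row and column counts from the configured
#' distributions (all row sizes first, then all column sizes). Normal draws
#' are rounded to the nearest integer; every size is clamped to
#' `[1, dataset dimension]`.
#'
#' @param spec a validated [generator_spec()].
#' @return a data frame with columns `rows` and `cols`, one row per
#'   bicluster.
#' @export
sample_sizes <- function(spec) {
  draw <- function(sd, q, dim_size) {
    if (sd$kind == "fixed" && sd$value > dim_size)
      stop("infeasible bicluster size: fixed size ", sd$value,
           " exceeds dataset dimension ", dim_size, call. = FALSE)
    x <- switch(sd$kind,
      fixed = rep(sd$value, q),
      uniform = rsample(seq(sd$low, sd$high), q),
      normal = round(stats::rnorm(q, sd$mean, sd$sd))
    )
    as.integer(pmin(pmax(x, 1), dim_size))
  }
  q <- spec$n_biclusters
  rows <- draw(spec$row_size, q, spec$n_rows)
  cols <- draw(spec$col_size, q, spec$n_cols)
  data.frame(rows = rows, cols = cols)
}

#' Partition biclusters into overlap groups
#'
#' `round(pct_biclusters/100 * q)` biclusters are placed into overlap groups
#' of between 2 and `max_interactions` members; the remaining biclusters are
#' singletons, placed cell-disjoint from everything else. A request leaving
#' a lone bicluster to overlap (e.g. one percent-rounded bicluster, or a
#' single-bicluster dataset) degrades to no overlap with a warning.
#'
#' @param spec a validated [generator_spec()].
#' @param n_biclusters number of biclusters (defaults to the spec's).
#' @return an object of class `bic_overlap_plan`: list with `groups` (list
#'   of integer vectors of bicluster indices) and `singletons` (integer
#'   vector).
#' @export
build_overlap_plan <- function(spec, n_biclusters = spec$n_biclusters) {
  q <- n_biclusters
  ov <- spec$overlap
  empty <- structure(list(groups = list(), singletons = seq_len(q)),
                     class = "bic_overlap_plan")
  if (ov$plaid == "no-overlap" || ov$pct_biclusters == 0) return(empty)
  q_ov <- round(ov$pct_biclusters / 100 * q)
  if (q_ov < 2) {
    if (q_ov > 0)
      warning("overlap requested for ", q_ov,
              " bicluster; degrading to no overlap", call. = FALSE)
    return(empty)
  }
  sizes <- NULL
  k <- q_ov
  while (k >= 2 && is.null(sizes)) {
    lo <- ceiling(k / ov$max_interactions)
    hi <- floor(k / 2)
    for (ng in seq(lo, max(lo, hi))) {
      if (ng > hi && k > ov$max_interactions) next
      if (ng < 1) next
      s <- rep(k %/% ng, ng)
      if (k %% ng > 0) s[seq_len(k %% ng)] <- s[seq_len(k %% ng)] + 1
      if (all(s >= 2) && all(s <= ov$max_interactions)) { sizes <- s; break }
    }
    if (is.null(sizes)) k <- k - 1
  }
  if (is.null(sizes)) return(empty)
  members <- resample(seq_len(q), k)
  groups <- split(members, rep(seq_along(sizes), sizes))
  names(groups) <- NULL
  structure(list(groups = groups,
                 singletons = setdiff(seq_len(q), members)),
            class = "bic_overlap_plan")
}

# Two frames (Cartesian products I x J) share a cell iff their row sets and
# column sets both intersect.
frames_conflict <- function(rows, cols, frame) {
  any(frame$colmask[cols]) && any(frame$rowmask[rows])
}

new_frame <- function(rows, cols, n, m, contiguous) {
  rows <- sort(as.integer(rows)); cols <- sort(as.integer(cols))
  rowmask <- logical(n); rowmask[rows] <- TRUE
  colmask <- logical(m); colmask[cols] <- TRUE
  structure(list(rows = rows, cols = cols, contiguous = contiguous,
                 rowmask = rowmask, colmask = colmask),
            class = "bic_frame")
}

draw_cols <- function(pool, c_size, contiguous, m) {
  if (!contiguous) return(sort(resample(pool, c_size)))
  start <- resample(seq_len(m - c_size + 1), 1)
  seq(start, start + c_size - 1)
}

# Deterministic sweep fallback: scan candidate column runs left to right;
# for each, collect the rows blocked by frames touching those columns and
# take the first free rows (row sets need not be contiguous).
sweep_place <- function(r, c, n, m, placed, col_pool, contiguous) {
  pool <- if (contiguous) seq_len(m) else sort(col_pool)
  if (length(pool) < c || r > n) return(NULL)
  n_cand <- length(pool) - c + 1
  if (length(placed) == 0)
    return(list(rows = seq_len(r), cols = pool[seq_len(c)]))
  rmask <- vapply(placed, function(f) f$rowmask, logical(n)) * 1  # n x F
  hit <- vapply(seq_len(n_cand), function(j) {
    cand <- pool[j:(j + c - 1)]
    vapply(placed, function(f) any(f$colmask[cand]), TRUE) * 1
  }, numeric(length(placed)))
  hit <- matrix(hit, nrow = length(placed))                        # F x n_cand
  blocked <- (rmask %*% hit) > 0                                   # n x n_cand
  free_rows <- n - colSums(blocked)
  j <- which(free_rows >= r)
  if (length(j) == 0) return(NULL)
  j <- j[1]
  list(rows = which(!blocked[, j])[seq_len(r)],
       cols = pool[j:(j + c - 1)])
}

place_singleton <- function(r, c, n, m, row_pool, col_pool, contiguous,
                            placed, relax, what) {
  for (try in seq_len(PLACEMENT_BUDGET)) {
    rows <- sort(resample(row_pool, r))
    cols <- draw_cols(col_pool, c, contiguous, m)
    ok <- TRUE
    for (f in placed) if (frames_conflict(rows, cols, f)) { ok <- FALSE; break }
    if (ok) return(new_frame(rows, cols, n, m, contiguous))
  }
  sw <- sweep_place(r, c, n, m, placed, col_pool, contiguous)
  if (!is.null(sw))
    return(new_frame(sw$rows, sw$cols, n, m, contiguous))
  if (relax) {
    rows <- sort(resample(row_pool, r))
    cols <- draw_cols(col_pool, c, contiguous, m)
    return(new_frame(rows, cols, n, m, contiguous))
  }
  stop("cannot place a disjoint ", r, "x", c, " bicluster (", what,
       ") in a ", n, "x", m, " matrix after ", PLACEMENT_BUDGET,
       " attempts and a deterministic sweep; the configuration is ",
       "over-packed (set relax_placement = TRUE to allow unplanned overlap)",
       call. = FALSE)
}

shared_quotas <- function(r, c, prev_r, prev_c, ov) {
  k_r <- round(ov$pct_rows / 100 * min(r, prev_r))
  k_c <- round(ov$pct_cols / 100 * min(c, prev_c))
  cap <- round(ov$pct_elements / 100 * min(r * c, prev_r * prev_c))
  while (k_r * k_c > cap && k_c > 0) k_c <- k_c - 1
  while (k_r * k_c > cap && k_r > 0) k_r <- k_r - 1
  c(k_r = k_r, k_c = k_c)
}

place_group_member <- function(r, c, n, m, row_pool, col_pool, contiguous,
                               prev, outside, ov, relax, what) {
  q <- shared_quotas(r, c, length(prev$rows), length(prev$cols), ov)
  k_r <- min(q[["k_r"]], r); k_c <- min(q[["k_c"]], c)
  last <- NULL
  for (try in seq_len(PLACEMENT_BUDGET)) {
    shared_rows <- resample(prev$rows, k_r)
    free_rows <- setdiff(row_pool, prev$rows)
    if (length(free_rows) < r - k_r) break
    rows <- sort(c(shared_rows, resample(free_rows, r - k_r)))
    if (contiguous) {
      a <- min(prev$cols); b <- max(prev$cols)
      starts <- integer(0)
      if (k_c > 0) {
        s_right <- b - k_c + 1          # run extends rightwards
        s_left <- a - (c - k_c)         # run extends leftwards
        if (s_right >= 1 && s_right + c - 1 <= m) starts <- c(starts, s_right)
        if (s_left >= 1 && s_left + c - 1 <= m && s_left != s_right)
          starts <- c(starts, s_left)
      } else {
        cand <- seq_len(m - c + 1)
        starts <- cand[cand + c - 1 < a | cand > b]
      }
      if (length(starts) == 0) break
      s <- resample(starts, 1)
      cols <- seq(s, s + c - 1)
    } else {
      shared_cols <- resample(prev$cols, k_c)
      free_cols <- setdiff(col_pool, prev$cols)
      if (length(free_cols) < c - k_c) break
      cols <- sort(c(shared_cols, resample(free_cols, c - k_c)))
    }
    last <- list(rows = rows, cols = cols)
    ok <- TRUE
    for (f in outside) if (frames_conflict(rows, cols, f)) { ok <- FALSE; break }
    if (ok) return(new_frame(rows, cols, n, m, contiguous))
  }
  if (relax && !is.null(last))
    return(new_frame(last$rows, last$cols, n, m, contiguous))
  stop("cannot place overlapping ", r, "x", c, " bicluster (", what,
       ") honoring the overlap quotas in a ", n, "x", m, " matrix; the ",
       "configuration is over-packed (set relax_placement = TRUE to allow ",
       "unplanned overlap)", call. = FALSE)
}

#' Place bicluster frames in the dataset
#'
#' Places every bicluster's row and column sets honoring the overlap plan:
#' singletons share no cell with any other frame; within an overlap group,
#' consecutive frames share `round(pct_rows/100 * |I|)` rows and
#' `round(pct_cols/100 * |J|)` columns (percentages of the smaller frame),
#' with the shared cell count capped by `pct_elements`. Contiguous specs
#' place each column set as a run of consecutive indices. Placement is
#' rejection sampling with a retry budget, then a deterministic block sweep;
#' geometrically infeasible configurations fail with a message naming the
#' parameters unless `relax_placement` is set.
#'
#' @param sizes data frame from [sample_sizes()].
#' @param plan a [build_overlap_plan()] result.
#' @param spec a validated [generator_spec()].
#' @param row_pools,col_pools optional per-bicluster lists of admissible row
#'   and column indices (used to restrict heterogeneous biclusters to
#'   columns of one attribute type).
#' @return list of `bic_frame` objects (fields `rows`, `cols`,
#'   `contiguous`), one per bicluster, in bicluster index order.
#' @export
place_frames <- function(sizes, plan, spec, row_pools = NULL, col_pools = NULL) {
  n <- spec$n_rows; m <- spec$n_cols
  q <- nrow(sizes)
  frames <- vector("list", q)
  relax <- isTRUE(spec$relax_placement)
  pool_r <- function(t) if (is.null(row_pools)) seq_len(n) else row_pools[[t]]
  pool_c <- function(t) if (is.null(col_pools)) seq_len(m) else col_pools[[t]]
  placed <- list()

  order_units <- c(lapply(plan$singletons, function(i) list(kind = "singleton", ids = i)),
                   lapply(plan$groups, function(g) list(kind = "group", ids = g)))
  # deterministic unit order: by first bicluster index
  ord <- order(vapply(order_units, function(u) min(u$ids), 1L))
  for (u in order_units[ord]) {
    if (u$kind == "singleton") {
      t <- u$ids
      frames[[t]] <- place_singleton(sizes$rows[t], sizes$cols[t], n, m,
                                     pool_r(t), pool_c(t), spec$contiguity,
                                     placed, relax,
                                     paste0("bicluster ", t))
      placed <- c(placed, frames[t])
    } else {
      group_frames <- list()
      prev <- NULL
      for (t in u$ids) {
        f <- if (is.null(prev)) {
          place_singleton(sizes$rows[t], sizes$cols[t], n, m,
                          pool_r(t), pool_c(t), spec$contiguity,
                          placed, relax, paste0("bicluster ", t))
        } else {
          place_group_member(sizes$rows[t], sizes$cols[t], n, m,
                             pool_r(t), pool_c(t), spec$contiguity,
                             prev, placed, spec$overlap, relax,
                             paste0("bicluster ", t))
        }
        frames[[t]] <- f
        group_frames <- c(group_frames, list(f))
        prev <- f
      }
      placed <- c(placed, group_frames)
    }
  }
  lapply(frames, function(f) f[c("rows", "cols", "contiguous")])
}
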