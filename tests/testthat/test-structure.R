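test_that("sizes respect their distributions and the dataset bounds", {
  sp <- validate_spec(tiny_spec(n_rows = 50, n_cols = 150, n_biclusters = 10,
                                row_size = size_dist("uniform", low = 3, high = 12),
                                col_size = size_dist("uniform", low = 10, high = 20)))
  set.seed(9)
  sz <- sample_sizes(sp)
  expect_true(all(sz$rows >= 3 & sz$rows <= 12))
  expect_true(all(sz$cols >= 10 & sz$cols <= 20))

  spf <- validate_spec(tiny_spec(n_rows = 60, n_cols = 60, n_biclusters = 3,
                                 row_size = size_dist("fixed", value = 50),
                                 col_size = size_dist("fixed", value = 50)))
  expect_equal(unname(as.matrix(sample_sizes(spf))),
               matrix(50L, 3, 2))

  bad <- tiny_spec(row_size = size_dist("fixed", value = 500))
  expect_error(validate_spec(bad), "exceeds dataset dimension")
})

test_that("normal size draws replay under the seeded stream", {
  sp <- validate_spec(tiny_spec(n_rows = 660, n_cols = 180, n_biclusters = 52,
                                row_size = size_dist("normal", mean = 73, sd = 3),
                                col_size = size_dist("fixed", value = 4)))
  set.seed(123)
  sz <- sample_sizes(sp)
  set.seed(123)
  oracle <- as.integer(pmin(pmax(round(stats::rnorm(52, 73, 3)), 1), 660))
  expect_equal(sz$rows, oracle)
  expect_true(all(sz$cols == 4))
})

test_that("overlap plans hit the rounded bicluster quota", {
  sp <- validate_spec(tiny_spec(n_biclusters = 10,
                                overlap = overlap_spec("additive",
                                                       pct_biclusters = 40,
                                                       max_interactions = 3)))
  set.seed(4)
  plan <- build_overlap_plan(sp)
  expect_equal(length(plan$singletons), 6)
  expect_equal(sum(lengths(plan$groups)), 4)
  expect_true(all(lengths(plan$groups) >= 2 & lengths(plan$groups) <= 3))

  sp2 <- validate_spec(tiny_spec(n_biclusters = 2,
                                 overlap = overlap_spec("additive",
                                                        pct_biclusters = 100)))
  plan2 <- build_overlap_plan(sp2)
  expect_equal(lengths(plan2$groups), 2)
  expect_length(plan2$singletons, 0)

  sp3 <- validate_spec(tiny_spec(overlap = overlap_spec("additive",
                                                        pct_biclusters = 0)))
  expect_length(build_overlap_plan(sp3)$groups, 0)

  sp4 <- validate_spec(tiny_spec(n_biclusters = 1,
                                 overlap = overlap_spec("additive",
                                                        pct_biclusters = 100)))
  expect_warning(plan4 <- build_overlap_plan(sp4), "degrading to no overlap")
  expect_equal(plan4$singletons, 1L)
})

test_that("consecutive group members share the configured rows and columns", {
  sp <- validate_spec(generator_spec(100, 100, n_biclusters = 2,
    row_size = size_dist("fixed", value = 50),
    col_size = size_dist("fixed", value = 50),
    overlap = overlap_spec("additive", pct_biclusters = 100,
                           max_interactions = 2, pct_rows = 50,
                           pct_cols = 50, pct_elements = 100)))
  set.seed(2)
  plan <- build_overlap_plan(sp)
  frames <- place_frames(sample_sizes(sp), plan, sp)
  shared_r <- length(intersect(frames[[1]]$rows, frames[[2]]$rows))
  shared_c <- length(intersect(frames[[1]]$cols, frames[[2]]$cols))
  expect_equal(shared_r, 25)
  expect_equal(shared_c, 25)
})

test_that("a zero element cap forces row-only sharing (no shared cell)", {
  sp <- validate_spec(generator_spec(60, 60, n_biclusters = 2,
    row_size = size_dist("fixed", value = 10),
    col_size = size_dist("fixed", value = 10),
    overlap = overlap_spec("additive", pct_biclusters = 100,
                           max_interactions = 2, pct_rows = 50,
                           pct_cols = 50, pct_elements = 0)))
  set.seed(5)
  frames <- place_frames(sample_sizes(sp), build_overlap_plan(sp), sp)
  shared_r <- length(intersect(frames[[1]]$rows, frames[[2]]$rows))
  shared_c <- length(intersect(frames[[1]]$cols, frames[[2]]$cols))
  expect_equal(shared_r * shared_c, 0)
  expect_gt(shared_r + shared_c, 0)
})

test_that("contiguous frames are runs of consecutive columns", {
  sp <- validate_spec(tiny_spec(n_rows = 40, n_cols = 150, n_biclusters = 5,
                                contiguity = TRUE,
                                col_size = size_dist("fixed", value = 8)))
  set.seed(6)
  frames <- place_frames(sample_sizes(sp), build_overlap_plan(sp), sp)
  for (f in frames) {
    expect_equal(max(f$cols) - min(f$cols), 7)
    expect_equal(f$cols, seq(min(f$cols), max(f$cols)))
  }
})

test_that("singleton frames are pairwise cell-disjoint (exhaustive check)", {
  sp <- validate_spec(tiny_spec(n_rows = 40, n_cols = 40, n_biclusters = 6,
                                row_size = size_dist("uniform", low = 4, high = 8),
                                col_size = size_dist("uniform", low = 4, high = 8)))
  for (s in 1:5) {
    set.seed(s)
    frames <- place_frames(sample_sizes(sp), build_overlap_plan(sp), sp)
    cells <- lapply(frames, function(f)
      as.vector(outer(f$rows, (f$cols - 1) * 40, `+`)))
    for (i in 1:5) for (j in (i + 1):6)
      expect_length(intersect(cells[[i]], cells[[j]]), 0)
  }
})

test_that("no cell is covered by more frames than max_interactions", {
  sp <- validate_spec(tiny_spec(n_rows = 60, n_cols = 60, n_biclusters = 8,
                                row_size = size_dist("fixed", value = 8),
                                col_size = size_dist("fixed", value = 8),
                                overlap = overlap_spec("additive",
                                                       pct_biclusters = 75,
                                                       max_interactions = 3,
                                                       pct_rows = 40, pct_cols = 40)))
  set.seed(8)
  d <- generate_dataset(sp)
  expect_lte(max(d$composition$coverage), 3)
})

test_that("over-packed configurations fail loudly with the parameters named", {
  sp <- validate_spec(tiny_spec(n_rows = 10, n_cols = 10, n_biclusters = 4,
                                row_size = size_dist("fixed", value = 6),
                                col_size = size_dist("fixed", value = 6)))
  set.seed(1)
  expect_error(place_frames(sample_sizes(sp), build_overlap_plan(sp), sp),
               "over-packed")
  sp$relax_placement <- TRUE
  frames <- place_frames(sample_sizes(sp), build_overlap_plan(sp), sp)
  expect_length(frames, 4)
})
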