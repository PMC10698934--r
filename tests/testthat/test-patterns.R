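frame_of <- function(nr, nc, contiguous = FALSE)
  list(rows = seq_len(nr), cols = seq_len(nc), contiguous = contiguous)

test_that("constant patterns fill the grid with the seed value", {
  set.seed(1)
  b <- plant_pattern(frame_of(3, 4), pattern_spec("constant", "constant"),
                     real_alpha())
  expect_true(all(b$values == b$mu))
  expect_equal(dim(b$values), c(3, 4))
})

test_that("the coherency formulas reproduce the stored factors exactly", {
  combos <- list(c("additive", "additive"), c("constant", "additive"),
                 c("additive", "constant"),
                 c("multiplicative", "multiplicative"),
                 c("constant", "multiplicative"), c("multiplicative", "constant"),
                 c("none", "constant"), c("constant", "none"))
  for (s in 1:5) {
    set.seed(s)
    for (p in combos) {
      b <- plant_pattern(frame_of(4, 5), pattern_spec(p[1], p[2]), real_alpha())
      mult <- any(p == "multiplicative")
      expected <- if (p[1] == "none") {
        matrix(b$alpha, 4, 5)
      } else if (p[2] == "none") {
        matrix(b$beta, 4, 5, byrow = TRUE)
      } else if (mult) {
        b$mu * outer(b$alpha, b$beta)
      } else {
        b$mu + outer(b$alpha, b$beta, `+`)
      }
      expect_identical(b$values, expected,
                       info = paste(p, collapse = "/"))
      expect_true(all(b$values >= -100 & b$values <= 100))
    }
  }
})

test_that("hand-picked additive and multiplicative grids match the formulas", {
  # mu = 1, alpha = (0, 2), beta = (0, 3) -> [[1, 4], [3, 6]]
  g <- bicsim:::pattern_grid(1, c(0, 2), c(0, 3), "additive", "additive", 2, 2)
  expect_equal(g, matrix(c(1, 3, 4, 6), 2, 2))
  # mu = 2, alpha = (1, 3), beta = 1 -> rows of constant 2 and 6
  g2 <- bicsim:::pattern_grid(2, c(1, 3), c(1, 1), "multiplicative", "constant", 2, 2)
  expect_equal(g2, matrix(c(2, 6, 2, 6), 2, 2))
})

test_that("one shared column permutation sorts every order-preserving row", {
  for (s in 1:5) {
    set.seed(s)
    b <- plant_pattern(frame_of(3, 4), pattern_spec("none", "order-preserving"),
                       real_alpha())
    # brute force: some permutation sorts all rows, and it is the stored one
    perms <- as.matrix(expand.grid(rep(list(1:4), 4)))
    perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 4), ]
    sorts_all <- apply(perms, 1, function(p)
      all(apply(b$values[, p], 1, function(r) all(diff(r) > 0))))
    expect_true(any(sorts_all))
    expect_true(all(apply(b$values[, b$permutation], 1,
                          function(r) all(diff(r) > 0))))
  }
})

test_that("row-side order preservation sorts every column under one row order", {
  set.seed(3)
  b <- plant_pattern(frame_of(5, 3), pattern_spec("order-preserving", "none"),
                     real_alpha())
  expect_true(all(apply(b$values[b$permutation, ], 2,
                        function(col) all(diff(col) > 0))))
})

test_that("symbolic order-preserving orders by alphabet rank", {
  set.seed(2)
  b <- plant_pattern(frame_of(4, 3), pattern_spec("none", "order-preserving"),
                     sym_alpha())
  ranks <- matrix(match(b$values, c("a", "b", "c", "d", "e")), 4, 3)
  expect_true(all(apply(ranks[, b$permutation], 1, function(r) all(diff(r) > 0))))
  expect_error(plant_pattern(frame_of(2, 9),
                             pattern_spec("none", "order-preserving"),
                             sym_alpha()),
               "distinct symbols")
})

test_that("time profiles order rows in real column order", {
  fr <- frame_of(4, 6, contiguous = TRUE)
  set.seed(4)
  inc <- plant_pattern(fr, pattern_spec("none", "order-preserving",
                                        time_profile = "monotonically-increasing"),
                       real_alpha())
  expect_true(all(apply(inc$values, 1, function(r) all(diff(r) > 0))))
  dec <- plant_pattern(fr, pattern_spec("none", "order-preserving",
                                        time_profile = "monotonically-decreasing"),
                       real_alpha())
  expect_true(all(apply(dec$values, 1, function(r) all(diff(r) < 0))))
  expect_equal(inc$permutation, 1:6)
  expect_equal(dec$permutation, 6:1)
})

test_that("re-profiling preserves the value multiset and flips the order", {
  fr <- frame_of(3, 5, contiguous = TRUE)
  set.seed(5)
  b <- plant_pattern(fr, pattern_spec("none", "order-preserving",
                                      time_profile = "random"),
                     real_alpha())
  dec <- apply_time_profile(b, "monotonically-decreasing")
  expect_equal(apply(dec$values, 1, sort), apply(b$values, 1, sort))
  expect_true(all(apply(dec$values, 1, function(r) all(diff(r) < 0))))
  # a drawn identity permutation is exactly the increasing profile
  inc <- apply_time_profile(b, "monotonically-increasing")
  rand_as_identity <- b
  rand_as_identity$values <- inc$values
  rand_as_identity$permutation <- seq_len(5)
  expect_equal(rand_as_identity$values,
               apply_time_profile(rand_as_identity,
                                  "monotonically-increasing")$values)
  nb <- b; nb$contiguous <- FALSE
  expect_error(apply_time_profile(nb, "monotonically-increasing"), "contiguous")
})

test_that("symbolic additive and multiplicative planting is rejected", {
  expect_error(plant_pattern(frame_of(2, 2), pattern_spec("additive", "additive"),
                             sym_alpha()),
               "numeric alphabet")
})

test_that("planted values always stay inside the alphabet", {
  for (s in 1:10) {
    set.seed(s)
    b <- plant_pattern(frame_of(6, 6),
                       pattern_spec("multiplicative", "multiplicative"),
                       real_alpha(-5, 5))
    expect_true(all(b$values >= -5 & b$values <= 5))
    bi <- plant_pattern(frame_of(6, 6), pattern_spec("additive", "additive"),
                        int_alpha(0, 10))
    expect_true(all(bi$values >= 0 & bi$values <= 10 &
                    bi$values == round(bi$values)))
  }
})
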