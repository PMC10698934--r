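test_that("plaid modes combine overlapping contributions as sum/product/mean", {
  bg <- matrix(0, 6, 6)
  b1 <- const_bic(1:3, 1:3, 2)
  b2 <- const_bic(2:4, 2:4, 3)
  add <- compose(bg, list(b1, b2), mode = "additive", alphabet = real_alpha())
  expect_equal(add$values[2, 2], 5)      # overlap: 2 + 3
  expect_equal(add$values[1, 1], 2)      # single coverage keeps its value
  mult <- compose(bg, list(b1, b2), mode = "multiplicative", alphabet = real_alpha())
  expect_equal(mult$values[3, 3], 6)     # overlap: 2 * 3
  b3 <- const_bic(2:4, 2:4, 4)
  interp <- compose(bg, list(b1, b3), mode = "interpoled", alphabet = real_alpha())
  expect_equal(interp$values[2, 2], 3)   # overlap: mean(2, 4)
  expect_equal(interp$values[4, 4], 4)   # covered once: its own value
})

test_that("composition matches the brute-force membership oracle", {
  for (s in 1:5) {
    set.seed(s)
    bg <- matrix(round(stats::runif(400, -50, 50), 3), 20, 20)
    bics <- lapply(1:3, function(t)
      const_bic(sort(sample.int(20, sample(3:6, 1))),
                sort(sample.int(20, sample(3:6, 1))),
                round(stats::runif(1, -5, 5), 3)))
    for (mode in c("additive", "multiplicative", "interpoled", "none")) {
      got <- compose(bg, bics, mode = mode, alphabet = real_alpha())$values
      expect_equal(got, brute_force_compose(bg, bics, mode), info = mode)
    }
  }
})

test_that("uncovered cells keep the background bit-exactly", {
  set.seed(1)
  bg <- matrix(stats::runif(100, -10, 10), 10, 10)
  b <- const_bic(1:3, 1:3, 5)
  out <- compose(bg, list(b), mode = "additive", alphabet = real_alpha())
  outside <- out$coverage == 0
  expect_identical(out$values[outside], bg[outside])
})

test_that("with a single bicluster every plaid mode gives the same matrix", {
  set.seed(2)
  bg <- matrix(stats::runif(64, -10, 10), 8, 8)
  b <- const_bic(2:5, 3:6, 7)
  mats <- lapply(c("additive", "multiplicative", "interpoled", "none"),
                 function(mo) compose(bg, list(b), mode = mo,
                                      alphabet = real_alpha())$values)
  for (k in 2:4) expect_identical(mats[[1]], mats[[k]])
})

test_that("mode none is last-writer-wins in generation order", {
  bg <- matrix(0, 5, 5)
  b1 <- const_bic(1:3, 1:3, 2)
  b2 <- const_bic(2:4, 2:4, 9)
  out <- compose(bg, list(b1, b2), mode = "none", alphabet = real_alpha())
  expect_equal(out$values[2, 2], 9)
  out_rev <- compose(bg, list(b2, b1), mode = "none", alphabet = real_alpha())
  expect_equal(out_rev$values[2, 2], 2)
})

test_that("out-of-range composed values are clipped and flagged", {
  bg <- matrix(0, 4, 4)
  b1 <- const_bic(1:2, 1:2, 80)
  b2 <- const_bic(1:2, 1:2, 80)
  out <- compose(bg, list(b1, b2), mode = "additive", alphabet = real_alpha())
  expect_equal(out$values[1, 1], 100)
  expect_setequal(out$clipped, c(1, 2, 5, 6))
  sol <- ground_truth(list(b1, b2), out)
  expect_setequal(sol$biclusters[[1]]$clipped_cells, c(1, 2, 5, 6))
})

test_that("arithmetic plaid on symbolic matrices is rejected", {
  bg <- matrix("a", 4, 4)
  b <- const_bic(1:2, 1:2, 1)
  b$values <- matrix("b", 2, 2); b$type <- "symbolic"
  expect_error(compose(bg, list(b), mode = "additive"), "symbolic")
  out <- compose(bg, list(b), mode = "none")
  expect_equal(out$values[1, 1], "b")
})

test_that("the solution record lists every bicluster cell and membership", {
  sp <- validate_spec(generator_spec(100, 100,
    background = background_spec("normal", mean = 0, sd = 30),
    n_biclusters = 1,
    row_size = size_dist("fixed", value = 50),
    col_size = size_dist("fixed", value = 50)))
  d <- generate_dataset(sp, seed = 3)
  b <- d$solution$biclusters[[1]]
  expect_equal(b$n_rows * b$n_cols, 2500)
  expect_equal(dim(b$values), c(50, 50))
  mem <- plaid_membership(d$biclusters, 100, 100)
  expect_equal(sum(mem$rho), 50)
  expect_equal(sum(mem$kappa), 50)
  expect_equal(which(mem$rho[, 1]), b$rows)
})

test_that("overlapping biclusters both list the shared cells at composed values", {
  d <- generate_dataset(preset_spec("illustrative-2"), seed = 4)
  b1 <- d$solution$biclusters[[1]]
  b2 <- d$solution$biclusters[[2]]
  sr <- intersect(b1$rows, b2$rows)
  sc <- intersect(b1$cols, b2$cols)
  expect_gt(length(sr) * length(sc), 0)
  i <- sr[1]; j <- sc[1]
  v1 <- b1$values[match(i, b1$rows), match(j, b1$cols)]
  v2 <- b2$values[match(i, b2$rows), match(j, b2$cols)]
  expect_identical(v1, v2)                      # both record the final value
  expect_identical(v1, d$data[i, j])            # which is the matrix value
  planted1 <- d$biclusters[[1]]$values[match(i, b1$rows), match(j, b1$cols)]
  planted2 <- d$biclusters[[2]]$values[match(i, b2$rows), match(j, b2$cols)]
  expect_equal(v1, planted1 + planted2)         # additive plaid on the overlap
})
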