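clean_dataset <- function(n = 20, m = 20, n_bics = 1, quality = quality_spec(),
                          alphabet = real_alpha(), data_type = "numeric",
                          seed = 1) {
  sp <- validate_spec(tiny_spec(n_rows = n, n_cols = m, n_biclusters = n_bics,
                                data_type = data_type, alphabet = alphabet,
                                background = background_spec("uniform"),
                                row_size = size_dist("fixed", value = 5),
                                col_size = size_dist("fixed", value = 5),
                                quality = quality))
  generate_dataset(sp, seed = seed)
}

test_that("full background missingness leaves bicluster cells intact", {
  d <- clean_dataset(quality = quality_spec(pct_missing_background = 100))
  bg <- d$composition$coverage == 0
  expect_true(all(is.na(d$data[bg])))
  expect_false(anyNA(d$data[!bg]))
})

test_that("perturbed-cell counts equal their rounded quotas exactly", {
  d <- clean_dataset(n = 30, m = 30, n_bics = 2,
                     quality = quality_spec(pct_missing_background = 7,
                                            pct_noise_background = 11,
                                            pct_error_background = 3,
                                            pct_missing_biclusters = 10,
                                            pct_noise_biclusters = 20,
                                            pct_error_biclusters = 4,
                                            noise_threshold = 5))
  bg_size <- 900 - 50
  rc <- d$quality$region_counts
  expect_equal(rc$missing, c(round(0.07 * bg_size), 2, 2)) # 10% of 25 cells, twice
  expect_equal(rc$noisy, c(round(0.11 * bg_size), 5, 5))
  expect_equal(rc$error, c(round(0.03 * bg_size), 1, 1))
  expect_length(d$quality$missing, sum(rc$missing))
  expect_length(d$quality$noisy, sum(rc$noisy))
  expect_length(d$quality$error, sum(rc$error))
  # roles are mutually exclusive
  expect_length(intersect(d$quality$missing, d$quality$noisy), 0)
  expect_length(intersect(d$quality$missing, d$quality$error), 0)
  expect_length(intersect(d$quality$noisy, d$quality$error), 0)
})

test_that("noise stays within the threshold and errors beyond it", {
  for (s in 1:3) {
    d <- clean_dataset(n = 40, m = 40,
                       quality = quality_spec(pct_noise_background = 15,
                                              pct_error_background = 10,
                                              pct_noise_biclusters = 20,
                                              pct_error_biclusters = 10,
                                              noise_threshold = 5),
                       seed = s)
    clean <- generate_dataset(utils::modifyList(d$spec,
                                                list(quality = quality_spec())),
                              seed = s)
    delta <- d$data - clean$data
    expect_true(all(abs(delta[d$quality$noisy]) > 0))
    expect_true(all(abs(delta[d$quality$noisy]) <= 5))
    expect_true(all(abs(delta[d$quality$error]) > 5))
    untouched <- setdiff(seq_along(delta),
                         c(d$quality$noisy, d$quality$error, d$quality$missing))
    expect_true(all(delta[untouched] == 0))
  }
})

test_that("integer-alphabet perturbations stay integral and in range", {
  d <- clean_dataset(alphabet = int_alpha(0, 20),
                     quality = quality_spec(pct_noise_background = 20,
                                            pct_error_background = 10,
                                            noise_threshold = 3))
  v <- d$data[!is.na(d$data)]
  expect_true(all(v == round(v) & v >= 0 & v <= 20))
})

test_that("symbolic noise moves one rank, symbolic errors at least two", {
  sp <- validate_spec(tiny_spec(n_rows = 25, n_cols = 20,
                                data_type = "symbolic", alphabet = sym_alpha(),
                                background = background_spec("uniform"),
                                row_size = size_dist("fixed", value = 5),
                                col_size = size_dist("fixed", value = 5),
                                quality = quality_spec(pct_noise_background = 20,
                                                       pct_error_background = 10)))
  d <- generate_dataset(sp, seed = 2)
  clean <- generate_dataset(utils::modifyList(sp, list(quality = quality_spec())),
                            seed = 2)
  rank <- function(x) match(x, c("a", "b", "c", "d", "e"))
  dn <- abs(rank(d$data[d$quality$noisy]) - rank(clean$data[d$quality$noisy]))
  de <- abs(rank(d$data[d$quality$error]) - rank(clean$data[d$quality$error]))
  expect_true(all(dn == 1))
  expect_true(all(de >= 2))
})

test_that("overlap-shared cells are charged to the first bicluster only", {
  sp <- validate_spec(generator_spec(60, 60, n_biclusters = 2,
    row_size = size_dist("fixed", value = 10),
    col_size = size_dist("fixed", value = 10),
    overlap = overlap_spec("additive", pct_biclusters = 100,
                           max_interactions = 2, pct_rows = 50, pct_cols = 50),
    quality = quality_spec(pct_missing_biclusters = 100)))
  d <- generate_dataset(sp, seed = 3)
  rc <- d$quality$region_counts
  expect_equal(rc$missing[rc$region == "bicluster_1"], 100)
  expect_equal(rc$missing[rc$region == "bicluster_2"], 100 - 25)
  covered <- d$composition$coverage > 0
  expect_true(all(is.na(d$data[covered])))
})

test_that("identical spec and seed give identical quality masks", {
  q <- quality_spec(pct_missing_background = 5, pct_noise_background = 5,
                    pct_error_background = 5, noise_threshold = 4)
  d1 <- clean_dataset(quality = q, seed = 11)
  d2 <- clean_dataset(quality = q, seed = 11)
  expect_identical(d1$quality, d2$quality)
  expect_identical(d1$data, d2$data)
})
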