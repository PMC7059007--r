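test_that("targeted filter drops Xenobiotics and untargeted compounds", {
  cat <- tiny_catalogue(n_targeted = 6, n_xeno = 3, n_untargeted = 1)
  v <- matrix(1, 3, 10, dimnames = list(NULL, cat$metabolite_id))
  m <- toy_matrix(v)
  out <- filter_targeted(m, cat)
  expect_equal(ncol(out$values), 6)
  expect_identical(colnames(out$values), cat$metabolite_id[1:6])

  # no Xenobiotics, all targeted: identity
  cat2 <- tiny_catalogue(n_targeted = 10, n_xeno = 0, n_untargeted = 0)
  m2 <- toy_matrix(matrix(1, 3, 10,
                          dimnames = list(NULL, cat2$metabolite_id)))
  expect_identical(filter_targeted(m2, cat2)$values, m2$values)

  # idempotence
  expect_identical(filter_targeted(out, cat)$values, out$values)

  # unknown metabolite named in the error
  m3 <- m
  colnames(m3$values)[1] <- "M999"
  expect_error(filter_targeted(m3, cat), "M999")
})

test_that("median rescaling gives every column median 1 and keeps order", {
  v <- matrix(c(2, 4, 8,
                5, 5, 5,
                1, NA, 3), 3, 3,
              dimnames = list(NULL, c("A", "B", "C")))
  v <- cbind(v, D = c(9, NA, 1))  # median of observed c(9, 1) = 5
  m <- median_rescale(toy_matrix(v))
  expect_equal(unname(m$values[, "A"]), c(0.5, 1, 2))
  expect_equal(unname(m$values[, "B"]), c(1, 1, 1))
  expect_equal(unname(m$values[, "C"]), c(0.5, NA, 1.5))
  meds <- apply(m$values, 2, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(1, 4))
  expect_equal(m$stage, "rescaled")
  # [1, missing, 3, 9]: median of observed = 3
  v2 <- matrix(c(1, NA, 3, 9), 4, 1, dimnames = list(NULL, "A"))
  m2 <- median_rescale(toy_matrix(v2, weeks = c(0, 0, 6, 6)))
  expect_equal(unname(m2$values[, 1]), c(1 / 3, NA, 1, 3))
  # value ordering within columns is preserved
  expect_identical(order(m$values[, "A"]), order(v[, "A"]))
  # a fully missing column errors, naming the column
  v3 <- matrix(NA_real_, 3, 1, dimnames = list(NULL, "E"))
  expect_error(median_rescale(toy_matrix(cbind(v, v3))), "E")
})

test_that("rescaling an already-rescaled matrix is the identity", {
  set.seed(1)
  v <- matrix(rlnorm(60), 6, 10)
  m1 <- median_rescale(toy_matrix(v))
  m2 <- median_rescale(toy_matrix(m1$values))
  expect_equal(m1$values, m2$values, tolerance = 1e-12)
})

test_that("log10 transform maps known values and preserves missing", {
  v <- matrix(c(1, 100, NA, 0.1), 4, 1, dimnames = list(NULL, "A"))
  m <- toy_matrix(v, weeks = c(0, 0, 6, 6))
  lm_ <- log10_transform(median_rescale(m))
  expect_equal(m$stage, "raw")
  expect_true(is.na(lm_$values[3, 1]))
  # direct spec examples on an identity-rescaled column
  v2 <- matrix(c(1, 100, NA), 3, 1, dimnames = list(NULL, "A"))
  m2 <- toy_matrix(v2)
  m2$stage <- "rescaled"
  out <- log10_transform(m2)
  expect_equal(unname(out$values[, 1]), c(0, 2, NA))
  # nonpositive values are rejected
  m3 <- toy_matrix(matrix(c(1, 2, 3), 3, 1), stage = "raw")
  m3$stage <- "rescaled"
  m3$values[1] <- -1
  expect_error(log10_transform(m3), "positive")
})

test_that("stage tags forbid out-of-order pipeline steps", {
  m <- toy_matrix(matrix(1:9 + 0, 3, 3))
  expect_error(log10_transform(m), "rescaled")
  expect_error(exclude_outliers(m), "log10")
  expect_error(median_rescale(log10_transform(median_rescale(m))),
               "raw")
})

test_that("4-SD exclusion masks a single extreme point only at n >= 18", {
  # eighteen 0.0s and one 1.0: z = (1 - 1/19) / (1/sqrt(19)) = 4.13 > 4
  v <- matrix(c(rep(0, 18), 1), 19, 1, dimnames = list(NULL, "A"))
  m <- toy_matrix(v, stage = "log10", weeks = rep_len(c(0, 6, 12), 19))
  out <- exclude_outliers(m)
  expect_equal(nrow(out$masked), 1)
  expect_equal(out$masked$value, 1)
  expect_equal(out$masked$z, (1 - 1 / 19) * sqrt(19), tolerance = 1e-12)
  expect_true(is.na(out$matrix$values[19, 1]))

  # any 10-observation column: max attainable |z| = 9/sqrt(10) < 4
  set.seed(42)
  for (r in 1:20) {
    v10 <- matrix(rnorm(10, sd = 10^runif(1, -2, 2)), 10, 1,
                  dimnames = list(NULL, "A"))
    m10 <- toy_matrix(v10, stage = "log10", weeks = rep_len(c(0, 6), 10))
    expect_equal(nrow(exclude_outliers(m10)$masked), 0)
  }

  # constant column: SD 0 guard
  vc <- matrix(5, 19, 1, dimnames = list(NULL, "A"))
  mc <- toy_matrix(vc, stage = "log10", weeks = rep_len(c(0, 6, 12), 19))
  expect_equal(nrow(exclude_outliers(mc)$masked), 0)

  expect_error(exclude_outliers(m, z_max = 0), "positive")
})

test_that("columns with < 18 present values are never masked", {
  set.seed(7)
  for (n in c(5, 11, 17)) {
    v <- matrix(rnorm(n * 4), n, 4)
    v[sample(length(v), 3)] <- NA
    m <- toy_matrix(v, stage = "log10", weeks = rep_len(c(0, 6, 12), n))
    expect_equal(nrow(exclude_outliers(m)$masked), 0)
  }
})

test_that("preprocess chains the steps and logs provenance", {
  cfg <- sim_config(seed = 8)
  cat <- generate_catalogue(cfg)
  gen <- generate_abundances(cat, cfg)
  out <- preprocess(gen$matrix, cat)
  expect_equal(out$matrix$stage, "outlier-masked")
  expect_lte(ncol(out$matrix$values), 736)
  expect_true(all(c("filter_targeted") %in% out$provenance$stage))
  expect_equal(sum(out$provenance$stage == "filter_targeted"), 867 - 736)
})
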