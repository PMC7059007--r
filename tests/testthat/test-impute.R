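test_that("detection limit is the global minimum observed value", {
  v <- matrix(c(1, 0.5, 2, NA), 2, 2, dimnames = list(NULL, c("A", "B")))
  m <- toy_matrix(v, weeks = c(0, 6))
  expect_equal(estimate_detection_limit(m), 0.5)
  v1 <- matrix(c(NA, 3.2, NA, NA), 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_equal(estimate_detection_limit(toy_matrix(v1, weeks = c(0, 6))), 3.2)
  vna <- matrix(NA_real_, 2, 2, dimnames = list(NULL, c("A", "B")))
  expect_error(estimate_detection_limit(toy_matrix(vna, weeks = c(0, 6))),
               "no observed")
})

test_that("truncated MLE collapses to the plain Gaussian MLE when
           truncation is negligible", {
  set.seed(10)
  x <- rnorm(200, mean = 5, sd = 2)
  f <- fit_truncated_gaussian(x, dl = min(x) - 50)
  n <- length(x)
  # plain Gaussian MLE: mean and the 1/n-denominator SD
  expect_equal(f$mu, mean(x), tolerance = 1e-6)
  expect_equal(f$sigma, sd(x) * sqrt((n - 1) / n), tolerance = 1e-6)
  expect_true(f$converged)

  # dl -> -Inf limit checked at min - 10 * SD
  f2 <- fit_truncated_gaussian(x, dl = min(x) - 10 * sd(x))
  expect_equal(f2$mu, mean(x), tolerance = 1e-6)
})

test_that("truncated MLE recovers (0, 1) from draws truncated at -0.5", {
  set.seed(7)
  x <- rnorm(2e4)
  x <- x[x >= -0.5][1:1e4]
  f <- fit_truncated_gaussian(x, -0.5)
  expect_true(f$converged)
  expect_lt(abs(f$mu), 0.05)
  expect_lt(abs(f$sigma - 1), 0.05)
  # naive moments are visibly biased by the truncation, the MLE is not
  expect_gt(abs(mean(x)), 0.1)
})

test_that("too few observations signal a fallback instead of fitting", {
  f <- fit_truncated_gaussian(c(1.2, 3.4), dl = 1, min_observed = 3)
  expect_false(f$converged)
  expect_true(is.na(f$log_likelihood))
  expect_error(fit_truncated_gaussian(c(0.5, 2, 3), dl = 1), "below")
})

test_that("truncated log-likelihood at the MLE dominates the naive start", {
  loglik <- function(mu, sigma, x, dl) {
    sum(dnorm((x - mu) / sigma, log = TRUE)) - length(x) * log(sigma) -
      length(x) * pnorm((dl - mu) / sigma, lower.tail = FALSE, log.p = TRUE)
  }
  set.seed(11)
  for (r in 1:10) {
    x0 <- rnorm(60, mean = r / 5, sd = 0.8)
    dl <- unname(quantile(x0, 0.3))
    x <- x0[x0 >= dl]
    f <- fit_truncated_gaussian(x, dl)
    expect_gte(f$log_likelihood + 1e-8, loglik(mean(x), sd(x), x, dl))
    expect_equal(f$log_likelihood, loglik(f$mu, f$sigma, x, dl),
                 tolerance = 1e-8)
  }
})

test_that("MLE bias shrinks with sample size", {
  bias_at <- function(n) {
    mus <- sapply(1:30, function(r) {
      set.seed(r * 1000 + n)
      x <- rnorm(5 * n)
      x <- x[x >= -0.5][1:n]
      fit_truncated_gaussian(x, -0.5)$mu
    })
    abs(mean(mus))
  }
  b <- sapply(c(50, 500, 5000), bias_at)
  expect_true(all(diff(b) <= 0))
})

test_that("standardize and back-transform are exact inverses", {
  cfg <- null_sim_config(25, seed = 14, censor = 0.08)
  gen <- generate_abundances(generate_catalogue(cfg), cfg)
  pre <- preprocess(gen$matrix, generate_catalogue(cfg))
  dl <- estimate_detection_limit(pre$matrix)
  fits <- fit_matrix_truncated(pre$matrix, dl)
  std <- standardize_matrix(pre$matrix, fits)
  # x = mu -> 0 and x = mu + sigma -> 1
  j <- which(fits$converged)[1]
  probe <- pre$matrix
  probe$values[1, j] <- fits$mu[j]
  probe$values[2, j] <- fits$mu[j] + fits$sigma[j]
  pstd <- standardize_matrix(probe, fits)
  expect_equal(unname(pstd$values[1, j]), 0, tolerance = 1e-12)
  expect_equal(unname(pstd$values[2, j]), 1, tolerance = 1e-12)
  back <- back_transform(std, fits)
  expect_equal(back$values, pre$matrix$values, tolerance = 1e-12)
  expect_equal(back$stage, "imputed")
  expect_error(standardize_matrix(pre$matrix, fits[-1, ]), "fit")
})

test_that("knn imputation honours perfect correlation and weight sums", {
  # two perfectly correlated metabolites plus an uncorrelated third
  set.seed(3)
  a <- rnorm(10)
  v <- cbind(A = a, B = a, C = rnorm(10))
  m <- toy_matrix(v, stage = "standardized", weeks = rep_len(c(0, 6, 12), 10))
  m$values[4, "A"] <- NA
  out <- knn_impute(m, impute_config(k_neighbours = 1))
  expect_equal(unname(out$matrix$values[4, "A"]), a[4], tolerance = 1e-9)
  expect_equal(out$log$neighbours, "B")

  # all K neighbours carry value v with positive correlations -> exactly v
  set.seed(4)
  base <- rnorm(12)
  vv <- sapply(1:5, function(k) base + rnorm(12, sd = 0.05))
  colnames(vv) <- paste0("N", 1:5)
  m2 <- toy_matrix(vv, stage = "standardized", weeks = rep_len(c(0, 6, 12), 12))
  m2$values[6, "N1"] <- NA
  m2$values[6, colnames(vv)[-1]] <- 0.77
  out2 <- knn_impute(m2, impute_config(k_neighbours = 4))
  expect_equal(unname(out2$matrix$values[6, "N1"]), 0.77, tolerance = 1e-9)

  # anti-correlated neighbour: sign-corrected value
  v3 <- cbind(A = a, B = -a)
  m3 <- toy_matrix(v3, stage = "standardized", weeks = rep_len(c(0, 6, 12), 10))
  m3$values[2, "A"] <- NA
  out3 <- knn_impute(m3, impute_config(k_neighbours = 1))
  expect_equal(unname(out3$matrix$values[2, "A"]), a[2], tolerance = 1e-9)
})

test_that("imputation leaves observed cells untouched and fills all gaps", {
  cfg <- null_sim_config(40, seed = 15, censor = 0.1)
  gen <- generate_abundances(generate_catalogue(cfg), cfg)
  pre <- preprocess(gen$matrix, generate_catalogue(cfg))
  imp <- impute_knn_tn(pre$matrix)
  expect_false(anyNA(imp$matrix$values))
  obs <- !is.na(pre$matrix$values)
  expect_equal(imp$matrix$values[obs], pre$matrix$values[obs],
               tolerance = 1e-10)
  expect_equal(nrow(imp$log), sum(!obs))
})

test_that("KNN-TN beats column-mean imputation on MNAR-censored data", {
  wins <- 0
  for (s in 1:10) {
    cfg <- null_sim_config(80, seed = s, censor = 0.10)
    cat_ <- generate_catalogue(cfg)
    gen <- generate_abundances(cat_, cfg)
    pre <- preprocess(gen$matrix, cat_)
    kept <- colnames(pre$matrix$values)
    med <- apply(gen$matrix$values[, kept], 2, median, na.rm = TRUE)
    truth_log <- sweep(gen$truth$log10_clean[, kept], 2, log10(med), "-")
    imp <- impute_knn_tn(pre$matrix)
    miss <- is.na(pre$matrix$values)
    rmse_knn <- sqrt(mean((imp$matrix$values[miss] - truth_log[miss])^2))
    cm <- pre$matrix$values
    for (j in seq_len(ncol(cm)))
      cm[is.na(cm[, j]), j] <- mean(cm[, j], na.rm = TRUE)
    rmse_cm <- sqrt(mean((cm[miss] - truth_log[miss])^2))
    wins <- wins + (rmse_knn < rmse_cm)
  }
  expect_gte(wins, 9)
})
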