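## KNN-TN imputation of left-censored (MNAR) missing values:
##   1. detection limit (DL) = global minimum observed value,
##   2. per-metabolite (mu, sigma) by MLE of a left-truncated Gaussian,
##   3. standardize with the truncated-normal MLEs,
##   4. K nearest metabolites by |Pearson r| (pairwise-complete),
##   5. sign-corrected correlation-weighted average,
##   6. back-transform to the original scale.

#' Imputation configuration
#'
#' @param k_neighbours number of nearest metabolites K (default 10).
#' @param min_observed_for_mle minimum observed values needed for the
#'   truncated-Gaussian MLE; below it a column-moment fallback is used and
#'   flagged.
#' @param min_shared_samples minimum pairwise-complete samples for a
#'   correlation to qualify a neighbour.
#' @param fallback imputation for a cell with no usable neighbour:
#'   `"column_mean"` (default; mean of the metabolite's observed values)
#'   or `"half_dl"` (DL/2 on the original scale). Half-DL is the classic
#'   choice for raw-scale censoring, but after per-metabolite median
#'   rescaling the global DL is dominated by whichever metabolite has the
#'   deepest tail below its own median and badly undershoots most
#'   columns, so the column mean is the safer default here.
#' @return list of class `"impute_config"`.
#' @export
impute_config <- function(k_neighbours = 10, min_observed_for_mle = 3,
                          min_shared_samples = 3,
                          fallback = c("column_mean", "half_dl")) {
  if (k_neighbours < 1) stop("'k_neighbours' must be >= 1")
  structure(list(k_neighbours = as.integer(k_neighbours),
                 min_observed_for_mle = as.integer(min_observed_for_mle),
                 min_shared_samples = as.integer(min_shared_samples),
                 fallback = match.arg(fallback)),
            class = "impute_config")
}

#' Detection limit of the dataset
#'
#' The instrument's detection level is estimated as the minimum observed
#' value over the whole matrix.
#'
#' @param mat an [abundance_matrix()].
#' @return scalar minimum present value.
#' @export
estimate_detection_limit <- function(mat) {
  .assert_abundance(mat)
  if (all(is.na(mat$values))) stop("matrix has no observed values")
  min(mat$values, na.rm = TRUE)
}

#' Left-truncated Gaussian maximum-likelihood fit
#'
#' Maximizes the log-likelihood of observations from a normal distribution
#' truncated on the left at `dl`:
#' `sum(log phi((x - mu)/sigma) - log sigma) - n * log(1 - Phi((dl - mu)/sigma))`.
#' Solved by direct numerical optimization over `(mu, log sigma)` from the
#' naive sample moments; robust down to n = 3. With fewer than
#' `min_observed` values the naive moments are returned with
#' `converged = FALSE` (fallback signalled, never silent).
#'
#' @param values observed values (all >= `dl`).
#' @param dl left-truncation point (detection limit), same scale as
#'   `values`.
#' @param min_observed minimum n for the MLE.
#' @return list of class `"trunc_gauss_fit"`: `mu`, `sigma`, `dl`,
#'   `n_observed`, `converged`, `log_likelihood`.
#' @export
fit_truncated_gaussian <- function(values, dl, min_observed = 3) {
  x <- values[!is.na(values)]
  n <- length(x)
  if (n && min(x) < dl - 1e-9)
    stop("observed value below the stated detection limit")
  naive_mu <- if (n) mean(x) else NA_real_
  naive_sd <- if (n > 1) sd(x) else NA_real_
  fallback <- function() {
    structure(list(mu = naive_mu,
                   sigma = if (is.na(naive_sd) || naive_sd == 0) 1e-8
                           else naive_sd,
                   dl = dl, n_observed = n, converged = FALSE,
                   log_likelihood = NA_real_),
              class = "trunc_gauss_fit")
  }
  if (n < max(2L, min_observed) || is.na(naive_sd) || naive_sd == 0)
    return(fallback())

  negll <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    z <- (x - mu) / sigma
    a <- (dl - mu) / sigma
    ## log S(a) = log(1 - Phi(a)), computed stably in the upper tail
    -(sum(dnorm(z, log = TRUE)) - n * par[2] -
        n * pnorm(a, lower.tail = FALSE, log.p = TRUE))
  }
  start <- c(naive_mu, log(naive_sd))
  opt <- tryCatch(
    optim(start, negll, method = "Nelder-Mead",
          control = list(maxit = 2000, reltol = 1e-12)),
    error = function(e) NULL)
  if (is.null(opt) || !is.finite(opt$value)) return(fallback())
  structure(list(mu = opt$par[1], sigma = exp(opt$par[2]), dl = dl,
                 n_observed = n, converged = opt$convergence == 0,
                 log_likelihood = -opt$value),
            class = "trunc_gauss_fit")
}

#' Fit every metabolite of a matrix
#'
#' @param mat an [abundance_matrix()] (log10 stage of the pipeline).
#' @param dl detection limit; defaults to [estimate_detection_limit()].
#' @param config an [impute_config()].
#' @return data.frame, one row per metabolite: `metabolite_id`, `mu`,
#'   `sigma`, `dl`, `n_observed`, `converged`, `log_likelihood`.
#' @export
fit_matrix_truncated <- function(mat, dl = estimate_detection_limit(mat),
                                 config = impute_config()) {
  .assert_abundance(mat)
  fits <- lapply(colnames(mat$values), function(m) {
    f <- fit_truncated_gaussian(mat$values[, m], dl,
                                min_observed = config$min_observed_for_mle)
    data.frame(metabolite_id = m, mu = f$mu, sigma = f$sigma, dl = f$dl,
               n_observed = f$n_observed, converged = f$converged,
               log_likelihood = f$log_likelihood)
  })
  do.call(rbind, fits)
}

#' Standardize / back-transform with truncated-normal MLEs
#'
#' `standardize_matrix()` maps every present value `x` of metabolite `m`
#' to `(x - mu_m)/sigma_m`; `back_transform()` inverts it (`z -> mu_m +
#' sigma_m * z`) and tags the matrix as imputed.
#'
#' @param mat an [abundance_matrix()] at stage `"outlier-masked"`
#'   (standardize) or `"standardized"` (back-transform).
#' @param fits data.frame from [fit_matrix_truncated()], one row per
#'   matrix column.
#' @return the transformed `AbundanceMatrix`.
#' @export
standardize_matrix <- function(mat, fits) {
  .assert_abundance(mat)
  idx <- match(colnames(mat$values), fits$metabolite_id)
  if (anyNA(idx))
    stop("no truncated-Gaussian fit for: ",
         paste(head(colnames(mat$values)[is.na(idx)], 5), collapse = ", "))
  mat$values <- sweep(sweep(mat$values, 2, fits$mu[idx], "-"),
                      2, fits$sigma[idx], "/")
  .advance_stage(mat, "outlier-masked", "standardized")
}

#' @rdname standardize_matrix
#' @export
back_transform <- function(mat, fits) {
  .assert_abundance(mat)
  idx <- match(colnames(mat$values), fits$metabolite_id)
  if (anyNA(idx)) stop("missing fits for back-transformation")
  mat$values <- sweep(sweep(mat$values, 2, fits$sigma[idx], "*"),
                      2, fits$mu[idx], "+")
  .advance_stage(mat, "standardized", "imputed")
}

#' Correlation-weighted K-nearest-metabolite imputation
#'
#' For each missing cell (sample i, metabolite m), candidate neighbours
#' are the metabolites observed in sample i whose pairwise-complete
#' Pearson correlation with m rests on at least `min_shared_samples`
#' shared observations. The K candidates with largest |r| are averaged
#' with weights `|r_k| / sum |r|`, negating a neighbour's value when its
#' correlation is negative; fewer than K candidates means all are used,
#' and no candidate at all triggers the configured fallback.
#'
#' @param mat a standardized [abundance_matrix()] (stage
#'   `"standardized"`).
#' @param config an [impute_config()].
#' @param fits optional fits table; needed only for the `"half_dl"`
#'   fallback (to place DL/2 on the standardized scale).
#' @return list with `matrix` (complete, still standardized) and `log`
#'   (data.frame per imputed cell: `sample_id`, `metabolite_id`,
#'   `neighbours`, `correlations`, `weights`, `imputed`, `method`).
#' @export
knn_impute <- function(mat, config = impute_config(), fits = NULL) {
  .assert_abundance(mat)
  if (!identical(mat$stage, "standardized"))
    stop("expected a matrix at stage 'standardized' but got '",
         mat$stage, "'")
  v <- mat$values
  obs <- !is.na(v)
  if (!any(is.na(v)))
    return(list(matrix = mat,
                log = data.frame(sample_id = character(),
                                 metabolite_id = character(),
                                 neighbours = character(),
                                 correlations = character(),
                                 weights = character(),
                                 imputed = numeric(),
                                 method = character())))
  suppressWarnings(cmat <- cor(v, use = "pairwise.complete.obs"))
  shared <- crossprod(obs)  # pairwise-complete sample counts
  cmat[shared < config$min_shared_samples] <- NA
  diag(cmat) <- NA

  ids <- colnames(v)
  fallback_value <- function(m) {
    if (config$fallback == "column_mean") {
      val <- mean(v[, m], na.rm = TRUE)
      if (is.nan(val)) val <- 0
      return(val)
    }
    if (is.null(fits)) return(0)
    i <- match(m, fits$metabolite_id)
    ## DL/2 on the raw scale is dl - log10(2) on log10 values
    (fits$dl[i] - log10(2) - fits$mu[i]) / fits$sigma[i]
  }

  log_rows <- vector("list", sum(is.na(v)))
  li <- 0L
  miss <- which(is.na(v), arr.ind = TRUE)
  ## deterministic order: by metabolite then sample
  miss <- miss[order(miss[, 2], miss[, 1]), , drop = FALSE]
  for (r in seq_len(nrow(miss))) {
    i <- miss[r, 1]; m <- miss[r, 2]
    rr <- cmat[m, ]
    cand <- which(obs[i, ] & !is.na(rr) & abs(rr) > 0)
    li <- li + 1L
    if (!length(cand)) {
      val <- fallback_value(ids[m])
      log_rows[[li]] <- data.frame(sample_id = rownames(v)[i],
                                   metabolite_id = ids[m],
                                   neighbours = "", correlations = "",
                                   weights = "", imputed = val,
                                   method = config$fallback)
    } else {
      ## largest |r| first; ties broken by metabolite ID lexical order
      ord <- cand[order(-abs(rr[cand]), ids[cand])]
      sel <- ord[seq_len(min(config$k_neighbours, length(ord)))]
      w <- abs(rr[sel]) / sum(abs(rr[sel]))
      val <- sum(w * sign(rr[sel]) * v[i, sel])
      log_rows[[li]] <- data.frame(
        sample_id = rownames(v)[i], metabolite_id = ids[m],
        neighbours = paste(ids[sel], collapse = ";"),
        correlations = paste(sprintf("%.4f", rr[sel]), collapse = ";"),
        weights = paste(sprintf("%.4f", w), collapse = ";"),
        imputed = val, method = "knn")
    }
    v[i, m] <- val
  }
  mat$values <- v
  list(matrix = mat, log = do.call(rbind, log_rows[seq_len(li)]))
}

#' Full KNN-TN imputation of a normalized matrix
#'
#' Chains [estimate_detection_limit()], [fit_matrix_truncated()],
#' [standardize_matrix()], [knn_impute()] and [back_transform()].
#'
#' @param mat an [abundance_matrix()] at stage `"outlier-masked"`.
#' @param config an [impute_config()].
#' @return list with `matrix` (complete, stage `"imputed"`, original
#'   log10 scale), `fits`, `log`, `dl`.
#' @export
impute_knn_tn <- function(mat, config = impute_config()) {
  dl <- estimate_detection_limit(mat)
  fits <- fit_matrix_truncated(mat, dl, config)
  std <- standardize_matrix(mat, fits)
  knn <- knn_impute(std, config, fits)
  list(matrix = back_transform(knn$matrix, fits),
       fits = fits, log = knn$log, dl = dl)
}
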