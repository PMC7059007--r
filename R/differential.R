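## Patient-blocked differential abundance. Week is the fixed effect of
## interest; the repeated measures within a patient are modelled by an
## exchangeable (compound-symmetry) correlation, estimated per metabolite
## and pooled into a single consensus value, then used in a GLS fit per
## metabolite. Variances are moderated by empirical Bayes (scaled
## inverse-chi-square prior, hyperparameters by moment matching on the log
## variances), p-values from a t distribution on df + d0 degrees of
## freedom, and BH FDR control at 10% by default.

#' Design specification for the blocked differential analysis
#'
#' @param samples data.frame with `sample_id`, `patient_id`, `week`.
#' @param contrasts character vector naming the contrasts to test. For a
#'   three-week design (weeks w0 < w1 < w2, e.g. 0/6/12) the available
#'   names are `"W6+W12 vs W0"` (average treated effect), `"W6 vs W0"`,
#'   `"W12 vs W0"` and `"W12 vs W6"`, spelled with the actual week labels.
#' @return list of class `"design_spec"`: `samples`, `weeks`, `X` (fixed
#'   effects design), `L` (contrast matrix, contrasts x coefficients).
#' @export
design_spec <- function(samples, contrasts = NULL) {
  weeks <- sort(unique(samples$week))
  if (length(weeks) < 2)
    stop("design is singular: only one timepoint present")
  tab <- table(samples$patient_id)
  if (any(tab < 2))
    stop("every patient needs >= 2 timepoints; offending: ",
         paste(names(tab)[tab < 2], collapse = ", "))
  wf <- factor(samples$week, levels = weeks)
  X <- model.matrix(~wf)
  colnames(X) <- c("(Intercept)", paste0("W", weeks[-1]))
  p <- ncol(X)
  L <- NULL
  if (length(weeks) == 3) {
    w <- weeks
    L <- rbind(c(0, 0.5, 0.5), c(0, 1, 0), c(0, 0, 1), c(0, -1, 1))
    rownames(L) <- c(sprintf("W%g+W%g vs W%g", w[2], w[3], w[1]),
                     sprintf("W%g vs W%g", w[2], w[1]),
                     sprintf("W%g vs W%g", w[3], w[1]),
                     sprintf("W%g vs W%g", w[3], w[2]))
  } else {
    L <- matrix(0, length(weeks) - 1, p)
    for (i in seq_len(nrow(L))) L[i, i + 1] <- 1
    rownames(L) <- sprintf("W%g vs W%g", weeks[-1], weeks[1])
  }
  colnames(L) <- colnames(X)
  if (!is.null(contrasts)) {
    missing <- setdiff(contrasts, rownames(L))
    if (length(missing))
      stop("unknown contrast(s): ", paste(missing, collapse = ", "))
    L <- L[contrasts, , drop = FALSE]
  }
  if (anyDuplicated(rownames(L))) stop("contrast names must be unique")
  structure(list(samples = samples, weeks = weeks, X = X, L = L),
            class = "design_spec")
}

## Exchangeable intra-patient correlation from a matrix of fixed-effect
## residuals, pooled across metabolites on the atanh scale (clamped
## inside the valid compound-symmetry range). `df_fixed` is the number of
## fixed-effect parameters already removed from the residuals, so the
## error mean square uses the two-way layout's df:
## N - df_fixed - (n_patients - 1).
.consensus_rho <- function(resid, patient_id, df_fixed = 1) {
  pats <- unique(patient_id)
  k <- as.integer(table(patient_id)[1])
  n <- length(patient_id)
  df_b <- length(pats) - 1
  df_w <- max(n - df_fixed - df_b, 1)
  rho_one <- function(e) {
    pm <- tapply(e, patient_id, mean)
    ssb <- sum(table(patient_id)[pats] * (pm[pats] - mean(e))^2)
    ssw <- sum((e - pm[patient_id])^2)
    msb <- ssb / df_b
    msw <- ssw / df_w
    if (msw == 0 && msb == 0) return(0)
    if (msw == 0) return(0.99)
    (msb - msw) / (msb + (k - 1) * msw)
  }
  lo <- -1 / (k - 1) + 0.05
  rho <- apply(resid, 2, rho_one)
  rho <- pmin(pmax(rho, lo), 0.99)
  tanh(mean(atanh(rho)))
}

#' Fit the patient-blocked linear model to every metabolite
#'
#' Ordinary least squares on the week design first yields residuals from
#' which a per-metabolite exchangeable intra-patient correlation is
#' estimated (one-way ANOVA moment estimator) and pooled into a consensus
#' value; each metabolite is then refit by GLS under that common block
#' correlation. Returns, besides coefficients and contrast effects, two
#' residual matrices: `residuals` (week effect removed — model residuals)
#' and `residuals_patient` (patient means removed, week effect retained —
#' the matrix used for unsupervised clustering of treatment timepoints).
#'
#' @param mat complete [abundance_matrix()] (stage `"imputed"`, or any
#'   complete log-scale matrix).
#' @param design a [design_spec()].
#' @param rho optional fixed intra-patient correlation; when `NULL`
#'   (default) the pooled consensus estimate is used.
#' @return list: `effects` (contrasts x metabolites), `stdev_unscaled`
#'   (per contrast), `s2` (residual variance per metabolite), `df`
#'   (residual degrees of freedom), `coefficients`, `residuals`,
#'   `residuals_patient`, `consensus_rho`.
#' @export
fit_blocked_model <- function(mat, design, rho = NULL) {
  .assert_abundance(mat)
  Y <- mat$values
  if (anyNA(Y)) stop("blocked model requires a complete (imputed) matrix")
  samples <- design$samples
  idx <- match(rownames(Y), samples$sample_id)
  if (anyNA(idx)) stop("design does not cover every sample")
  samples <- samples[idx, , drop = FALSE]
  X <- design$X[idx, , drop = FALSE]
  n <- nrow(Y); p <- ncol(X)
  if (n <= p) stop("not enough samples for the week design")

  ## pass 1: OLS residuals -> consensus intra-patient correlation
  if (is.null(rho)) {
    qrX <- qr(X)
    beta_ols <- qr.coef(qrX, Y)
    res_ols <- Y - X %*% beta_ols
    rho <- .consensus_rho(res_ols, samples$patient_id, df_fixed = ncol(X))
  }

  ## pass 2: GLS under block-exchangeable correlation
  R <- diag(n)
  same <- outer(samples$patient_id, samples$patient_id, "==")
  R[same & !diag(n)] <- rho
  U <- chol(R)
  Xw <- backsolve(U, X, transpose = TRUE)
  Yw <- backsolve(U, Y, transpose = TRUE)
  qrW <- qr(Xw)
  beta <- qr.coef(qrW, Yw)
  dimnames(beta) <- list(colnames(X), colnames(Y))  # backsolve drops names
  resw <- Yw - Xw %*% beta
  df <- n - p
  s2 <- colSums(resw^2) / df
  XtXinv <- chol2inv(qr.R(qrW))
  L <- design$L
  effects <- L %*% beta
  stdev_unscaled <- sqrt(diag(L %*% XtXinv %*% t(L)))

  pat_means <- apply(Y, 2, function(y) tapply(y, samples$patient_id, mean))
  residuals_patient <- Y - pat_means[samples$patient_id, , drop = FALSE]

  list(effects = effects, stdev_unscaled = stdev_unscaled, s2 = s2,
       df = df, coefficients = beta, residuals = Y - X %*% beta,
       residuals_patient = residuals_patient, consensus_rho = rho,
       samples = samples)
}

## Inverse of the trigamma function (monotone decreasing on (0, Inf)).
.trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > trigamma(1e-8)) return(1e-8)
  exp(stats::uniroot(function(t) trigamma(exp(t)) - y,
                     lower = log(1e-8), upper = log(1e8),
                     tol = 1e-12)$root)
}

#' Empirical-Bayes variance moderation
#'
#' Assumes the per-metabolite sample variances follow a scaled F
#' distribution around a common prior variance `s0²` with prior degrees of
#' freedom `d0` (a scaled inverse-chi-square prior on the true variances).
#' `(d0, s0²)` are estimated in closed form by matching the mean and
#' variance of `log s²` to their theoretical values; posterior variances
#' are `(d0 s0² + df s²) / (d0 + df)`.
#'
#' @param s2 per-metabolite residual variances.
#' @param df residual degrees of freedom of each `s2`.
#' @param d0 optional: force the prior degrees of freedom (0 recovers the
#'   ordinary t-test; `Inf` fully pools the variances).
#' @return list: `s2_post`, `d0`, `s0_2`, `df_total` (= `df + d0`, capped
#'   for p-value use), `degenerate` flag.
#' @export
moderate_variances <- function(s2, df, d0 = NULL) {
  if (length(s2) < 10 && is.null(d0))
    stop("need >= 10 metabolites to estimate moderation hyperparameters")
  degenerate <- all(s2 < .Machine$double.eps)  # numerically zero variances
  if (degenerate)
    return(list(s2_post = s2, d0 = 0, s0_2 = 0, df_total = df,
                degenerate = TRUE))
  if (is.null(d0)) {
    z <- log(s2[s2 > 0])
    e <- z - digamma(df / 2) + log(df / 2)
    evar <- var(e) - trigamma(df / 2)
    if (!is.finite(evar) || evar <= 0) {
      ## no excess spread beyond chi-square sampling noise: variances are
      ## exchangeable, the prior scale is the plain mean
      d0 <- Inf
      s0_2 <- mean(s2)
    } else {
      d0 <- 2 * .trigamma_inverse(evar)
      s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
    }
  } else if (is.infinite(d0)) {
    s0_2 <- mean(s2)
  } else if (d0 == 0) {
    s0_2 <- 0
  } else {
    z <- log(s2[s2 > 0])
    e <- z - digamma(df / 2) + log(df / 2)
    s0_2 <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  }
  s2_post <- if (is.infinite(d0)) rep(s0_2, length(s2))
             else (d0 * s0_2 + df * s2) / (d0 + df)
  list(s2_post = s2_post, d0 = d0, s0_2 = s0_2, df_total = df + d0,
       degenerate = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (via [stats::p.adjust()]): monotone in p, capped
#' at 1; an empty input returns an empty vector.
#'
#' @param p numeric vector of p-values in \[0,1\].
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  p.adjust(p, method = "BH")
}

#' Moderated differential abundance across all contrasts
#'
#' Runs [fit_blocked_model()], moderates the variances, computes
#' moderated t statistics `effect / (s_post * stdev_unscaled)` and
#' two-sided p-values on `df + d0` degrees of freedom, and BH-adjusts
#' within each contrast.
#'
#' @param mat complete [abundance_matrix()].
#' @param design a [design_spec()].
#' @param d0 optional forced prior degrees of freedom (see
#'   [moderate_variances()]).
#' @param rho optional fixed intra-patient correlation (see
#'   [fit_blocked_model()]).
#' @return list: `table` (long data.frame `metabolite_id`, `contrast`,
#'   `effect`, `t_mod`, `p`, `q`, `df_total`), `fit` (the blocked-model
#'   fit), `moderation` (hyperparameters).
#' @export
differential_abundance <- function(mat, design, d0 = NULL, rho = NULL) {
  fit <- fit_blocked_model(mat, design, rho = rho)
  mod <- moderate_variances(fit$s2, fit$df, d0 = d0)
  ids <- colnames(fit$effects)
  tabs <- lapply(rownames(design$L), function(ct) {
    eff <- fit$effects[ct, ]
    if (mod$degenerate) {
      ## variances identically zero: effects are exact, call sign only
      p <- ifelse(eff == 0, 1, .Machine$double.xmin)
      t_mod <- ifelse(eff == 0, 0, sign(eff) * Inf)
      dft <- fit$df
    } else {
      se <- sqrt(mod$s2_post) * fit$stdev_unscaled[ct]
      t_mod <- ifelse(se > 0, eff / se,
                      ifelse(eff == 0, 0, sign(eff) * Inf))
      dft <- min(mod$df_total, 1e6)
      p <- 2 * pt(-abs(t_mod), df = dft)
    }
    data.frame(metabolite_id = ids, contrast = ct, effect = eff,
               t_mod = t_mod, p = p, q = bh_fdr(p), df_total = dft,
               row.names = NULL)
  })
  list(table = do.call(rbind, tabs), fit = fit, moderation = mod)
}

#' Volcano table for one contrast
#'
#' Per-metabolite effect, -log10 p, significance flag at `q <= fdr` and
#' super-pathway annotation, ordered by p then metabolite ID.
#'
#' @param results the `table` element of [differential_abundance()].
#' @param contrast contrast name present in `results`.
#' @param catalogue optional catalogue for super-pathway annotation.
#' @param fdr FDR threshold for the significance flag (default 0.10).
#' @return data.frame `metabolite_id`, `effect`, `neg_log10_p`, `q`,
#'   `significant`, `super_pathway`.
#' @export
volcano_table <- function(results, contrast, catalogue = NULL, fdr = 0.10) {
  if (!contrast %in% results$contrast)
    stop("unknown contrast: ", contrast)
  d <- results[results$contrast == contrast, , drop = FALSE]
  out <- data.frame(metabolite_id = d$metabolite_id, effect = d$effect,
                    neg_log10_p = -log10(d$p), q = d$q,
                    significant = d$q <= fdr)
  out$super_pathway <- if (is.null(catalogue)) NA_character_ else
    catalogue$super_pathway[match(out$metabolite_id,
                                  catalogue$metabolite_id)]
  out[order(d$p, out$metabolite_id), , drop = FALSE]
}
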