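test_that("noiseless planted shifts are recovered exactly", {
  # +1 log10 at weeks 6 and 12 for metabolite A, nothing elsewhere
  weeks <- rep(c(0, 6, 12), 6)
  pats <- rep(sprintf("P%d", 1:6), each = 3)
  v <- cbind(A = ifelse(weeks > 0, 1, 0), B = rep(0.3, 18))
  rownames(v) <- sprintf("%s_W%d", pats, weeks)
  samples <- data.frame(sample_id = rownames(v), patient_id = pats,
                        week = weeks, run_day = "D1")
  m <- abundance_matrix(v, samples, stage = "imputed")
  des <- design_spec(samples)
  fit <- fit_blocked_model(m, des, rho = 0)
  expect_equal(unname(fit$effects["W6+W12 vs W0", "A"]), 1.0,
               tolerance = 1e-12)
  expect_equal(unname(fit$effects["W12 vs W6", "A"]), 0, tolerance = 1e-12)
  # saturated no-noise data: all residuals zero
  expect_true(all(abs(fit$residuals) < 1e-12))
})

test_that("consensus correlation tracks the patient random effect", {
  # zero patient effect: consensus within +-0.1 of 0 over seeds
  rhos <- sapply(1:4, function(s) {
    cfg <- null_sim_config(120, seed = s, patient_sd = 0)
    sim <- log10_complete(cfg)
    fit_blocked_model(sim$matrix, design_spec(sim$matrix$samples))$consensus_rho
  })
  expect_true(all(abs(rhos) < 0.1))
  # strong patient effect: consensus near the true intraclass correlation
  cfg <- null_sim_config(200, seed = 5, patient_sd = 0.15)
  sim <- log10_complete(cfg)
  rho <- fit_blocked_model(sim$matrix,
                           design_spec(sim$matrix$samples))$consensus_rho
  icc <- 0.15^2 / (0.15^2 + 0.10^2)
  expect_lt(abs(rho - icc), 0.1)
})

test_that("effects are invariant to adding a per-sample constant", {
  cfg <- null_sim_config(30, seed = 6)
  sim <- log10_complete(cfg)
  des <- design_spec(sim$matrix$samples)
  f1 <- fit_blocked_model(sim$matrix, des)
  shifted <- sim$matrix
  shifted$values <- shifted$values + 3.7
  f2 <- fit_blocked_model(shifted, des)
  expect_equal(f1$effects, f2$effects, tolerance = 1e-10)
  expect_equal(f1$s2, f2$s2, tolerance = 1e-10)
})

test_that("moderation limits behave as prescribed", {
  cfg <- null_sim_config(60, seed = 7)
  sim <- log10_complete(cfg)
  des <- design_spec(sim$matrix$samples)
  fit <- fit_blocked_model(sim$matrix, des)

  # d0 = 0: ordinary t statistic per metabolite
  d0_0 <- differential_abundance(sim$matrix, des, d0 = 0)
  tb <- d0_0$table[d0_0$table$contrast == "W6+W12 vs W0", ]
  t_ord <- fit$effects["W6+W12 vs W0", ] /
    (sqrt(fit$s2) * fit$stdev_unscaled["W6+W12 vs W0"])
  expect_equal(tb$t_mod, unname(t_ord[tb$metabolite_id]), tolerance = 1e-10)
  p_ord <- 2 * pt(-abs(t_ord), df = fit$df)
  expect_equal(tb$p, unname(p_ord[tb$metabolite_id]), tolerance = 1e-10)

  # d0 = Inf: every posterior variance equals the prior
  mod_inf <- moderate_variances(fit$s2, fit$df, d0 = Inf)
  expect_equal(mod_inf$s2_post, rep(mod_inf$s0_2, length(fit$s2)))
})

test_that("moment matching recovers known moderation hyperparameters", {
  set.seed(8)
  m <- 2000; df <- 15; d0_true <- 8; s0_true <- 0.04
  sigma2 <- s0_true * d0_true / rchisq(m, d0_true)
  s2 <- sigma2 * rchisq(m, df) / df
  mod <- moderate_variances(s2, df)
  expect_lt(abs(mod$d0 - d0_true) / d0_true, 0.25)
  expect_lt(abs(mod$s0_2 - s0_true) / s0_true, 0.1)
  if (requireNamespace("limma", quietly = TRUE)) {
    fd <- limma::fitFDist(s2, df1 = df)
    expect_equal(mod$d0, fd$df2, tolerance = 0.02)
    expect_equal(mod$s0_2, fd$scale, tolerance = 0.02)
  }
})

test_that("blocked moderated fit agrees with limma at a shared correlation", {
  skip_if_not_installed("limma")
  cfg <- sim_config(n_metabolites_by_class = c(Lipid = 120),
                    affected_pathways = "histidine_metabolism",
                    effect_log10 = c("6" = 0.3, "12" = 0.3),
                    censor_quantile = 0, outlier_rate = 0, runday_sd = 0,
                    n_background_pathways = 0, seed = 3)
  gen <- generate_abundances(generate_catalogue(cfg), cfg)
  m <- gen$matrix
  m$values <- log10(m$values)
  m$stage <- "imputed"
  des <- design_spec(m$samples)
  Y <- t(m$values)
  dc <- limma::duplicateCorrelation(Y, des$X, block = m$samples$patient_id)
  rho_l <- dc$consensus.correlation

  ours <- differential_abundance(m, des, rho = rho_l)
  expect_lt(abs(ours$fit$consensus_rho - rho_l), 0.15)

  lfit <- limma::lmFit(Y, des$X, block = m$samples$patient_id,
                       correlation = rho_l)
  cm <- cbind(avg = c(0, 0.5, 0.5))
  rownames(cm) <- colnames(des$X)
  lfit2 <- limma::eBayes(limma::contrasts.fit(lfit, cm))
  tb <- ours$table[ours$table$contrast == "W6+W12 vs W0", ]
  expect_equal(tb$effect,
               unname(lfit2$coefficients[tb$metabolite_id, "avg"]),
               tolerance = 1e-8)
  expect_lt(max(abs(tb$t_mod - lfit2$t[tb$metabolite_id, "avg"])), 0.05)
  expect_gt(cor(tb$p, lfit2$p.value[tb$metabolite_id, "avg"]), 0.9999)
})

test_that("null p-values are uniform across all four contrasts", {
  cfg <- null_sim_config(500, seed = 11)
  sim <- log10_complete(cfg)
  d <- differential_abundance(sim$matrix, design_spec(sim$matrix$samples))
  for (ct in unique(d$table$contrast)) {
    ks <- suppressWarnings(
      ks.test(d$table$p[d$table$contrast == ct], "punif"))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("BH adjustment follows the step-up arithmetic", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(0.2), 0.2)
  expect_equal(bh_fdr(rep(0.07, 5)), rep(0.07, 5))
  expect_equal(bh_fdr(numeric(0)), numeric(0))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0,1\\]")
  # q is monotone in p and never below p
  set.seed(12)
  p <- runif(100)
  q <- bh_fdr(p)
  expect_true(all(q >= p - 1e-12))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # if all p >= alpha, no q < alpha
  p2 <- runif(50, 0.3, 1)
  expect_true(all(bh_fdr(p2) >= 0.3))
  # permutation equivariance
  perm <- sample(100)
  expect_equal(bh_fdr(p[perm]), q[perm])
})

test_that("volcano table flags planted effects and orders deterministically", {
  cfg <- sim_config(n_metabolites_by_class = c(`Amino Acid` = 100),
                    affected_pathways = "histidine_metabolism",
                    effect_log10 = c("6" = 0.5, "12" = 0.5),
                    affected_pathway_size = 10, noise_sd = 0.1,
                    censor_quantile = 0, outlier_rate = 0, runday_sd = 0,
                    n_background_pathways = 0, seed = 13)
  cat_ <- generate_catalogue(cfg)
  gen <- generate_abundances(cat_, cfg)
  m <- gen$matrix
  m$values <- log10(m$values)
  m$stage <- "imputed"
  d <- differential_abundance(m, design_spec(m$samples))
  vt <- volcano_table(d$table, "W6+W12 vs W0", cat_, fdr = 0.10)
  planted <- gen$truth$affected_metabolites
  expect_true(all(planted %in% vt$metabolite_id[vt$significant]))
  # planted metabolites occupy the smallest q-values
  expect_setequal(head(vt$metabolite_id, length(planted)), planted)
  expect_false(is.unsorted(-vt$neg_log10_p))
  expect_error(volcano_table(d$table, "no such contrast"), "unknown")
  # nothing significant -> no flags
  vt2 <- volcano_table(d$table, "W6+W12 vs W0", cat_, fdr = 1e-300)
  expect_equal(sum(vt2$significant), 0)
})

test_that("degenerate all-zero-variance input is flagged, not crashed", {
  weeks <- rep(c(0, 6, 12), 6)
  pats <- rep(sprintf("P%d", 1:6), each = 3)
  v <- matrix(rep(c(0, 1, 1), 6), 18, 12)
  dimnames(v) <- list(sprintf("%s_W%d", pats, weeks),
                      sprintf("M%02d", 1:12))
  samples <- data.frame(sample_id = rownames(v), patient_id = pats,
                        week = weeks, run_day = "D1")
  m <- abundance_matrix(v, samples, stage = "imputed")
  d <- differential_abundance(m, design_spec(samples), rho = 0)
  tb <- d$table[d$table$contrast == "W6+W12 vs W0", ]
  expect_true(d$moderation$degenerate)
  expect_true(all(tb$p < 1e-100))
  expect_true(all(tb$effect == 1))
})

test_that("single-timepoint designs are rejected", {
  samples <- data.frame(sample_id = c("a", "b"), patient_id = c("P1", "P1"),
                        week = c(0, 0), run_day = "D1")
  expect_error(design_spec(samples), "singular|one timepoint")
})
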