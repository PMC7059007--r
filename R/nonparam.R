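## Exact and permutation tests for tiny cohorts. The paired sign-flip
## Wilcoxon test enumerates all 2^n sign assignments of the per-patient
## differences (the only permutation scheme that preserves the paired
## structure of a two-condition design), so with 6 patients the smallest
## attainable two-sided p is 2/64 = 0.031 — the floor every significant
## paired comparison in this cohort sits on. The observed arrangement is
## always counted in the null, so p is never 0. Two-sidedness is by
## centred-statistic symmetry (|T - E[T]|), well defined under ties.

.perm_result <- function(statistic, p, null_size, exact, draws,
                         seed = NA_integer_, degenerate = FALSE) {
  structure(list(statistic = statistic, p_empirical = p,
                 null_size = null_size, exact = exact,
                 n_flips_or_draws = draws, seed = seed,
                 degenerate = degenerate),
            class = "perm_test_result")
}

#' @export
print.perm_test_result <- function(x, ...) {
  cat(sprintf("%s permutation test: statistic = %g, p = %.4g (null size %d)\n",
              if (x$exact) "Exact" else "Monte-Carlo",
              x$statistic, x$p_empirical, x$null_size))
  invisible(x)
}

#' Exact sign-flip Wilcoxon signed-rank test
#'
#' Computes the Wilcoxon signed-rank statistic W (sum of ranks of positive
#' differences; zero differences dropped, midranks for tied magnitudes)
#' and its two-sided empirical p-value against the sign-flip null: every
#' one of the `2^n` sign assignments of the paired differences, enumerated
#' exactly while `2^n <= max_enumeration`, sampled with `n_draws` Monte
#' Carlo flips otherwise. `p = #\{|W_null - E[W]| >= |W_obs - E[W]|\} /
#' null_size`, observed assignment included.
#'
#' @param pre,post equal-length paired per-patient vectors.
#' @param max_enumeration largest exact null size (default `2^20`).
#' @param n_draws Monte Carlo draws beyond that.
#' @param seed seed for the Monte Carlo branch.
#' @return a `perm_test_result`: `statistic`, `p_empirical`, `null_size`,
#'   `exact`, `n_flips_or_draws`, `seed`, `degenerate`.
#' @examples
#' # six concordant pairs: the attainable floor 2/64
#' signflip_wilcoxon(rep(0, 6), 1:6)$p_empirical  # 0.03125
#' @export
signflip_wilcoxon <- function(pre, post, max_enumeration = 2^20,
                              n_draws = 1e5, seed = 1L) {
  if (length(pre) != length(post))
    stop("'pre' and 'post' must have equal length")
  d <- post - pre
  d <- d[d != 0]
  n <- length(d)
  if (n == 0)
    return(.perm_result(0, 1, 1L, TRUE, 0L, degenerate = TRUE))
  ## doubled midranks are integers: exact tie comparisons on integer sums
  r2 <- as.integer(round(2 * rank(abs(d))))
  w_obs <- sum(r2[d > 0])
  e_w <- sum(r2) / 2
  dev_obs <- abs(w_obs - e_w)
  if (2^n <= max_enumeration) {
    ## subset sums of r2 over all sign assignments, by vector doubling
    sums <- 0
    for (r in r2) sums <- c(sums, sums + r)
    p <- mean(abs(sums - e_w) >= dev_obs - 1e-9)
    .perm_result(w_obs / 2, p, length(sums), TRUE, length(sums))
  } else {
    flips <- .with_seed(seed, matrix(runif(n_draws * n) < 0.5, n_draws, n))
    sums <- flips %*% r2
    ## observed assignment counted in the null
    p <- (sum(abs(sums - e_w) >= dev_obs - 1e-9) + 1) / (n_draws + 1)
    .perm_result(w_obs / 2, p, n_draws + 1L, FALSE, n_draws, seed = seed)
  }
}

#' Permutation Mann-Whitney test
#'
#' Mann-Whitney U for two independent groups with an empirical null built
#' from group relabelings: all `choose(n_a + n_b, n_a)` assignments
#' enumerated exactly while that count is at most `max_enumeration`,
#' Monte Carlo otherwise. Two-sided p by centred-statistic symmetry
#' (`E[U] = n_a n_b / 2`), observed labelling included.
#'
#' @param group_a,group_b nonempty numeric vectors.
#' @param max_enumeration largest exact null size (default 1e6).
#' @param n_draws Monte Carlo draws.
#' @param seed seed for the Monte Carlo branch.
#' @return a `perm_test_result`.
#' @export
perm_mann_whitney <- function(group_a, group_b, max_enumeration = 1e6,
                              n_draws = 1e5, seed = 1L) {
  na <- length(group_a); nb <- length(group_b)
  if (na == 0 || nb == 0) stop("both groups must be nonempty")
  pooled <- c(group_a, group_b)
  rk <- rank(pooled)
  u_of <- function(idx_a) sum(rk[idx_a]) - na * (na + 1) / 2
  u_obs <- u_of(seq_len(na))
  e_u <- na * nb / 2
  dev_obs <- abs(u_obs - e_u)
  n_comb <- choose(na + nb, na)
  if (n_comb <= max_enumeration) {
    assignments <- combn(na + nb, na)
    u_null <- colSums(matrix(rk[assignments], nrow = na)) -
      na * (na + 1) / 2
    p <- mean(abs(u_null - e_u) >= dev_obs - 1e-9)
    .perm_result(u_obs, p, ncol(assignments), TRUE, ncol(assignments))
  } else {
    u_null <- .with_seed(seed, vapply(seq_len(n_draws), function(i)
      u_of(sample.int(na + nb, na)), 0))
    p <- (sum(abs(u_null - e_u) >= dev_obs - 1e-9) + 1) / (n_draws + 1)
    .perm_result(u_obs, p, n_draws + 1L, FALSE, n_draws, seed = seed)
  }
}

#' Kruskal-Wallis test with Tukey HSD follow-up on ranks
#'
#' Tie-corrected Kruskal-Wallis H with its chi-square p-value (via
#' [stats::kruskal.test()]); when the null is rejected at `alpha`, all
#' pairwise group comparisons are performed by Tukey's honest significant
#' differences applied to the global midranks.
#'
#' @param groups list of >= 2 nonempty numeric vectors.
#' @param alpha gate for the Tukey follow-up (default 0.05).
#' @return list: `H`, `p`, `pairwise` (data.frame `comparison`, `diff`,
#'   `lwr`, `upr`, `p_adj`, or `NULL` when not rejected or H is
#'   degenerate).
#' @export
kruskal_tukey <- function(groups, alpha = 0.05) {
  if (length(groups) < 2) stop("need >= 2 groups")
  sizes <- lengths(groups)
  if (any(sizes == 0)) stop("every group must be nonempty")
  if (is.null(names(groups)))
    names(groups) <- sprintf("g%d", seq_along(groups))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  if (length(unique(x)) == 1)  # all values identical: H = 0, nothing to test
    return(list(H = 0, p = 1, pairwise = NULL))
  kw <- kruskal.test(x, g)
  pairwise <- NULL
  if (is.finite(kw$p.value) && kw$p.value <= alpha && length(groups) > 1) {
    rk <- rank(x)
    tk <- TukeyHSD(aov(rk ~ g))$g
    pairwise <- data.frame(comparison = rownames(tk),
                           diff = tk[, "diff"], lwr = tk[, "lwr"],
                           upr = tk[, "upr"], p_adj = tk[, "p adj"],
                           row.names = NULL)
  }
  list(H = unname(kw$statistic), p = kw$p.value, pairwise = pairwise)
}
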