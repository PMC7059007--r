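## Unsupervised k-means of patient-centred residuals. Lloyd's algorithm
## with k-means++ seeding is run with many restarts and the lowest-inertia
## solution kept; a per-iteration inertia trace is retained so the
## monotone-descent property can be asserted. The hand-rolled Lloyd loop
## exists because the restart/seeding policy and the iteration trace are
## part of the contract; stats::kmeans serves as an independent
## cross-check in the tests.

.kmeanspp_init <- function(X, k) {
  n <- nrow(X)
  centers <- numeric(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((X - matrix(X[centers[1], ], n, ncol(X), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1] <- sample.int(n, 1, prob = probs)
    nd <- rowSums((X - matrix(X[centers[j + 1], ], n, ncol(X),
                              byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  X[centers, , drop = FALSE]
}

.lloyd <- function(X, centers, max_iter = 100) {
  n <- nrow(X); k <- nrow(centers)
  assign_pts <- function(C) {
    d <- outer(rowSums(X^2), rep(1, k)) - 2 * X %*% t(C) +
      outer(rep(1, n), rowSums(C^2))
    list(lab = max.col(-d, ties.method = "first"),
         inertia = sum(d[cbind(seq_len(n), max.col(-d, "first"))]))
  }
  trace <- numeric(0)
  lab <- NULL
  for (it in seq_len(max_iter)) {
    a <- assign_pts(centers)
    trace <- c(trace, max(a$inertia, 0))
    if (!is.null(lab) && all(a$lab == lab)) break
    lab <- a$lab
    for (j in seq_len(k)) {
      if (any(lab == j)) {
        centers[j, ] <- colMeans(X[lab == j, , drop = FALSE])
      } else {
        ## empty cluster: reseed at the point farthest from its centre
        d2 <- rowSums((X - centers[lab, , drop = FALSE])^2)
        centers[j, ] <- X[which.max(d2), ]
        lab[which.max(d2)] <- j
      }
    }
  }
  a <- assign_pts(centers)
  list(labels = a$lab, centers = centers, inertia = max(a$inertia, 0),
       inertia_trace = c(trace, max(a$inertia, 0)))
}

#' k-means clustering of residual profiles
#'
#' Best-of-restarts Lloyd's algorithm with k-means++ seeding on
#' unit-variance standardized columns, Euclidean distance. Deterministic
#' given `seed`; the returned solution has the smallest inertia over all
#' restarts, and each restart's inertia trace is non-increasing.
#'
#' @param residuals complete numeric matrix, samples x metabolites
#'   (typically `residuals_patient` from [fit_blocked_model()]).
#' @param k number of clusters (default 3).
#' @param restarts number of k-means++ restarts (default 100).
#' @param seed integer seed.
#' @param standardize scale columns to unit variance first (default TRUE;
#'   zero-variance columns are left unscaled).
#' @return list of class `"cluster_assignment"`: `assignments`
#'   (data.frame `sample_id`, `cluster`, `distance_to_centroid`),
#'   `centers`, `inertia`, `inertia_trace` (best restart), `k`, `seed`.
#' @export
kmeans_residuals <- function(residuals, k = 3, restarts = 100, seed = 1L,
                             standardize = TRUE) {
  X <- as.matrix(residuals)
  if (anyNA(X)) stop("residual matrix must be complete")
  if (k > nrow(X))
    stop("k (", k, ") exceeds the number of samples (", nrow(X), ")")
  if (standardize) {
    s <- apply(X, 2, sd)
    s[is.na(s) | s == 0] <- 1
    X <- sweep(X, 2, s, "/")
  }
  best <- NULL
  .with_seed(seed, {
    for (r in seq_len(restarts)) {
      fit <- .lloyd(X, .kmeanspp_init(X, k))
      if (is.null(best) || fit$inertia < best$inertia) best <- fit
    }
  })
  d2 <- rowSums((X - best$centers[best$labels, , drop = FALSE])^2)
  ids <- rownames(X)
  if (is.null(ids)) ids <- sprintf("s%d", seq_len(nrow(X)))
  structure(list(
    assignments = data.frame(sample_id = ids, cluster = best$labels,
                             distance_to_centroid = sqrt(d2)),
    centers = best$centers, inertia = best$inertia,
    inertia_trace = best$inertia_trace, k = k, seed = seed),
    class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  cat("k-means assignment: k =", x$k, ", inertia =",
      format(x$inertia, digits = 6), "\n")
  print(table(cluster = x$assignments$cluster))
  invisible(x)
}

#' Silhouette-based diagnostic scan over k
#'
#' Mean silhouette width of [kmeans_residuals()] solutions for each
#' candidate k. Purely diagnostic; the pipeline default stays k = 3.
#'
#' @param residuals complete samples x metabolites matrix.
#' @param ks candidate cluster counts.
#' @param ... passed to [kmeans_residuals()].
#' @return data.frame `k`, `mean_silhouette`.
#' @export
silhouette_scan <- function(residuals, ks = 2:6, ...) {
  X <- as.matrix(residuals)
  D <- as.matrix(stats::dist(X))
  sil_for <- function(lab) {
    s <- vapply(seq_len(nrow(X)), function(i) {
      own <- lab == lab[i]
      a <- if (sum(own) > 1) mean(D[i, own & seq_len(nrow(X)) != i]) else 0
      b <- min(vapply(setdiff(unique(lab), lab[i]), function(cl)
        mean(D[i, lab == cl]), 0))
      if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    }, 0)
    mean(s)
  }
  data.frame(k = ks, mean_silhouette = vapply(ks, function(k) {
    if (k >= nrow(X)) return(NA_real_)
    sil_for(kmeans_residuals(residuals, k = k, ...)$assignments$cluster)
  }, 0))
}
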