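## Normalization of a raw abundance matrix, in fixed pipeline order:
## 1. drop partially characterised compounds and the Xenobiotics class,
## 2. rescale each metabolite to median 1 (adjusts for instrument run-day
##    tuning differences),
## 3. log10 transform,
## 4. mask data points more than z_max (default 4) SDs from the
##    metabolite mean.
## Stage tags on the matrix enforce the order.

#' Restrict a matrix to targeted, non-Xenobiotics metabolites
#'
#' Removes partially characterised (untargeted) compounds and every
#' metabolite in the `"Xenobiotics"` super-pathway. With the default
#' 867-compound catalogue (4 untargeted, 127 Xenobiotics) this retains
#' 736 metabolites. Column order is preserved.
#'
#' @param mat an [abundance_matrix()] at stage `"raw"`.
#' @param catalogue catalogue data.frame covering every matrix column.
#' @return the filtered `AbundanceMatrix`, still at stage `"raw"`.
#' @export
filter_targeted <- function(mat, catalogue) {
  .assert_abundance(mat)
  ids <- colnames(mat$values)
  hit <- match(ids, catalogue$metabolite_id)
  if (anyNA(hit))
    stop("metabolite(s) missing from catalogue: ",
         paste(head(ids[is.na(hit)], 5), collapse = ", "))
  keep <- catalogue$targeted[hit] &
    (is.na(catalogue$super_pathway[hit]) |
       catalogue$super_pathway[hit] != "Xenobiotics")
  ## untargeted compounds have no super-pathway; they are dropped by the
  ## targeted flag, so NA class only survives if explicitly targeted
  keep[is.na(keep)] <- FALSE
  mat$values <- mat$values[, keep, drop = FALSE]
  mat
}

#' Rescale each metabolite to median 1
#'
#' Divides every present value by the median of that metabolite's present
#' values, so each rescaled column has median exactly 1. With
#' `scope = "per_run_day"` the median is computed within each run-day
#' batch instead (the batch structure the step is meant to absorb).
#'
#' @param mat an [abundance_matrix()] at stage `"raw"`.
#' @param scope `"global"` (default) or `"per_run_day"`.
#' @return the matrix at stage `"rescaled"`.
#' @export
median_rescale <- function(mat, scope = c("global", "per_run_day")) {
  .assert_abundance(mat)
  scope <- match.arg(scope)
  v <- mat$values
  rescale_block <- function(block) {
    med <- apply(block, 2, median, na.rm = TRUE)
    if (anyNA(med))
      stop("metabolite(s) with zero present values: ",
           paste(head(colnames(block)[is.na(med)], 5), collapse = ", "))
    sweep(block, 2, med, "/")
  }
  if (scope == "global") {
    v <- rescale_block(v)
  } else {
    for (d in unique(mat$samples$run_day)) {
      rows <- mat$samples$run_day == d
      v[rows, ] <- rescale_block(v[rows, , drop = FALSE])
    }
  }
  mat$values <- v
  .advance_stage(mat, "raw", "rescaled")
}

#' Log10-transform all present values
#'
#' @param mat an [abundance_matrix()] at stage `"rescaled"`; all present
#'   values must be positive.
#' @return the matrix at stage `"log10"`.
#' @export
log10_transform <- function(mat) {
  .assert_abundance(mat)
  if (any(mat$values <= 0, na.rm = TRUE))
    stop("log10 transform requires strictly positive values")
  out <- mat
  out$values <- log10(mat$values)
  .advance_stage(out, "rescaled", "log10")
}

#' Mask per-metabolite outliers beyond z_max standard deviations
#'
#' For each metabolite, values with `|x - mean| / sd > z_max` (sample SD,
#' n-1 denominator, over present values) become missing. Applied once, not
#' iterated. A zero-SD column is never masked. Note that with a single
#' extreme point the largest attainable |z| is `(n-1)/sqrt(n)`, so columns
#' with fewer than 18 present values can never lose a cell at the default
#' `z_max = 4`.
#'
#' @param mat an [abundance_matrix()] at stage `"log10"`.
#' @param z_max positive z-score threshold (default 4).
#' @return list with `matrix` (stage `"outlier-masked"`) and `masked`
#'   (data.frame `sample_id`, `metabolite_id`, `value`, `z`).
#' @export
exclude_outliers <- function(mat, z_max = 4) {
  .assert_abundance(mat)
  if (z_max <= 0) stop("'z_max' must be positive")
  if (!identical(mat$stage, "log10"))
    stop("expected a matrix at stage 'log10' but got '", mat$stage, "'")
  v <- mat$values
  mu <- colMeans(v, na.rm = TRUE)
  s <- apply(v, 2, sd, na.rm = TRUE)
  z <- sweep(sweep(v, 2, mu, "-"), 2, s, "/")
  z[, is.na(s) | s == 0] <- 0
  mask <- !is.na(v) & abs(z) > z_max
  idx <- which(mask, arr.ind = TRUE)
  masked <- data.frame(sample_id = rownames(v)[idx[, 1]],
                       metabolite_id = colnames(v)[idx[, 2]],
                       value = v[idx], z = z[idx],
                       stringsAsFactors = FALSE)
  v[mask] <- NA_real_
  mat$values <- v
  list(matrix = .advance_stage(mat, "log10", "outlier-masked"),
       masked = masked)
}

#' Run the full normalization chain
#'
#' Convenience wrapper: [filter_targeted()], drop of never-detected
#' metabolites (columns with zero present values, which a reporting
#' platform would not list and which no rescaling can handle),
#' [median_rescale()], [log10_transform()], [exclude_outliers()],
#' collecting a provenance table of every cell removed or masked along
#' the way.
#'
#' @param mat raw [abundance_matrix()].
#' @param catalogue catalogue data.frame.
#' @param z_max outlier threshold.
#' @param rescale_scope passed to [median_rescale()].
#' @return list with `matrix` (stage `"outlier-masked"`) and `provenance`
#'   (data.frame `sample_id`, `metabolite_id`, `stage`, `reason`).
#' @export
preprocess <- function(mat, catalogue, z_max = 4,
                       rescale_scope = "global") {
  filt <- filter_targeted(mat, catalogue)
  dropped <- setdiff(colnames(mat$values), colnames(filt$values))
  prov <- if (length(dropped)) {
    data.frame(sample_id = NA_character_, metabolite_id = dropped,
               stage = "filter_targeted",
               reason = "untargeted or Xenobiotics")
  } else {
    data.frame(sample_id = character(), metabolite_id = character(),
               stage = character(), reason = character())
  }
  undetected <- colSums(!is.na(filt$values)) == 0
  if (any(undetected)) {
    prov <- rbind(prov,
                  data.frame(sample_id = NA_character_,
                             metabolite_id = colnames(filt$values)[undetected],
                             stage = "drop_undetected",
                             reason = "no observed value in any sample"))
    filt$values <- filt$values[, !undetected, drop = FALSE]
  }
  out <- exclude_outliers(log10_transform(median_rescale(filt,
                                                         rescale_scope)),
                          z_max = z_max)
  if (nrow(out$masked))
    prov <- rbind(prov,
                  data.frame(sample_id = out$masked$sample_id,
                             metabolite_id = out$masked$metabolite_id,
                             stage = "exclude_outliers",
                             reason = sprintf("|z| = %.2f > %g",
                                              abs(out$masked$z), z_max)))
  list(matrix = out$matrix, provenance = prov)
}
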