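## AbundanceMatrix: samples x metabolites values with sample metadata and a
## stage tag that enforces pipeline order.

.STAGES <- c("raw", "rescaled", "log10", "outlier-masked", "standardized",
             "imputed")

#' Construct an abundance matrix
#'
#' Container for a samples x metabolites abundance matrix together with its
#' sample metadata (patient, week, run day) and a processing-stage tag.
#' Missing cells are `NA`. Stage transitions are only allowed in pipeline
#' order (raw -> rescaled -> log10 -> outlier-masked -> standardized ->
#' imputed), which the stage-advancing helpers enforce.
#'
#' @param values numeric matrix, samples in rows, metabolites in columns;
#'   both dimnames required. `NA` marks a missing cell.
#' @param samples data.frame with columns `sample_id`, `patient_id`, `week`,
#'   `run_day`; one row per row of `values`, matched by `sample_id`.
#' @param stage processing stage, one of
#'   `c("raw","rescaled","log10","outlier-masked","standardized","imputed")`.
#' @return An object of class `"AbundanceMatrix"`: a list with elements
#'   `values`, `samples`, `stage`.
#' @examples
#' v <- matrix(c(1, 2, 4, 8), 2, 2,
#'             dimnames = list(c("P1_W0", "P1_W6"), c("M1", "M2")))
#' s <- data.frame(sample_id = c("P1_W0", "P1_W6"), patient_id = "P1",
#'                 week = c(0, 6), run_day = c("D1", "D2"))
#' abundance_matrix(v, s)
#' @export
abundance_matrix <- function(values, samples, stage = "raw") {
  stage <- match.arg(stage, .STAGES)
  if (!is.matrix(values) || !is.numeric(values))
    stop("'values' must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("'values' must have sample row names and metabolite column names")
  req <- c("sample_id", "patient_id", "week", "run_day")
  if (!all(req %in% names(samples)))
    stop("'samples' must have columns ", paste(req, collapse = ", "))
  if (nrow(samples) != nrow(values))
    stop("sample metadata rows (", nrow(samples),
         ") do not match matrix rows (", nrow(values), ")")
  samples <- samples[match(rownames(values), samples$sample_id), , drop = FALSE]
  if (anyNA(samples$sample_id))
    stop("every matrix row must have a matching 'sample_id' in 'samples'")
  rownames(samples) <- NULL
  if (stage %in% c("raw", "rescaled")) {
    bad <- which(!is.na(values) & values <= 0)
    if (length(bad))
      stop("stage '", stage, "' requires all present values > 0; found ",
           length(bad), " nonpositive cell(s)")
  }
  structure(list(values = values, samples = samples, stage = stage),
            class = "AbundanceMatrix")
}

#' @export
print.AbundanceMatrix <- function(x, ...) {
  v <- x$values
  cat("AbundanceMatrix: ", nrow(v), " samples x ", ncol(v),
      " metabolites [stage: ", x$stage, "]\n", sep = "")
  cat("  missing cells: ", sum(is.na(v)),
      sprintf(" (%.1f%%)", 100 * mean(is.na(v))), "\n", sep = "")
  cat("  patients: ", length(unique(x$samples$patient_id)),
      "; weeks: ", paste(sort(unique(x$samples$week)), collapse = "/"),
      "; run days: ", length(unique(x$samples$run_day)), "\n", sep = "")
  invisible(x)
}

#' @export
dim.AbundanceMatrix <- function(x) dim(x$values)

## Advance the stage tag, refusing to skip or reverse pipeline order.
.advance_stage <- function(mat, from, to) {
  if (!identical(mat$stage, from))
    stop("expected a matrix at stage '", from, "' but got '", mat$stage, "'")
  stopifnot(match(to, .STAGES) > match(from, .STAGES))
  mat$stage <- to
  mat
}

.assert_abundance <- function(mat) {
  if (!inherits(mat, "AbundanceMatrix"))
    stop("expected an 'AbundanceMatrix' (see abundance_matrix())")
  invisible(mat)
}
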