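## File formats: TSV abundance matrix (first column sample_id; metadata
## columns patient_id, week, run_day; remaining columns metabolite IDs;
## empty cell = missing), catalogue CSV, GMT pathway membership, two-column
## undirected edge-list TSV, JSON ground truth.

#' Write / read an abundance matrix as TSV
#'
#' The on-disk dialect has one row per sample: `sample_id`, `patient_id`,
#' `week`, `run_day`, then one column per metabolite. Missing cells are
#' written as empty fields.
#'
#' @param mat an [abundance_matrix()].
#' @param path file path.
#' @return `write_abundance_tsv()` returns `path` invisibly;
#'   `read_abundance_tsv()` returns an `AbundanceMatrix`.
#' @param stage stage tag to assign on read.
#' @export
write_abundance_tsv <- function(mat, path) {
  .assert_abundance(mat)
  df <- cbind(mat$samples[c("sample_id", "patient_id", "week", "run_day")],
              as.data.frame(mat$values, check.names = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_abundance_tsv
#' @export
read_abundance_tsv <- function(path, stage = "raw") {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   na.strings = "",
                   colClasses = c(sample_id = "character",
                                  patient_id = "character",
                                  run_day = "character"))
  meta <- c("sample_id", "patient_id", "week", "run_day")
  values <- as.matrix(df[setdiff(names(df), meta)])
  rownames(values) <- df$sample_id
  abundance_matrix(values, df[meta], stage = stage)
}

#' Write / read a metabolite catalogue as CSV
#'
#' Columns: `metabolite_id`, `name`, `super_pathway`, `targeted` (logical;
#' FALSE marks partially characterised compounds), `pathway_ids`
#' (semicolon-separated, empty when unannotated).
#'
#' @param catalogue data.frame as returned by [generate_catalogue()].
#' @param path file path.
#' @export
write_catalogue_csv <- function(catalogue, path) {
  write.csv(catalogue, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

#' @rdname write_catalogue_csv
#' @export
read_catalogue_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE,
                 colClasses = c(metabolite_id = "character",
                                pathway_ids = "character"))
  df$targeted <- as.logical(df$targeted)
  df$pathway_ids[is.na(df$pathway_ids)] <- ""
  df$super_pathway[!is.na(df$super_pathway) &
                     df$super_pathway == ""] <- NA_character_
  df
}

#' Read / write pathway membership in GMT format
#'
#' One pathway per line: ID, description, then member metabolite IDs,
#' tab-separated.
#'
#' @param pathways named list of character vectors (member IDs); names are
#'   pathway IDs. Descriptions are taken from the `"description"` attribute
#'   of each element when present.
#' @param path file path.
#' @return `read_gmt()` returns a named list of character vectors with a
#'   `"description"` attribute per element.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line (need id, description, >=1 member): ", ln)
    members <- parts[-(1:2)]
    attr(members, "description") <- parts[2]
    members
  })
  names(out) <- vapply(lines, function(ln)
    strsplit(ln, "\t", fixed = TRUE)[[1]][1], "")
  out
}

#' @rdname read_gmt
#' @export
write_gmt <- function(pathways, path) {
  lines <- vapply(names(pathways), function(id) {
    m <- pathways[[id]]
    desc <- attr(m, "description")
    if (is.null(desc)) desc <- id
    paste(c(id, desc, as.character(m)), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write undirected pathway edge lists
#'
#' TSV with columns `pathway_id`, `from`, `to`; one undirected edge per
#' row. Returned as a named list of two-column character matrices.
#'
#' @param edges named list of 2-column matrices (or `NULL` entries).
#' @param path file path.
#' @export
write_edges_tsv <- function(edges, path) {
  rows <- do.call(rbind, lapply(names(edges), function(id) {
    e <- edges[[id]]
    if (is.null(e) || nrow(e) == 0) return(NULL)
    data.frame(pathway_id = id, from = e[, 1], to = e[, 2])
  }))
  if (is.null(rows))
    rows <- data.frame(pathway_id = character(), from = character(),
                       to = character())
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edges_tsv
#' @export
read_edges_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   colClasses = "character")
  split_rows <- split(df, df$pathway_id)
  lapply(split_rows, function(d) as.matrix(d[c("from", "to")]))
}
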