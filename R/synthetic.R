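## Synthetic serum-metabolomics generator. Emulates the assumed
## data-generating process of a 6-patient x 3-timepoint cohort: log10-scale
## patient random effects, treatment shifts concentrated in designated
## pathways, per-run-day batch factors, left censoring at a global
## detection limit, and rare extreme spikes. Ground truth is always
## returned alongside the data so parameter recovery can be tested.

## Run expr with a private RNG stream, restoring the caller's state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## Printed super-pathway breakdown of the 867-compound serum catalogue.
.DEFAULT_CLASS_COUNTS <- c(
  "Amino Acid" = 187, "Carbohydrate" = 27, "Cofactors and Vitamins" = 28,
  "Energy" = 11, "Lipid" = 409, "Nucleotide" = 37, "Peptide" = 37,
  "Xenobiotics" = 127, "Partially Characterised" = 4)

#' Simulation configuration
#'
#' Parameters of the synthetic cohort. Defaults reproduce the study
#' conditions: 6 patients at weeks 0/6/12, the printed 867-metabolite
#' super-pathway breakdown (including 127 Xenobiotics and 4 partially
#' characterised compounds), treatment shifts of +0.3 log10 at weeks 6 and
#' 12 concentrated in three designated pathways, a patient random effect
#' of 0.15 log10 SD, residual noise of 0.10 log10 SD, per-run-day batch
#' factors of 0.05 log10 SD, 10% left censoring at the detection limit and
#' a 1/1000 rate of extreme spikes.
#'
#' @param n_patients number of patients.
#' @param weeks ordered numeric timepoint labels; the first is untreated.
#' @param n_metabolites_by_class named integer vector, super-pathway ->
#'   count. The reserved class `"Partially Characterised"` is generated
#'   untargeted (no super-pathway, `targeted = FALSE`).
#' @param affected_pathways character IDs of pathways carrying treatment
#'   effects.
#' @param effect_log10 named numeric vector, week label -> log10 shift,
#'   applied to members of every affected pathway at that week; or a list
#'   of such vectors, one per affected pathway.
#' @param patient_sd,noise_sd,runday_sd log10-scale standard deviations of
#'   the patient random effect, residual noise and run-day batch factor.
#' @param censor_quantile fraction in \[0,1) of the value distribution
#'   censored at the detection limit.
#' @param outlier_rate per-cell probability of an extreme spike.
#' @param outlier_shift_log10 log10 magnitude of a spike.
#' @param affected_pathway_size members per affected pathway (>= 5).
#' @param n_background_pathways number of additional null pathways.
#' @param background_size_range inclusive size range of null pathways.
#' @param seed integer RNG seed.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_patients = 6,
                       weeks = c(0, 6, 12),
                       n_metabolites_by_class = .DEFAULT_CLASS_COUNTS,
                       affected_pathways = c("histidine_metabolism",
                                             "alanine_aspartate_glutamate_metabolism",
                                             "tca_cycle"),
                       effect_log10 = c("6" = 0.3, "12" = 0.3),
                       patient_sd = 0.15,
                       noise_sd = 0.10,
                       runday_sd = 0.05,
                       censor_quantile = 0.10,
                       outlier_rate = 0.001,
                       outlier_shift_log10 = 3,
                       affected_pathway_size = 12,
                       n_background_pathways = 20,
                       background_size_range = c(8, 25),
                       seed = 1L) {
  if (n_patients < 1) stop("'n_patients' must be positive")
  if (length(weeks) < 2) stop("need at least two timepoints")
  counts <- n_metabolites_by_class
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("'n_metabolites_by_class' must be a named vector")
  if (any(counts < 0) || sum(counts) < 1)
    stop("class counts must be nonnegative with positive total")
  if (censor_quantile < 0 || censor_quantile >= 1)
    stop("'censor_quantile' must be in [0, 1)")
  for (s in c(patient_sd, noise_sd, runday_sd))
    if (s < 0) stop("standard deviations must be >= 0")
  if (outlier_rate < 0 || outlier_rate > 1)
    stop("'outlier_rate' must be a probability")
  if (length(affected_pathways) && affected_pathway_size < 5)
    stop("affected pathways need >= 5 members")
  if (!is.list(effect_log10))
    effect_log10 <- rep(list(effect_log10), length(affected_pathways))
  if (length(effect_log10) != length(affected_pathways))
    stop("'effect_log10' must give one shift vector per affected pathway")
  names(effect_log10) <- affected_pathways
  structure(list(
    n_patients = as.integer(n_patients), weeks = weeks,
    n_metabolites_by_class = counts,
    affected_pathways = affected_pathways, effect_log10 = effect_log10,
    patient_sd = patient_sd, noise_sd = noise_sd, runday_sd = runday_sd,
    censor_quantile = censor_quantile, outlier_rate = outlier_rate,
    outlier_shift_log10 = outlier_shift_log10,
    affected_pathway_size = as.integer(affected_pathway_size),
    n_background_pathways = as.integer(n_background_pathways),
    background_size_range = as.integer(background_size_range),
    seed = as.integer(seed)), class = "sim_config")
}

#' Generate a metabolite catalogue
#'
#' Builds a catalogue with exactly the configured number of metabolites per
#' super-pathway class, flags the `"Partially Characterised"` class as
#' untargeted, and assigns pathway memberships: each affected pathway draws
#' `affected_pathway_size` members (without overlap) from targeted
#' non-Xenobiotics compounds of a thematically matching class, and
#' background pathways draw from the same pool with overlap allowed.
#'
#' @param config a [sim_config()].
#' @return data.frame with columns `metabolite_id`, `name`,
#'   `super_pathway`, `targeted`, `pathway_ids` (semicolon-separated).
#' @seealso [catalogue_pathways()] to recover the pathway -> members list.
#' @export
generate_catalogue <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  counts <- config$n_metabolites_by_class
  total <- sum(counts)
  if (total == 0) stop("catalogue would contain zero metabolites")
  .with_seed(config$seed, {
    cls <- rep(names(counts), counts)
    id <- sprintf("M%0*d", max(4L, nchar(total)), seq_len(total))
    untargeted <- cls == "Partially Characterised"
    cat <- data.frame(
      metabolite_id = id,
      name = paste0("metabolite_", id),
      super_pathway = ifelse(untargeted, NA_character_, cls),
      targeted = !untargeted,
      pathway_ids = "",
      stringsAsFactors = FALSE)

    eligible <- cat$targeted & !is.na(cat$super_pathway) &
      cat$super_pathway != "Xenobiotics"
    pool_for <- function(pw) {
      ## thematic class affinity for the default affected pathways;
      ## anything else draws from the whole eligible pool
      aa <- eligible & cat$super_pathway == "Amino Acid"
      en <- eligible & cat$super_pathway %in% c("Energy", "Carbohydrate")
      if (grepl("histidine|alanine|amino", pw) && sum(aa)) which(aa)
      else if (grepl("tca|citrate|energy", pw) && sum(en)) which(en)
      else which(eligible)
    }
    membership <- list()
    taken <- integer(0)
    for (pw in config$affected_pathways) {
      pool <- setdiff(pool_for(pw), taken)
      if (length(pool) < config$affected_pathway_size)
        pool <- setdiff(which(eligible), taken)
      if (length(pool) < 5)
        stop("not enough eligible metabolites to populate pathway '", pw, "'")
      sel <- sort(sample(pool, min(config$affected_pathway_size,
                                   length(pool))))
      membership[[pw]] <- sel
      taken <- c(taken, sel)
    }
    if (config$n_background_pathways > 0 && sum(eligible) >= 5) {
      rng <- config$background_size_range
      for (i in seq_len(config$n_background_pathways)) {
        sz <- sample(rng[1]:rng[2], 1)
        sel <- sort(sample(which(eligible), min(sz, sum(eligible))))
        membership[[sprintf("background_%02d", i)]] <- sel
      }
    }
    for (pw in names(membership)) {
      idx <- membership[[pw]]
      has <- nzchar(cat$pathway_ids[idx])
      cat$pathway_ids[idx] <- ifelse(has,
                                     paste(cat$pathway_ids[idx], pw, sep = ";"),
                                     pw)
    }
    cat
  })
}

#' Pathway membership list from a catalogue
#'
#' Inverts the semicolon-separated `pathway_ids` column into a named list
#' pathway ID -> member metabolite IDs, suitable for [write_gmt()] and
#' [enrich()].
#'
#' @param catalogue a catalogue data.frame.
#' @return named list of character vectors.
#' @export
catalogue_pathways <- function(catalogue) {
  ann <- which(nzchar(catalogue$pathway_ids))
  pairs <- lapply(ann, function(i)
    data.frame(pw = strsplit(catalogue$pathway_ids[i], ";")[[1]],
               id = catalogue$metabolite_id[i]))
  if (!length(pairs)) return(list())
  pairs <- do.call(rbind, pairs)
  out <- lapply(split(pairs$id, pairs$pw), function(m) {
    m <- sort(unique(m))
    attr(m, "description") <- ""
    m
  })
  out[order(names(out))]
}

#' Generate random connected pathway graphs
#'
#' One undirected graph per pathway: a random spanning tree over the
#' members plus extra edges added independently with probability
#' `extra_edge_prob`. Used for the topology-impact score.
#'
#' @param pathways named list of member ID vectors (see
#'   [catalogue_pathways()]).
#' @param extra_edge_prob probability of each non-tree edge.
#' @param seed integer seed.
#' @return named list of two-column character edge matrices.
#' @export
generate_pathway_graphs <- function(pathways, extra_edge_prob = 0.15,
                                    seed = 1L) {
  .with_seed(seed, {
    out <- lapply(pathways, function(members) {
      n <- length(members)
      if (n < 2) return(matrix(character(0), 0, 2))
      ord <- sample(members)
      tree <- cbind(ord[-1],
                    vapply(2:n, function(i) ord[sample.int(i - 1, 1)], ""))
      extra <- NULL
      if (n > 2) {
        all_pairs <- t(combn(sort(members), 2))
        key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]))
        free <- all_pairs[!(key(all_pairs) %in% key(tree)), , drop = FALSE]
        keep <- runif(nrow(free)) < extra_edge_prob
        extra <- free[keep, , drop = FALSE]
      }
      unname(rbind(tree, extra))
    })
    out
  })
}

#' Generate a synthetic abundance matrix with ground truth
#'
#' Raw values are `10^(true_mu + patient effect + week effect + run-day
#' factor + noise)`. Cells whose log10 value falls below the global
#' empirical `censor_quantile` are deleted (left-censoring at the
#' detection limit, MNAR); surviving cells spike with probability
#' `outlier_rate`. Samples are assigned to run days by visit week.
#'
#' @param catalogue catalogue from [generate_catalogue()] (must be
#'   consistent with `config`).
#' @param config a [sim_config()].
#' @return list with elements `matrix` (an [abundance_matrix()] at stage
#'   `"raw"`) and `truth` (list: `true_mu`, `true_effect`
#'   (metabolites x weeks log10 shifts), `patient_effects`,
#'   `runday_effects`, `dl_log10`, `censored_cells`, `outlier_cells`,
#'   `affected_metabolites`).
#' @export
generate_abundances <- function(catalogue, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  total <- sum(config$n_metabolites_by_class)
  if (nrow(catalogue) != total)
    stop("catalogue size (", nrow(catalogue),
         ") does not match config total (", total, ")")
  .with_seed(config$seed + 1L, {
    patients <- sprintf("P%d", seq_len(config$n_patients))
    weeks <- config$weeks
    samples <- expand.grid(patient_id = patients, week = weeks,
                           KEEP.OUT.ATTRS = FALSE,
                           stringsAsFactors = FALSE)
    samples <- samples[order(samples$patient_id, samples$week), ]
    samples$sample_id <- sprintf("%s_W%g", samples$patient_id, samples$week)
    ## run days partitioned by visit week (one batch per visit)
    samples$run_day <- sprintf("D%d", match(samples$week, weeks))
    rownames(samples) <- NULL

    m_ids <- catalogue$metabolite_id
    n_s <- nrow(samples); n_m <- length(m_ids)
    true_mu <- setNames(rnorm(n_m, mean = 4, sd = 1), m_ids)
    patient_effects <- setNames(rnorm(length(patients), 0, config$patient_sd),
                                patients)
    rundays <- unique(samples$run_day)
    runday_effects <- setNames(rnorm(length(rundays), 0, config$runday_sd),
                               rundays)

    true_effect <- matrix(0, n_m, length(weeks),
                          dimnames = list(m_ids, as.character(weeks)))
    pw_members <- catalogue_pathways(catalogue)
    for (pw in config$affected_pathways) {
      members <- intersect(pw_members[[pw]], m_ids)
      shift <- config$effect_log10[[pw]]
      for (w in names(shift))
        true_effect[members, w] <- true_effect[members, w] + shift[[w]]
    }

    logv <- matrix(true_mu, n_s, n_m, byrow = TRUE) +
      patient_effects[samples$patient_id] +
      t(true_effect[, as.character(samples$week), drop = FALSE]) +
      runday_effects[samples$run_day] +
      matrix(rnorm(n_s * n_m, 0, config$noise_sd), n_s, n_m)
    dimnames(logv) <- list(samples$sample_id, m_ids)

    censored <- matrix(FALSE, n_s, n_m, dimnames = dimnames(logv))
    dl_log10 <- -Inf
    if (config$censor_quantile > 0) {
      dl_log10 <- quantile(logv, config$censor_quantile, names = FALSE)
      censored <- logv < dl_log10
    }
    spikes <- matrix(rbinom(n_s * n_m, 1, config$outlier_rate) == 1,
                     n_s, n_m, dimnames = dimnames(logv)) & !censored
    values <- 10^(logv + spikes * config$outlier_shift_log10)
    values[censored] <- NA_real_

    cells_df <- function(mask, pre) {
      idx <- which(mask, arr.ind = TRUE)
      data.frame(sample_id = rownames(mask)[idx[, 1]],
                 metabolite_id = colnames(mask)[idx[, 2]],
                 log10_pre = pre[idx], stringsAsFactors = FALSE)
    }
    truth <- list(
      true_mu = true_mu,
      true_effect = true_effect,
      patient_effects = patient_effects,
      runday_effects = runday_effects,
      dl_log10 = dl_log10,
      censored_cells = cells_df(censored, logv),
      outlier_cells = cells_df(spikes, logv),
      log10_clean = logv,
      affected_metabolites = m_ids[rowSums(abs(true_effect)) > 0])

    list(matrix = abundance_matrix(values,
                                   samples[c("sample_id", "patient_id",
                                             "week", "run_day")]),
         truth = truth)
  })
}

#' Write simulation ground truth as JSON
#'
#' @param truth the `truth` element of [generate_abundances()].
#' @param path file path.
#' @export
write_truth_json <- function(truth, path) {
  out <- truth
  out$true_effect <- as.data.frame(out$true_effect)
  out$log10_clean <- NULL  # bulky; regenerable from the seed
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns", pretty = TRUE)
  invisible(path)
}
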