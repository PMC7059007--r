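# Shared fixtures and independent oracles used across the suite.

# Tiny catalogue covering the filtering rules: n_targeted ordinary
# compounds, n_xeno Xenobiotics, n_untargeted partially characterised.
tiny_catalogue <- function(n_targeted = 6, n_xeno = 3, n_untargeted = 1,
                           class_ = "Lipid") {
  n <- n_targeted + n_xeno + n_untargeted
  data.frame(
    metabolite_id = sprintf("M%03d", seq_len(n)),
    name = sprintf("met_%03d", seq_len(n)),
    super_pathway = c(rep(class_, n_targeted), rep("Xenobiotics", n_xeno),
                      rep(NA_character_, n_untargeted)),
    targeted = c(rep(TRUE, n_targeted + n_xeno), rep(FALSE, n_untargeted)),
    pathway_ids = "", stringsAsFactors = FALSE)
}

# AbundanceMatrix wrapper around a bare matrix with default 6x3 metadata.
toy_matrix <- function(values, stage = "raw", weeks = NULL) {
  n <- nrow(values)
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%02d", seq_len(n))
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("M%03d", seq_len(ncol(values)))
  if (is.null(weeks)) weeks <- rep_len(c(0, 6, 12), n)
  samples <- data.frame(sample_id = rownames(values),
                        patient_id = sprintf("P%d", rep(seq_len(ceiling(n / 3)),
                                                        each = 3)[seq_len(n)]),
                        week = weeks,
                        run_day = sprintf("D%d", match(weeks, sort(unique(weeks)))))
  abundance_matrix(values, samples, stage = stage)
}

# Small null simulation used by several differential tests: one class,
# no treatment effects, optionally no censoring.
null_sim_config <- function(n_metab, seed, censor = 0, patient_sd = 0.15,
                            runday_sd = 0) {
  sim_config(n_metabolites_by_class = c(Lipid = n_metab),
             affected_pathways = character(0), effect_log10 = list(),
             patient_sd = patient_sd, runday_sd = runday_sd,
             censor_quantile = censor, outlier_rate = 0,
             n_background_pathways = 0, seed = seed)
}

# Complete log10-scale matrix straight from the generator (skipping the
# normalization chain), tagged imputed so the model accepts it.
log10_complete <- function(cfg) {
  gen <- generate_abundances(generate_catalogue(cfg), cfg)
  m <- gen$matrix
  m$values <- log10(m$values)
  m$stage <- "imputed"
  list(matrix = m, truth = gen$truth)
}

# Exhaustive-path-counting betweenness oracle: enumerates every simple
# path between each node pair, keeps the shortest ones, and credits each
# interior vertex its share; normalized per component by
# (n_c - 1)(n_c - 2)/2. Independent of igraph's Brandes algorithm.
brute_relative_betweenness <- function(edges, nodes) {
  adj <- setNames(lapply(nodes, function(v) character(0)), nodes)
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    if (a != b) {
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  all_paths <- function(s, t) {
    found <- list()
    rec <- function(path) {
      last <- path[length(path)]
      if (last == t) {
        found[[length(found) + 1]] <<- path
        return()
      }
      for (nb in adj[[last]]) if (!nb %in% path) rec(c(path, nb))
    }
    rec(s)
    found
  }
  comp_of <- setNames(rep(NA_integer_, length(nodes)), nodes)
  ci <- 0
  for (v in nodes) if (is.na(comp_of[v])) {
    ci <- ci + 1
    frontier <- v
    while (length(frontier)) {
      comp_of[frontier] <- ci
      frontier <- setdiff(unique(unlist(adj[frontier])),
                          names(comp_of)[!is.na(comp_of)])
    }
  }
  btw <- setNames(rep(0, length(nodes)), nodes)
  for (s_i in seq_along(nodes)) for (t_i in seq_len(s_i - 1)) {
    s <- nodes[s_i]; t <- nodes[t_i]
    if (comp_of[s] != comp_of[t]) next
    ps <- all_paths(s, t)
    if (!length(ps)) next
    lens <- lengths(ps)
    sp <- ps[lens == min(lens)]
    for (p in sp) for (v in setdiff(p, c(s, t)))
      btw[v] <- btw[v] + 1 / length(sp)
  }
  for (v in nodes) {
    nc <- sum(comp_of == comp_of[v])
    btw[v] <- if (nc > 2) btw[v] / ((nc - 1) * (nc - 2) / 2) else 0
  }
  btw
}

# Adjusted Rand index between two partitions.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_comb <- function(x) sum(choose(x, 2))
  sij <- sum_comb(tab)
  si <- sum_comb(rowSums(tab))
  sj <- sum_comb(colSums(tab))
  expected <- si * sj / choose(n, 2)
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# Plain Rand index (used for label-equivariance checks).
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  idx <- upper.tri(same_a)
  mean(same_a[idx] == same_b[idx])
}
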