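## Pathway over-representation (one-sided hypergeometric) with Holm
## step-down familywise control, and a topology "impact" score: the share
## of the pathway's relative-betweenness centrality carried by the hit
## metabolites.

#' Hypergeometric pathway over-representation
#'
#' For each pathway, tests whether the hit set is over-represented among
#' the pathway's members within the universe: `p_raw = P(X >= n_hits)`
#' with X hypergeometric(|universe|, |members in universe|, |hits|).
#' Pathways with no member in the universe are skipped (recorded in the
#' `skipped` attribute). One-sided over-representation only.
#'
#' @param hits character vector of significant metabolite IDs (must be a
#'   subset of `universe`).
#' @param universe character vector of all tested metabolite IDs.
#' @param pathways named list of member ID vectors (e.g. [read_gmt()]).
#' @return data.frame `pathway_id`, `n_hits`, `n_members_in_universe`,
#'   `p_raw`, `p_holm`; skipped pathway IDs in `attr(, "skipped")`.
#' @export
enrich <- function(hits, universe, pathways) {
  hits <- unique(hits); universe <- unique(universe)
  stray <- setdiff(hits, universe)
  if (length(stray))
    stop("hits outside the universe: ",
         paste(head(stray, 5), collapse = ", "))
  rows <- lapply(names(pathways), function(pw) {
    members <- intersect(pathways[[pw]], universe)
    if (!length(members)) return(NULL)
    k <- length(intersect(hits, members))
    p <- phyper(k - 1, length(members), length(universe) - length(members),
                length(hits), lower.tail = FALSE)
    data.frame(pathway_id = pw, n_hits = k,
               n_members_in_universe = length(members), p_raw = p)
  })
  keep <- !vapply(rows, is.null, TRUE)
  out <- if (any(keep)) do.call(rbind, rows[keep]) else
    data.frame(pathway_id = character(), n_hits = integer(),
               n_members_in_universe = integer(), p_raw = numeric())
  out$p_holm <- holm_adjust(out$p_raw)
  attr(out, "skipped") <- names(pathways)[!keep]
  out
}

#' Holm step-down adjusted p-values
#'
#' Familywise-error control by the Holm-Bonferroni step-down procedure
#' (via [stats::p.adjust()]): sorted ascending, `p_(i) * (m - i + 1)`,
#' monotonicity enforced, capped at 1.
#'
#' @param p numeric vector of p-values.
#' @return adjusted p-values, same order as input.
#' @export
holm_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0,1]")
  p.adjust(p, method = "holm")
}

#' Relative betweenness centrality, per connected component
#'
#' Betweenness of each node within its connected component, normalized by
#' `(n_c - 1)(n_c - 2)/2` (the maximum attainable for an undirected graph
#' on the `n_c` nodes of that component), then pooled over components.
#' Components of <= 2 nodes contribute zero.
#'
#' @param edges two-column character matrix of undirected edges.
#' @param nodes optional node IDs to include even when isolated.
#' @return named numeric vector of relative betweenness in \[0,1\].
#' @export
relative_betweenness <- function(edges, nodes = NULL) {
  all_nodes <- unique(c(as.vector(edges), nodes))
  out <- setNames(rep(0, length(all_nodes)), all_nodes)
  if (!nrow(edges)) return(out)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comp <- igraph::components(g)
  for (ci in seq_len(comp$no)) {
    vs <- names(comp$membership)[comp$membership == ci]
    nc <- length(vs)
    if (nc <= 2) next
    sub <- igraph::induced_subgraph(g, vs)
    b <- igraph::betweenness(sub, directed = FALSE, normalized = FALSE)
    out[names(b)] <- b / ((nc - 1) * (nc - 2) / 2)
  }
  out
}

#' Pathway topology impact score
#'
#' Importance of the hit metabolites within a pathway's graph: the sum of
#' relative-betweenness centralities over hit nodes divided by the sum
#' over all pathway nodes, giving a value in \[0,1\]. When the graph
#' carries no betweenness at all (e.g. <= 2 connected nodes) the score
#' falls back to the hit fraction `|hits ∩ members| / |members|`. A
#' pathway without a graph returns `NA` (flagged impact-absent).
#'
#' @param members pathway member IDs.
#' @param edges two-column edge matrix over the members, or `NULL`.
#' @param hits significant metabolite IDs.
#' @return scalar impact in \[0,1\], or `NA` when no graph is available.
#' @export
topology_impact <- function(members, edges, hits) {
  if (is.null(edges)) return(NA_real_)
  bad <- setdiff(unique(as.vector(edges)), members)
  if (length(bad))
    stop("graph nodes outside pathway membership: ",
         paste(head(bad, 5), collapse = ", "))
  hits_in <- intersect(hits, members)
  imp <- relative_betweenness(edges, nodes = members)
  total <- sum(imp)
  if (total == 0) return(length(hits_in) / length(members))
  sum(imp[hits_in]) / total
}

#' Joint enrichment and topology analysis
#'
#' Runs [enrich()] and attaches each pathway's [topology_impact()],
#' producing the scatter coordinates of an enrichment-vs-impact plot
#' (`-log10 p_raw` against impact).
#'
#' @param hits,universe,pathways as in [enrich()].
#' @param graphs named list of edge matrices (may lack some pathways).
#' @return data.frame: [enrich()] columns plus `impact`, `neg_log10_p`.
#' @export
pathway_analysis <- function(hits, universe, pathways, graphs = list()) {
  res <- enrich(hits, universe, pathways)
  res$impact <- vapply(res$pathway_id, function(pw)
    topology_impact(pathways[[pw]], graphs[[pw]],
                    intersect(hits, universe)), 0.0)
  res$neg_log10_p <- -log10(pmax(res$p_raw, .Machine$double.xmin))
  res[order(res$p_raw, res$pathway_id), , drop = FALSE]
}
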