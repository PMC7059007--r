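#!/usr/bin/env Rscript
# Stage 5 -- pathway enrichment and topology impact.
#
# One-sided hypergeometric over-representation of the 10%-FDR hits
# (headline contrast) within the annotated universe, Holm-adjusted at
# 10%, plus the relative-betweenness topology impact of the hit
# metabolites in each pathway graph. The output table doubles as the
# enrichment-vs-impact scatter (-log10 p against impact).

suppressPackageStartupMessages(library(bezametab))
out <- "results/05_pathways"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

volcano <- read.delim("results/04_differential/volcano_W6W12_vs_W0.tsv")
pathways <- read_gmt("results/01_simulate/pathways.gmt")
graphs <- read_edges_tsv("results/01_simulate/pathway_edges.tsv")

annotated <- unique(unlist(pathways))
universe <- intersect(volcano$metabolite_id, annotated)
hits <- intersect(volcano$metabolite_id[volcano$significant], universe)
res <- pathway_analysis(hits, universe, pathways, graphs)
write.table(res, file.path(out, "pathway_results.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, na = "")

cat(sprintf("universe: %d annotated metabolites; hits mapped: %d\n",
            length(universe), length(hits)))
sig <- res[res$p_holm <= 0.10, ]
cat(sprintf("%d pathways pass 10%% Holm-Bonferroni:\n", nrow(sig)))
if (nrow(sig))
  print(sig[, c("pathway_id", "n_hits", "p_raw", "p_holm", "impact")],
        row.names = FALSE)
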