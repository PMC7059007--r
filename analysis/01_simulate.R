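#!/usr/bin/env Rscript
# Stage 1 -- simulate the cohort.
#
# Generates the 867-metabolite catalogue (printed super-pathway
# proportions, 4 partially characterised compounds), pathway definitions
# with random connected graphs, and the 6-patient x 3-week abundance
# matrix with patient random effects, run-day batch factors, treatment
# shifts in the three designated pathways, 10% left censoring at the
# detection limit and rare spikes. Ground truth goes alongside the data.

suppressPackageStartupMessages(library(bezametab))
out <- "results/01_simulate"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- sim_config(seed = 20260926L)
catalogue <- generate_catalogue(cfg)
gen <- generate_abundances(catalogue, cfg)
pathways <- catalogue_pathways(catalogue)
graphs <- generate_pathway_graphs(pathways, seed = cfg$seed)

write_catalogue_csv(catalogue, file.path(out, "catalogue.csv"))
write_abundance_tsv(gen$matrix, file.path(out, "matrix_raw.tsv"))
write_truth_json(gen$truth, file.path(out, "truth.json"))
write_gmt(pathways, file.path(out, "pathways.gmt"))
write_edges_tsv(graphs, file.path(out, "pathway_edges.tsv"))

cat(sprintf("catalogue: %d metabolites (%d Xenobiotics, %d untargeted)\n",
            nrow(catalogue),
            sum(catalogue$super_pathway == "Xenobiotics", na.rm = TRUE),
            sum(!catalogue$targeted)))
cat(sprintf("matrix: %d samples x %d metabolites, %.1f%% censored at DL\n",
            nrow(gen$matrix$values), ncol(gen$matrix$values),
            100 * mean(is.na(gen$matrix$values))))
cat(sprintf("affected metabolites: %d across %d pathways\n",
            length(gen$truth$affected_metabolites),
            length(cfg$affected_pathways)))
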