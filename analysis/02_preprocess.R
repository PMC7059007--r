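#!/usr/bin/env Rscript
# Stage 2 -- normalization.
#
# Drops partially characterised and Xenobiotics compounds (867 -> 736),
# removes never-detected columns, rescales every metabolite to median 1,
# log10-transforms, and masks data points beyond 4 SD of their
# metabolite mean. Every removed or masked datum lands in the
# provenance table.

suppressPackageStartupMessages(library(bezametab))
inp <- "results/01_simulate"
out <- "results/02_preprocess"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

mat <- read_abundance_tsv(file.path(inp, "matrix_raw.tsv"))
catalogue <- read_catalogue_csv(file.path(inp, "catalogue.csv"))

pre <- preprocess(mat, catalogue, z_max = 4)
write_abundance_tsv(pre$matrix, file.path(out, "matrix_normalized.tsv"))
write.table(pre$provenance, file.path(out, "provenance.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, na = "")

n_filtered <- sum(pre$provenance$stage == "filter_targeted")
cat(sprintf("filtered %d untargeted/Xenobiotics columns: %d -> %d\n",
            n_filtered, ncol(mat$values), ncol(mat$values) - n_filtered))
cat(sprintf("dropped %d never-detected columns; masked %d outlier cells\n",
            sum(pre$provenance$stage == "drop_undetected"),
            sum(pre$provenance$stage == "exclude_outliers")))
cat(sprintf("normalized matrix: %d x %d at stage %s, %.1f%% missing\n",
            nrow(pre$matrix$values), ncol(pre$matrix$values),
            pre$matrix$stage, 100 * mean(is.na(pre$matrix$values))))
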