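#!/usr/bin/env Rscript
# Stage 3: compile the decisive supermatrix.
#
# Keeps only genes with at least one sequence in each of the four clusters,
# restricts rows to the clustered taxa (contaminants and other extraneous
# rows fall away here), concatenates with gap fill, and writes the relaxed
# PHYLIP supermatrix, a RAxML-style partition file, the reduced presence
# matrix and the coverage report.

suppressPackageStartupMessages(library(fclmap))

out <- "results/supermatrix"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

clusters <- read_clusters("results/data/clusters.tsv")
files <- list.files("results/qc/genes", pattern = "\\.fasta$",
                    full.names = TRUE)
aln <- setNames(lapply(files, read_fasta),
                sub("\\.fasta$", "", basename(files)))

cmp <- compile_decisive_dataset(aln, clusters)

write_phylip(cmp$supermatrix, file.path(out, "supermatrix.phy"))
write_partitions(cmp$supermatrix, file.path(out, "supermatrix.part"))
write_presence(cmp$presence, file.path(out, "presence.tsv"))
write.table(data.frame(metric = names(cmp$coverage),
                       percent = unname(cmp$coverage)),
            file.path(out, "coverage.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

cat(sprintf("Retained %d of %d genes under the decisiveness rule\n",
            length(cmp$genes), length(aln)))
cat(sprintf("Supermatrix: %d taxa x %d sites; coverage %.1f%% overall, %.1f%% addressed groups\n",
            length(cmp$supermatrix$taxa), cmp$supermatrix$nsites,
            cmp$coverage[["overall"]], cmp$coverage[["addressed_groups"]]))
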