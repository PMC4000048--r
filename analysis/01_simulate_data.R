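#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Emulates the structure of a transcriptome-based phylogenomic dataset for a
# single focal split: 20 taxa in four clusters whose true relationship pairs
# clusters (1,2) against (3,4) across an internal branch of 0.2
# substitutions/site, 12 single-copy genes of 250 aa evolved under LG with
# GAMMA(alpha = 1) site rates, patchy gene coverage (presence probability
# 0.75, decisiveness not enforced - that is stage 3's job), two planted
# contaminant sequences in gene001, and 40 binary morphological characters
# evolved on the same tree.

suppressPackageStartupMessages(library(fclmap))

seed <- 20140320L
out <- "results/data"
dir.create(file.path(out, "genes"), recursive = TRUE, showWarnings = FALSE)

fc <- four_cluster_tree(n_per_cluster = 5, internal = 0.2)
model <- substitution_model("LG", alpha = 1)

genes <- simulate_gene_set(fc$tree, model, n_genes = 12,
                           sites_per_gene = 250, seed = seed)
presence <- simulate_presence(12, fc$tree$tip.label, p = 0.75,
                              clusters = fc$clusters, seed = seed + 1)

aln <- lapply(seq_along(genes), function(g)
  genes[[g]][presence[g, names(genes[[g]])]])
names(aln) <- names(genes)

# plant two contaminants in the first gene for the QC stage to find
inj <- inject_contaminants(aln$gene001, k = 2, mode = "shuffled",
                           seed = seed + 2)
aln$gene001 <- inj$msa

for (g in names(aln)) write_fasta(aln[[g]], file.path(out, "genes",
                                                      paste0(g, ".fasta")))
write_clusters(fc$clusters, file.path(out, "clusters.tsv"))
ape::write.tree(fc$tree, file.path(out, "true_tree.nwk"))
write_presence(presence, file.path(out, "presence_true.tsv"))

chars <- simulate_characters(fc$tree, n_char = 40, k = 2, rate = 0.6,
                             seed = seed + 3)
write.table(data.frame(taxon = rownames(chars), chars, check.names = FALSE),
            file.path(out, "characters.tsv"), sep = "\t", quote = FALSE,
            row.names = FALSE)

truth <- list(seed = seed, internal_branch = 0.2, model = "LG", alpha = 1,
              n_genes = 12, sites_per_gene = 250, presence_p = 0.75,
              true_split = "T1 (clusters 1,2 | 3,4)",
              contaminants = inj$contaminants)
jsonlite::write_json(truth, file.path(out, "truth.json"), auto_unbox = TRUE,
                     pretty = TRUE)

cat("Simulated", length(aln), "genes for", length(fc$tree$tip.label),
    "taxa;", "planted contaminants:",
    paste(inj$contaminants, collapse = ", "), "\n")
cat("Coverage of the raw presence matrix:",
    sprintf("%.1f%%", 100 * mean(presence)), "\n")
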