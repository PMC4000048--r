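#!/usr/bin/env Rscript
# Stage 2: BLOSUM62-distance outlier screening per gene.
#
# The reference set stands in for the study's designated reference species
# and must span the taxonomic breadth of the alignment: one present taxon
# per cluster plus one extra, so the pairwise reference distances cover the
# within- and between-cluster range and the cutoff reflects genuine
# divergence. Two passes: flagged rows are re-aligned to the reference
# backbone once, rows still flagged afterwards are removed, and gap-only
# columns are dropped.

suppressPackageStartupMessages(library(fclmap))

ind <- "results/data/genes"
out <- "results/qc"
dir.create(file.path(out, "genes"), recursive = TRUE, showWarnings = FALSE)

clusters <- read_clusters("results/data/clusters.tsv")

pick_references <- function(msa) {
  refs <- character(0)
  for (mem in clusters$members) {
    hit <- intersect(mem, names(msa))
    if (length(hit) > 0) refs <- c(refs, hit[1])
  }
  extra <- setdiff(intersect(unlist(clusters$members), names(msa)), refs)
  if (length(refs) < 5 && length(extra) > 0)
    refs <- c(refs, extra[seq_len(min(5 - length(refs), length(extra)))])
  refs
}

files <- list.files(ind, pattern = "\\.fasta$", full.names = TRUE)
report <- list()
for (f in files) {
  gene <- sub("\\.fasta$", "", basename(f))
  msa <- read_fasta(f)
  refs <- pick_references(msa)
  if (length(refs) < 3 || length(msa) <= length(refs)) {
    write_fasta(msa, file.path(out, "genes", basename(f)))
    next
  }
  res <- qc_pipeline(msa, refs)
  write_fasta(res$msa, file.path(out, "genes", basename(f)))
  t1 <- res$reports$pass1$table; t1$pass <- 1L; t1$gene <- gene
  t2 <- res$reports$pass2$table; t2$pass <- 2L; t2$gene <- gene
  report[[gene]] <- rbind(t1, t2)
  if (length(res$removed) > 0)
    cat(gene, ": removed", paste(res$removed, collapse = ", "),
        "(", res$n_gap_columns_dropped, "gap-only columns dropped )\n")
}
report <- do.call(rbind, report)
write.table(report, file.path(out, "outlier_report.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

cat("Screened", length(files), "genes;",
    sum(report$flagged[report$pass == 2]), "sequences removed after pass 2\n")
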