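# Thin readers/writers around the ecosystem parsers: FASTA through
# Biostrings, Newick through ape; plus TSV writers for the tables the
# workflow emits. Relaxed PHYLIP and partition files live in
# matrix-builder.R next to the supermatrix type.

#' Read an amino-acid FASTA alignment
#' @param path file path.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path)
  invisible(path)
}

#' Write a taxon-to-cluster table
#' @param clusters a \code{cluster_assignment}.
#' @param path output TSV.
#' @export
write_clusters <- function(clusters, path) {
  d <- data.frame(
    taxon = unlist(clusters$members),
    cluster = rep(clusters$names,
                  vapply(clusters$members, length, integer(1))))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Write the per-quartet FcLM table
#' @param fclm an \code{fclm_result}.
#' @param path output TSV.
#' @export
write_fclm_results <- function(fclm, path) {
  write.table(fclm$results, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a gene presence/absence matrix
#' @param presence logical genes x taxa matrix.
#' @param path output TSV.
#' @export
write_presence <- function(presence, path) {
  d <- data.frame(gene = rownames(presence),
                  ifelse(presence, 1L, 0L), check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
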