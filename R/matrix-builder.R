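# Decisive supermatrix compilation: gene presence/absence, the decisiveness
# rule (every gene covered in all four clusters), concatenation with gap fill
# for absent taxa, coverage statistics, and relaxed-PHYLIP / partition-file
# round trips.

#' Gene presence/absence matrix from per-gene alignments
#'
#' @param alignments named list of per-gene alignments, each a named
#'   character vector of aligned sequences (names = taxon ids).
#' @param taxa taxon universe; default the union over genes.
#' @return logical genes x taxa matrix.
#' @export
gene_presence <- function(alignments, taxa = NULL) {
  if (length(alignments) == 0L) stop("no gene alignments")
  if (is.null(names(alignments)) || anyDuplicated(names(alignments)))
    stop("alignments must be uniquely named by gene")
  if (is.null(taxa)) taxa <- unique(unlist(lapply(alignments, names)))
  m <- t(vapply(alignments, function(a) taxa %in% names(a),
                logical(length(taxa))))
  dimnames(m) <- list(names(alignments), taxa)
  m
}

#' Select genes that make a dataset decisive
#'
#' A gene is retained iff each of the four clusters contributes at least one
#' taxon with the gene present, so every retained gene can inform the focal
#' split. Gene order is preserved.
#'
#' @param presence logical genes x taxa matrix with dimnames.
#' @param clusters a \code{cluster_assignment}; all members must be columns
#'   of \code{presence}.
#' @return character vector of retained gene ids (possibly empty, warned).
#' @export
select_decisive_genes <- function(presence, clusters) {
  stopifnot(is.matrix(presence), inherits(clusters, "cluster_assignment"))
  missing_taxa <- setdiff(unlist(clusters$members), colnames(presence))
  if (length(missing_taxa) > 0)
    stop("cluster taxa absent from presence matrix: ",
         paste(head(missing_taxa, 5), collapse = ", "))
  ok <- rep(TRUE, nrow(presence))
  for (m in clusters$members)
    ok <- ok & rowSums(presence[, m, drop = FALSE]) > 0L
  genes <- rownames(presence)[ok]
  if (length(genes) == 0L) warning("no gene satisfies the decisiveness rule")
  genes
}

#' Remove taxa irrelevant to the focal question
#'
#' @param alignments named list of per-gene alignments.
#' @param keep taxon ids to retain.
#' @return alignments with rows outside \code{keep} removed (genes left with
#'   zero rows are dropped); columns are untouched.
#' @export
drop_irrelevant_taxa <- function(alignments, keep) {
  if (length(keep) == 0L) stop("keep set is empty")
  out <- lapply(alignments, function(a) a[names(a) %in% keep])
  out[vapply(out, length, integer(1)) > 0L]
}

#' Concatenate per-gene alignments into a supermatrix
#'
#' Taxa missing from a gene are filled with '-' across that gene's partition.
#' Partition coordinates are 1-based inclusive.
#'
#' @param alignments named list of per-gene alignments (named character
#'   vectors of equal-length rows within each gene).
#' @param taxa taxon universe and row order; default the union over genes.
#' @return object of class \code{supermatrix}: list with \code{taxa},
#'   \code{seqs} (named character vector), \code{partitions} (data.frame
#'   gene, start, end) and \code{nsites}.
#' @export
concatenate_genes <- function(alignments, taxa = NULL) {
  if (length(alignments) == 0L) stop("no gene alignments")
  if (is.null(names(alignments)) || anyDuplicated(names(alignments)))
    stop("alignments must be uniquely named by gene")
  if (is.null(taxa)) taxa <- unique(unlist(lapply(alignments, names)))
  pieces <- matrix("", length(taxa), length(alignments),
                   dimnames = list(taxa, names(alignments)))
  lens <- integer(length(alignments))
  for (j in seq_along(alignments)) {
    a <- alignments[[j]]
    if (anyDuplicated(names(a)))
      stop("duplicate taxon id in gene ", names(alignments)[j], ": ",
           names(a)[duplicated(names(a))][1L])
    L <- unique(nchar(a))
    if (length(L) != 1L)
      stop("unequal row lengths in gene ", names(alignments)[j])
    lens[j] <- L
    gap <- strrep("-", L)
    col <- setNames(rep(gap, length(taxa)), taxa)
    hit <- intersect(names(a), taxa)
    col[hit] <- a[hit]
    pieces[, j] <- col
  }
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  seqs <- setNames(apply(pieces, 1L, paste, collapse = ""), taxa)
  structure(list(taxa = taxa, seqs = seqs,
                 partitions = data.frame(gene = names(alignments),
                                         start = starts, end = ends,
                                         stringsAsFactors = FALSE),
                 nsites = sum(lens)),
            class = "supermatrix")
}

#' @export
print.supermatrix <- function(x, ...) {
  cat(sprintf("Supermatrix: %d taxa x %d sites, %d partitions, %.1f%% missing\n",
              length(x$taxa), x$nsites, nrow(x$partitions),
              100 * missingness(x)))
  invisible(x)
}

#' Fraction of missing cells (gap/'X'/other non-residue) in a supermatrix
#' @param sm a \code{supermatrix}.
#' @return fraction in [0, 1].
#' @export
missingness <- function(sm) {
  codes <- encode_aa(sm$seqs)
  mean(is.na(codes))
}

#' Extract one partition from a supermatrix
#'
#' @param sm a \code{supermatrix}.
#' @param gene partition (gene) id.
#' @return named character vector: the gene's alignment rows, gap-filled for
#'   taxa that lacked the gene.
#' @export
extract_partition <- function(sm, gene) {
  i <- match(gene, sm$partitions$gene)
  if (is.na(i)) stop("no partition named ", gene)
  setNames(substr(sm$seqs, sm$partitions$start[i], sm$partitions$end[i]),
           sm$taxa)
}

#' Coverage statistics of a presence matrix
#'
#' Overall coverage is the percentage of present gene x taxon cells;
#' addressed-group coverage is the percentage of genes with at least one
#' present taxon in each of the four clusters (100 for any decisive dataset).
#'
#' @param presence logical genes x taxa matrix.
#' @param clusters a \code{cluster_assignment}.
#' @return named numeric: \code{overall}, \code{addressed_groups} (percent).
#' @export
coverage_stats <- function(presence, clusters) {
  stopifnot(is.matrix(presence), inherits(clusters, "cluster_assignment"))
  if (nrow(presence) == 0L) stop("zero genes: coverage undefined")
  covered <- rep(TRUE, nrow(presence))
  for (m in clusters$members)
    covered <- covered & rowSums(presence[, m, drop = FALSE]) > 0L
  c(overall = 100 * mean(presence),
    addressed_groups = 100 * mean(covered))
}

#' Remove transcripts assigned to more than one ortholog group
#'
#' @param assignments data.frame with columns \code{transcript}, \code{gene}
#'   (one row per assignment).
#' @return filtered data.frame: every transcript mapped to two or more
#'   distinct genes is removed entirely.
#' @export
redundancy_filter <- function(assignments) {
  stopifnot(all(c("transcript", "gene") %in% names(assignments)))
  ngene <- tapply(assignments$gene, assignments$transcript,
                  function(g) length(unique(g)))
  bad <- names(ngene)[ngene > 1L]
  assignments[!(assignments$transcript %in% bad), , drop = FALSE]
}

#' Write a supermatrix in relaxed PHYLIP format
#'
#' Header "ntaxa nsites", then one "name sequence" line per taxon (names up
#' to 250 characters, single space separator).
#'
#' @param sm a \code{supermatrix}.
#' @param path output file.
#' @export
write_phylip <- function(sm, path) {
  stopifnot(inherits(sm, "supermatrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(length(sm$taxa), sm$nsites), con)
  writeLines(paste(sm$taxa, unname(sm$seqs)), con)
  invisible(path)
}

#' Read a relaxed PHYLIP alignment
#'
#' @param path file path.
#' @param partitions optional partition table (e.g. from
#'   \code{\link{read_partitions}}) to attach.
#' @return a \code{supermatrix} (single partition "all" when none supplied).
#' @export
read_phylip <- function(path, partitions = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- scan(text = lines[1L], what = integer(), quiet = TRUE)
  if (length(hdr) != 2L) stop("malformed PHYLIP header")
  body <- strsplit(trimws(lines[-1L]), "[ \t]+")
  if (length(body) != hdr[1L]) stop("taxon count does not match header")
  taxa <- vapply(body, `[[`, character(1), 1L)
  seqs <- setNames(vapply(body, `[[`, character(1), 2L), taxa)
  if (any(nchar(seqs) != hdr[2L])) stop("sequence length does not match header")
  if (is.null(partitions))
    partitions <- data.frame(gene = "all", start = 1L, end = hdr[2L],
                             stringsAsFactors = FALSE)
  structure(list(taxa = taxa, seqs = seqs, partitions = partitions,
                 nsites = hdr[2L]),
            class = "supermatrix")
}

#' Write a RAxML-style partition file
#'
#' One line per partition: "MODEL, gene = start-end" (1-based inclusive).
#'
#' @param sm a \code{supermatrix}.
#' @param path output file.
#' @param model model label written per partition (default "LG").
#' @export
write_partitions <- function(sm, path, model = "LG") {
  p <- sm$partitions
  writeLines(sprintf("%s, %s = %d-%d", model, p$gene, p$start, p$end), path)
  invisible(path)
}

#' Read a RAxML-style partition file
#'
#' @param path file path.
#' @return data.frame with columns gene, start, end, model.
#' @export
read_partitions <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec(
    "^\\s*([^,]+)\\s*,\\s*(\\S+)\\s*=\\s*(\\d+)\\s*-\\s*(\\d+)\\s*$", lines))
  if (any(vapply(m, length, integer(1)) != 5L))
    stop("malformed partition line: ",
         lines[vapply(m, length, integer(1)) != 5L][1L])
  data.frame(gene = vapply(m, `[[`, character(1), 3L),
             start = as.integer(vapply(m, `[[`, character(1), 4L)),
             end = as.integer(vapply(m, `[[`, character(1), 5L)),
             model = trimws(vapply(m, `[[`, character(1), 2L)),
             stringsAsFactors = FALSE)
}

#' Compile a decisive supermatrix from per-gene alignments
#'
#' Applies the decisiveness rule, restricts to the clustered taxa, and
#' concatenates, i.e. the full dataset-design step in one call.
#'
#' @param alignments named list of per-gene alignments.
#' @param clusters a \code{cluster_assignment}; its members define both the
#'   taxon keep-set and the four groups of interest.
#' @return list with \code{supermatrix}, retained \code{genes}, the reduced
#'   \code{presence} matrix and \code{coverage} (see
#'   \code{\link{coverage_stats}}).
#' @export
compile_decisive_dataset <- function(alignments, clusters) {
  keep <- unlist(clusters$members)
  reduced <- drop_irrelevant_taxa(alignments, keep)
  presence <- gene_presence(reduced, taxa = keep)
  genes <- select_decisive_genes(presence, clusters)
  if (length(genes) == 0L) stop("decisive gene set is empty")
  sm <- concatenate_genes(reduced[genes], taxa = keep)
  list(supermatrix = sm, genes = genes,
       presence = presence[genes, , drop = FALSE],
       coverage = coverage_stats(presence[genes, , drop = FALSE], clusters))
}
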