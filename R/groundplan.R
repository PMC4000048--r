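# Maximum-parsimony groundplan reconstruction of unordered categorical
# characters on a fixed rooted tree: Fitch step counts, uniform-cost Sankoff
# MPR sets (handles polytomies natively), and per-focal-node groundplan
# tables with ambiguity and apomorphy flags.

# Parse one tip's coding into a logical state-set vector (1-based indexing of
# 0-based state codes). '?' and '-' both mean "any state" for reconstruction;
# polymorphic codings use '/' or ','.
.state_set <- function(code, nstates) {
  s <- rep(FALSE, nstates)
  code <- as.character(code)
  if (is.na(code) || code %in% c("?", "-", "")) return(rep(TRUE, nstates))
  vals <- suppressWarnings(as.integer(strsplit(code, "[/,]")[[1]]))
  if (any(is.na(vals)) || any(vals < 0L) || any(vals >= nstates))
    stop("state code out of range: '", code, "' (nstates = ", nstates, ")")
  s[vals + 1L] <- TRUE
  s
}

.tip_state_matrix <- function(tree, states, nstates) {
  if (is.null(names(states))) stop("tip states must be named")
  missing_tips <- setdiff(tree$tip.label, names(states))
  if (length(missing_tips) > 0)
    stop("no state for tips: ", paste(head(missing_tips, 5), collapse = ", "))
  vapply(states[tree$tip.label], .state_set, logical(nstates),
         nstates = nstates)
}

.infer_nstates <- function(states) {
  vals <- unlist(strsplit(as.character(states), "[/,]"))
  vals <- suppressWarnings(as.integer(vals[!(vals %in% c("?", "-", "")) &
                                             !is.na(vals)]))
  vals <- vals[!is.na(vals)]
  # floor of 2: a character with no observed variation (or none observed at
  # all) still reconstructs over a binary state space, so full-set ambiguity
  # is representable
  if (length(vals) == 0L) return(2L)
  max(max(vals) + 1L, 2L)
}

#' Fitch parsimony step count for one character
#'
#' Standard Fitch downpass (intersection, else union plus one step) on a
#' rooted binary tree; unordered states. Polytomies are resolved internally
#' by arbitrary zero-length expansion (\code{ape::multi2di}) before the pass.
#' Missing ('?') and inapplicable ('-') tips contribute the full state set at
#' zero forced cost.
#'
#' @param tree rooted \code{phylo}.
#' @param states named vector of tip codings: 0-based integer codes,
#'   polymorphic "0/1", missing "?", inapplicable "-".
#' @param nstates character cardinality; default inferred from the codings.
#' @return list with \code{steps}, \code{downpass} (logical states x nodes
#'   matrix of downpass sets on the possibly resolved tree) and
#'   \code{resolved} (TRUE if a polytomy was expanded).
#' @export
fitch_steps <- function(tree, states, nstates = NULL) {
  stopifnot(inherits(tree, "phylo"))
  resolved <- FALSE
  if (!ape::is.binary.phylo(tree)) {
    tree <- ape::multi2di(tree, random = FALSE)
    resolved <- TRUE
  }
  if (is.null(nstates)) nstates <- .infer_nstates(states)
  tips <- .tip_state_matrix(tree, states, nstates)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  sets <- matrix(FALSE, nstates, ntip + nnode)
  sets[, seq_len(ntip)] <- tips
  steps <- 0L
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  # visit each internal node once: combine its two children
  children <- split(edge[, 2L], edge[, 1L])
  for (node in unique(edge[, 1L])) {
    ch <- children[[as.character(node)]]
    s <- sets[, ch[1L]]
    for (c2 in ch[-1L]) {
      inter <- s & sets[, c2]
      if (any(inter)) s <- inter
      else { s <- s | sets[, c2]; steps <- steps + 1L }
    }
    sets[, node] <- s
  }
  list(steps = steps, downpass = sets, resolved = resolved)
}

# Uniform-cost Sankoff downpass: D[s, v] = min changes in v's subtree given
# state s at v. Works on multifurcating trees.
.sankoff_down <- function(tree, tips, nstates) {
  ntip <- length(tree$tip.label)
  D <- matrix(Inf, nstates, ntip + tree$Nnode)
  D[, seq_len(ntip)] <- ifelse(tips, 0, Inf)
  edge <- tree$edge[ape::postorder(tree), , drop = FALSE]
  children <- split(edge[, 2L], edge[, 1L])
  for (node in unique(edge[, 1L])) {
    acc <- rep(0, nstates)
    for (ch in children[[as.character(node)]]) {
      dc <- D[, ch]
      # uniform cost: min_{s'}(cost(s, s') + D(s')) = min(D(s), min D + 1)
      acc <- acc + pmin(dc, min(dc) + 1)
    }
    D[, node] <- acc
  }
  D
}

#' MPR state sets under uniform-cost (unordered) parsimony
#'
#' Sankoff down- and up-pass with unit change costs. Each node's set contains
#' every state realized by at least one reconstruction achieving the global
#' minimum number of changes; nodes with more than one state are flagged
#' ambiguous.
#'
#' @inheritParams fitch_steps
#' @return object of class \code{ancestral_reconstruction}: list with
#'   \code{steps}, \code{sets} (list over nodes, 0-based state codes; tips
#'   first, then internal nodes in \code{phylo} numbering), \code{ambiguous}
#'   (logical per node) and \code{nstates}.
#' @export
mpr_sets <- function(tree, states, nstates = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(nstates)) nstates <- .infer_nstates(states)
  tips <- .tip_state_matrix(tree, states, nstates)
  ntip <- length(tree$tip.label)
  nnode_all <- ntip + tree$Nnode
  D <- .sankoff_down(tree, tips, nstates)
  root <- ntip + 1L
  total <- min(D[, root])
  # uppass: U[s, v] = min changes outside v's subtree given state s at v
  U <- matrix(0, nstates, nnode_all)
  edge <- tree$edge[rev(ape::postorder(tree)), , drop = FALSE]  # preorder
  children <- split(tree$edge[, 2L], tree$edge[, 1L])
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; v <- edge[k, 2L]
    sib <- setdiff(children[[as.character(p)]], v)
    A <- U[, p]
    for (b in sib) A <- A + pmin(D[, b], min(D[, b]) + 1)
    # min over parent state s of A(s) + cost(s, s')
    U[, v] <- pmin(A, min(A) + 1)
  }
  totals <- D + U
  sets <- lapply(seq_len(nnode_all), function(v) which(totals[, v] == total) - 1L)
  if (any(vapply(sets, length, integer(1)) == 0L))
    stop("internal error: empty MPR set")
  structure(list(steps = as.integer(total),
                 sets = sets,
                 ambiguous = vapply(sets, length, integer(1)) > 1L,
                 nstates = nstates, ntip = ntip),
            class = "ancestral_reconstruction")
}

#' @export
print.ancestral_reconstruction <- function(x, ...) {
  cat(sprintf("Parsimony reconstruction: %d steps, %d/%d ambiguous nodes\n",
              x$steps, sum(x$ambiguous[-seq_len(x$ntip)]),
              length(x$ambiguous) - x$ntip))
  invisible(x)
}

#' Groundplan table for focal nodes over a character matrix
#'
#' Runs \code{\link{mpr_sets}} per character and reports, for every focal
#' internal node: the MPR state set, an ambiguity flag, and an apomorphy flag
#' (the node's set is disjoint from its parent's set, i.e. a change along the
#' subtending branch is required in every most-parsimonious reconstruction).
#'
#' @param tree rooted \code{phylo} with named internal nodes
#'   (\code{node.label}).
#' @param cmatrix taxa x characters matrix or data.frame of codings (rownames
#'   = taxa).
#' @param focal_nodes internal node labels to report.
#' @return data.frame: node, character, states (collapsed with '/'),
#'   ambiguous, apomorphic (NA for the root), steps.
#' @export
map_matrix <- function(tree, cmatrix, focal_nodes) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$node.label)) stop("tree has no internal node labels")
  cmatrix <- as.matrix(cmatrix)
  if (is.null(rownames(cmatrix))) stop("cmatrix needs taxon rownames")
  ntip <- length(tree$tip.label)
  node_ids <- match(focal_nodes, tree$node.label) + ntip
  if (any(is.na(node_ids)))
    stop("focal node not in tree: ",
         paste(focal_nodes[is.na(node_ids)], collapse = ", "))
  parent <- rep(NA_integer_, ntip + tree$Nnode)
  parent[tree$edge[, 2L]] <- tree$edge[, 1L]
  chars <- colnames(cmatrix)
  if (is.null(chars)) chars <- paste0("char", seq_len(ncol(cmatrix)))
  out <- list()
  for (j in seq_len(ncol(cmatrix))) {
    states <- setNames(cmatrix[, j], rownames(cmatrix))
    rec <- mpr_sets(tree, states)
    for (k in seq_along(focal_nodes)) {
      v <- node_ids[k]
      p <- parent[v]
      apo <- if (is.na(p)) NA else
        length(intersect(rec$sets[[v]], rec$sets[[p]])) == 0L
      out[[length(out) + 1L]] <- data.frame(
        node = focal_nodes[k], character = chars[j],
        states = paste(rec$sets[[v]], collapse = "/"),
        ambiguous = rec$ambiguous[v], apomorphic = apo,
        steps = rec$steps, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' Read a categorical character matrix from TSV
#'
#' First column = taxon id, remaining columns = characters; codings as
#' understood by \code{\link{mpr_sets}} ("0", "1", "0/1", "?", "-").
#'
#' @param path file path.
#' @return character matrix with taxon rownames.
#' @export
read_character_matrix <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                  colClasses = "character", check.names = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- d[[1L]]
  m
}
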