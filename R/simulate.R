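# Seeded generators reproducing the statistical structure the analysis
# assumes: amino-acid alignments evolved along a known tree (exchangeability
# model + discrete-GAMMA site rates), patchy gene coverage, planted
# contaminants for the outlier screen, and categorical characters evolved by
# a k-state Markov process.

#' Simulate an amino-acid alignment along a tree
#'
#' Root states are drawn from the model's stationary frequencies; states
#' evolve along each branch through the model's transition probabilities at a
#' per-site discrete-GAMMA category. No indels are generated, so the output
#' rows are already aligned.
#'
#' @param tree rooted \code{phylo} with branch lengths (expected
#'   substitutions per site).
#' @param model a \code{substitution_model}; its \code{alpha}/\code{ncat}
#'   drive the site-rate heterogeneity.
#' @param sites number of sites.
#' @param seed optional RNG seed (set once at entry).
#' @return named character vector of tip sequences.
#' @export
simulate_alignment <- function(tree, model, sites, seed = NULL) {
  stopifnot(inherits(tree, "phylo"), inherits(model, "substitution_model"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!is.null(seed)) set.seed(seed)
  sites <- as.integer(sites)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  cat_of_site <- sample.int(model$ncat, sites, replace = TRUE)
  states <- matrix(NA_integer_, nnode, sites)
  root <- ntip + 1L
  states[root, ] <- sample.int(20L, sites, replace = TRUE, prob = model$pi)
  edge <- tree$edge[rev(ape::postorder(tree)), , drop = FALSE]  # preorder
  lens <- tree$edge.length[rev(ape::postorder(tree))]
  for (k in seq_len(nrow(edge))) {
    p <- edge[k, 1L]; v <- edge[k, 2L]
    child <- integer(sites)
    for (cc in seq_len(model$ncat)) {
      idx <- which(cat_of_site == cc)
      if (length(idx) == 0L) next
      P <- transition_probabilities(model, lens[k], model$rates[cc])
      par_states <- states[p, idx]
      # sample each site's child state from its parent's row of P
      for (s in 1:20) {
        here <- idx[par_states == s]
        if (length(here) > 0L)
          child[here] <- sample.int(20L, length(here), replace = TRUE,
                                    prob = P[s, ])
      }
    }
    states[v, ] <- child
  }
  setNames(vapply(seq_len(ntip), function(i)
    paste(AA_ALPHABET[states[i, ]], collapse = ""), character(1)),
    tree$tip.label)
}

#' Simulate a set of gene alignments
#'
#' @inheritParams simulate_alignment
#' @param n_genes number of genes.
#' @param sites_per_gene sites per gene (recycled).
#' @param seed RNG seed (set once; genes drawn sequentially).
#' @return named list of alignments ("gene001", ...).
#' @export
simulate_gene_set <- function(tree, model, n_genes, sites_per_gene,
                              seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sites_per_gene <- rep_len(sites_per_gene, n_genes)
  out <- lapply(seq_len(n_genes), function(g)
    simulate_alignment(tree, model, sites_per_gene[g]))
  names(out) <- sprintf("gene%03d", seq_len(n_genes))
  out
}

#' Simulate a patchy gene presence/absence matrix
#'
#' Independent Bernoulli presence per gene x taxon cell. Optionally a stated
#' fraction of genes is forced to be decisive by switching on one random
#' member of every cluster that would otherwise be empty.
#'
#' @param n_genes number of genes.
#' @param taxa taxon ids.
#' @param p presence probability: scalar, or per-taxon vector.
#' @param clusters optional \code{cluster_assignment} (required when
#'   \code{force_decisive_frac > 0}).
#' @param force_decisive_frac fraction of genes guaranteed decisive.
#' @param seed RNG seed.
#' @return logical genes x taxa matrix.
#' @export
simulate_presence <- function(n_genes, taxa, p = 0.65, clusters = NULL,
                              force_decisive_frac = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (any(p < 0) || any(p > 1)) stop("p must be in [0, 1]")
  p <- rep_len(p, length(taxa))
  m <- matrix(rbinom(n_genes * length(taxa), 1L,
                     rep(p, each = n_genes)) == 1L,
              n_genes, length(taxa),
              dimnames = list(sprintf("gene%03d", seq_len(n_genes)), taxa))
  if (force_decisive_frac > 0) {
    if (is.null(clusters)) stop("clusters required to force decisiveness")
    forced <- seq_len(ceiling(force_decisive_frac * n_genes))
    for (g in forced) for (mem in clusters$members) {
      if (!any(m[g, mem])) m[g, sample(mem, 1L)] <- TRUE
    }
  }
  m
}

#' Plant contaminant rows in an alignment
#'
#' Adds \code{k} rows named "contaminant1..k": either a randomly chosen
#' genuine row with its columns shuffled ("shuffled", destroys positional
#' homology but keeps composition) or i.i.d. draws from the LG stationary
#' frequencies ("foreign").
#'
#' @param msa named character vector of aligned rows.
#' @param k number of contaminants.
#' @param mode "shuffled" or "foreign".
#' @param seed RNG seed.
#' @return list with \code{msa} (rows appended) and \code{contaminants}
#'   (the planted ids; truth labels).
#' @export
inject_contaminants <- function(msa, k, mode = c("shuffled", "foreign"),
                                seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(k)
  if (k == 0L) return(list(msa = msa, contaminants = character(0)))
  L <- unique(nchar(msa))
  if (length(L) != 1L) stop("rows differ in length")
  lab <- paste0("contaminant", seq_len(k))
  pi_lg <- .load_builtin_model("LG")$pi
  for (i in seq_len(k)) {
    row <- if (mode == "shuffled") {
      ch <- strsplit(msa[[sample(length(msa), 1L)]], "", fixed = TRUE)[[1]]
      paste(sample(ch), collapse = "")
    } else {
      paste(sample(AA_ALPHABET, L, replace = TRUE, prob = pi_lg),
            collapse = "")
    }
    msa[lab[i]] <- row
  }
  list(msa = msa, contaminants = lab)
}

#' Simulate categorical characters on a tree
#'
#' k-state symmetric Markov process (all transitions equally likely) with
#' total leave-rate \code{rate} per unit branch length; the root state is
#' uniform. Closed-form transition probabilities of the k-state
#' Jukes-Cantor-type chain.
#'
#' @param tree rooted \code{phylo} with branch lengths.
#' @param n_char number of characters.
#' @param k states per character (codes 0..k-1).
#' @param rate expected changes per unit branch length.
#' @param seed RNG seed.
#' @return character matrix taxa x characters of 0-based codes.
#' @export
simulate_characters <- function(tree, n_char, k = 2L, rate = 1, seed = NULL) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (!is.null(seed)) set.seed(seed)
  k <- as.integer(k)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  states <- matrix(NA_integer_, nnode, n_char)
  states[ntip + 1L, ] <- sample.int(k, n_char, replace = TRUE)
  ord <- rev(ape::postorder(tree))
  edge <- tree$edge[ord, , drop = FALSE]
  lens <- tree$edge.length[ord]
  for (e in seq_len(nrow(edge))) {
    # P(change to one specific other state) for the symmetric k-state chain
    t <- lens[e]
    p_other <- (1 - exp(-k / (k - 1) * rate * t)) / k
    change <- runif(n_char) < (k - 1) * p_other
    par <- states[edge[e, 1L], ]
    child <- par
    if (any(change)) {
      # uniform among the k-1 other states
      shift <- sample.int(k - 1L, sum(change), replace = TRUE)
      child[change] <- ((par[change] - 1L + shift) %% k) + 1L
    }
    states[edge[e, 2L], ] <- child
  }
  m <- matrix(as.character(states[seq_len(ntip), , drop = FALSE] - 1L),
              ntip, n_char,
              dimnames = list(tree$tip.label,
                              sprintf("char%03d", seq_len(n_char))))
  m
}

#' A balanced four-cluster tree for simulation studies
#'
#' Builds a rooted tree with four clades of \code{n_per_cluster} tips each,
#' arranged so clusters 1+2 and 3+4 are sister pairs separated by the
#' internal branch of interest (the T1 pairing 12|34). Setting
#' \code{internal = 0} yields a hard polytomy of the four clusters
#' (star-like signal).
#'
#' @param n_per_cluster tips per cluster.
#' @param internal length of the central branch separating (1,2) from (3,4).
#' @param cluster_depth length of each cluster stem.
#' @param tip_length pendant branch length (tips are spread along a ladder
#'   inside each cluster with \code{within} spacing).
#' @param within internal branch length inside each cluster.
#' @return list with \code{tree} (phylo; tips named c<k>_t<i>) and
#'   \code{clusters} (a \code{cluster_assignment}).
#' @export
four_cluster_tree <- function(n_per_cluster = 2L, internal = 0.2,
                              cluster_depth = 0.1, tip_length = 0.1,
                              within = 0.05) {
  clade <- function(k) {
    tips <- sprintf("c%d_t%d", k, seq_len(n_per_cluster))
    if (n_per_cluster == 1L) return(tips)
    # ladder: (((t1,t2),t3),...)
    s <- sprintf("(%s:%g,%s:%g)", tips[1], tip_length, tips[2], tip_length)
    for (i in seq_len(max(0L, n_per_cluster - 2L)) + 2L)
      s <- sprintf("(%s:%g,%s:%g)", s, within, tips[i], tip_length)
    s
  }
  stem_len <- cluster_depth + if (n_per_cluster == 1L) tip_length else 0
  stem <- function(k) sprintf("%s:%g", clade(k), stem_len)
  half <- internal / 2
  nwk <- sprintf("((%s,%s):%g,(%s,%s):%g);",
                 stem(1), stem(2), half, stem(3), stem(4), half)
  tree <- ape::read.tree(text = nwk)
  taxa <- tree$tip.label
  cl <- as.integer(sub("^c(\\d)_.*$", "\\1", taxa))
  list(tree = tree,
       clusters = cluster_assignment(taxa, cl,
                                     paste0("cluster", 1:4)))
}
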