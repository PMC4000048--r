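# Independent oracles and small fixture builders shared across test files.
# Oracles are deliberately written against first principles (explicit sums,
# quadrature, exhaustive enumeration) and never reuse the code paths they
# check.

# --- quartet likelihood: exhaustive sum over the two internal node states ---
# Works directly on sequences; gaps/'X' marginalized by all-ones tip vectors.
oracle_quartet_loglik <- function(seqs, topology, lengths, model) {
  alphabet <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  ord <- switch(topology, T1 = c(1, 2, 3, 4), T2 = c(1, 3, 2, 4),
                T3 = c(1, 4, 2, 3))
  chars <- lapply(strsplit(toupper(seqs), ""), function(x)
    match(x, alphabet))
  br <- c(lengths[1:4][ord], lengths[5])
  nsite <- length(chars[[1]])
  total <- 0
  for (s in seq_len(nsite)) {
    tipv <- lapply(ord, function(i) {
      v <- rep(1, 20)
      if (!is.na(chars[[i]][s])) { v <- rep(0, 20); v[chars[[i]][s]] <- 1 }
      v
    })
    if (all(vapply(tipv, function(v) all(v == 1), logical(1)))) next
    lik <- 0
    for (k in seq_len(model$ncat)) {
      P <- lapply(br, function(t)
        transition_probabilities(model, t, model$rates[k]))
      acc <- 0
      for (u in 1:20) for (v in 1:20)
        acc <- acc + model$pi[u] *
          sum(P[[1]][u, ] * tipv[[1]]) * sum(P[[2]][u, ] * tipv[[2]]) *
          P[[5]][u, v] *
          sum(P[[3]][v, ] * tipv[[3]]) * sum(P[[4]][v, ] * tipv[[4]])
      lik <- lik + acc / model$ncat
    }
    total <- total + log(lik)
  }
  unname(total)
}

# --- discrete GAMMA category means by numerical quadrature ---
oracle_gamma_means <- function(alpha, ncat) {
  bounds <- qgamma(seq(0, 1, length.out = ncat + 1), alpha, rate = alpha)
  r <- numeric(ncat)
  for (i in seq_len(ncat)) {
    num <- integrate(function(x) x * dgamma(x, alpha, rate = alpha),
                     bounds[i], bounds[i + 1], rel.tol = 1e-10)$value
    r[i] <- num * ncat   # each category has probability 1/ncat
  }
  r
}

# --- matrix exponential by scaling-and-squaring series summation ---
oracle_expm <- function(A, terms = 40L, squarings = 20L) {
  A <- A / 2^squarings
  S <- diag(nrow(A))
  term <- diag(nrow(A))
  for (k in seq_len(terms)) {
    term <- term %*% A / k
    S <- S + term
  }
  for (i in seq_len(squarings)) S <- S %*% S
  S
}

# --- exhaustive parsimony: minimum steps and realized root/internal sets ---
# tree: ape phylo (rooted, may be multifurcating); tipsets: logical
# nstates x ntip matrix of allowed tip states.
oracle_parsimony <- function(tree, tipsets) {
  nstates <- nrow(tipsets)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  combos <- as.matrix(expand.grid(rep(list(seq_len(nstates)), nnode)))
  edge <- tree$edge
  best <- Inf
  realized <- vector("list", ntip + nnode)
  for (r in seq_len(nrow(combos))) {
    asgn <- combos[r, ]
    node_state <- function(v) if (v <= ntip) NA else asgn[v - ntip]
    # tips: choose the cheapest allowed state given the parent
    cost <- 0
    tip_choice <- integer(ntip)
    for (e in seq_len(nrow(edge))) {
      p <- edge[e, 1]; v <- edge[e, 2]
      ps <- node_state(p)
      if (v <= ntip) {
        allowed <- which(tipsets[, v])
        if (ps %in% allowed) { tip_choice[v] <- ps }
        else { cost <- cost + 1; tip_choice[v] <- allowed[1] }
      } else {
        if (node_state(v) != ps) cost <- cost + 1
      }
    }
    if (cost < best) {
      best <- cost
      realized <- vector("list", ntip + nnode)
    }
    if (cost == best) {
      for (v in seq_len(ntip + nnode)) {
        s <- if (v <= ntip) tip_choice[v] else asgn[v - ntip]
        realized[[v]] <- union(realized[[v]], s)
      }
    }
  }
  list(steps = as.integer(best),
       sets = lapply(realized, function(s) sort(s) - 1L))
}

# random rooted binary tree with named tips
random_tree <- function(ntip, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tr <- ape::rtree(ntip, rooted = TRUE)
  tr$tip.label <- paste0("t", seq_len(ntip))
  tr
}

# quick random aligned sequences (possibly with gaps)
random_seqs <- function(n, len, gap_prob = 0.1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  alphabet <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  out <- vapply(seq_len(n), function(i) {
    ch <- sample(alphabet, len, replace = TRUE)
    ch[runif(len) < gap_prob] <- "-"
    paste(ch, collapse = "")
  }, character(1))
  setNames(out, paste0("s", seq_len(n)))
}
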