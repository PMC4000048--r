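# Maximum-likelihood machinery for one four-taxon amino-acid alignment:
# pattern compression, Felsenstein pruning (C++ kernel), coordinate-ascent
# optimization of the five branch lengths and optionally the GAMMA shape.

.TOPOLOGIES <- c("T1", "T2", "T3")
# tip order handed to the pruning kernel, which always pairs (1,2) vs (3,4)
.TOPO_ORDER <- list(T1 = c(1L, 2L, 3L, 4L),
                    T2 = c(1L, 3L, 2L, 4L),
                    T3 = c(1L, 4L, 2L, 3L))
.BL_MIN <- 1e-8
.BL_MAX <- 100

#' Encode amino-acid sequences as integer matrices
#'
#' Residues are mapped to 1..20 in the canonical order
#' A R N D C Q E G H I L K M F P S T W Y V; gaps ('-'), 'X' and any other
#' symbol become \code{NA} (fully missing).
#'
#' @param seqs character vector of equal-length aligned sequences.
#' @return integer matrix, one row per sequence.
#' @export
encode_aa <- function(seqs) {
  L <- unique(nchar(seqs))
  if (length(L) != 1L) stop("sequences differ in length")
  m <- matrix(match(unlist(strsplit(toupper(seqs), "", fixed = TRUE)),
                    AA_ALPHABET),
              nrow = length(seqs), byrow = TRUE)
  rownames(m) <- names(seqs)
  m
}

#' Build a quartet alignment with compressed site patterns
#'
#' Columns missing in all four taxa carry no signal; they are removed and
#' counted. Identical residue patterns are collapsed with multiplicities.
#'
#' @param ids four distinct taxon ids.
#' @param seqs four equal-length aligned amino-acid sequences (gap '-',
#'   ambiguity 'X').
#' @return object of class \code{quartet_alignment} with the pattern matrix
#'   (\code{codes}), pattern \code{weights}, the original site count
#'   (\code{nsites}), the number of all-missing columns removed
#'   (\code{n_all_missing}) and the number of informative sites (>= 2
#'   non-missing residues, \code{n_informative}).
#' @export
quartet_alignment <- function(ids, seqs) {
  if (length(ids) != 4L || length(seqs) != 4L)
    stop("a quartet alignment needs exactly 4 taxa")
  if (any(nchar(seqs) == 0) || length(unique(nchar(seqs))) != 1L)
    stop("sequences must be non-empty and of equal length")
  .qa_from_codes(ids, encode_aa(seqs))
}

# core constructor from a pre-encoded 4 x nsites integer matrix
.qa_from_codes <- function(ids, codes) {
  if (anyDuplicated(ids)) stop("taxon ids must be distinct")
  nsites <- ncol(codes)
  if (nsites == 0L) stop("empty alignment")
  nonmiss <- colSums(!is.na(codes))
  keep <- nonmiss > 0L
  n_informative <- sum(nonmiss >= 2L)
  codes <- codes[, keep, drop = FALSE]
  if (ncol(codes) > 0L) {
    key <- apply(codes, 2, function(col) paste(col, collapse = "."))
    first <- !duplicated(key)
    weights <- as.numeric(table(key)[key[first]])
    codes <- codes[, first, drop = FALSE]
  } else {
    weights <- numeric(0)
  }
  structure(list(ids = as.character(ids), codes = codes, weights = weights,
                 nsites = nsites, n_all_missing = sum(!keep),
                 n_informative = n_informative),
            class = "quartet_alignment")
}

# 20 x npat tip partial matrix: unit column for a residue, ones when missing
.tip_partials <- function(code_row) {
  npat <- length(code_row)
  X <- matrix(0, 20L, npat)
  miss <- is.na(code_row)
  if (any(miss)) X[, miss] <- 1
  if (any(!miss)) X[cbind(code_row[!miss], which(!miss))] <- 1
  X
}

# Evaluation block: everything the C++ kernel needs except branch lengths.
# run_fclm's partitioned mode sums several blocks under shared branches.
.make_block <- function(qa, model) {
  list(X = lapply(seq_len(4L), function(i) .tip_partials(qa$codes[i, ])),
       w = qa$weights, eig = model$eig, pi = unname(model$pi),
       rates = model$rates, ncat = model$ncat, use_median = model$use_median)
}

.block_ll <- function(block, ord, br) {
  quartet_loglik_cpp(block$X[[ord[1]]], block$X[[ord[2]]],
                     block$X[[ord[3]]], block$X[[ord[4]]],
                     block$w, br, block$eig$U, block$eig$Ui,
                     block$eig$lambda, block$pi, block$rates)
}

.blocks_ll <- function(blocks, ord, br) {
  sum(vapply(blocks, .block_ll, numeric(1), ord = ord, br = br))
}

#' Log-likelihood of one quartet topology
#'
#' Felsenstein pruning under a reversible amino-acid model with
#' discrete-GAMMA rate heterogeneity (equal-weight categories). Gaps and 'X'
#' contribute all-ones tip partials; a site missing in all four taxa has
#' likelihood 1.
#'
#' @param qa a \code{quartet_alignment}.
#' @param topology "T1" (12|34), "T2" (13|24) or "T3" (14|23).
#' @param lengths five branch lengths: four pendant (in the quartet's own
#'   taxon order), then the internal branch.
#' @param model a \code{substitution_model}.
#' @return total log-likelihood.
#' @export
quartet_loglik <- function(qa, topology, lengths, model) {
  stopifnot(inherits(qa, "quartet_alignment"))
  topology <- match.arg(topology, .TOPOLOGIES)
  if (length(lengths) != 5L || any(!is.finite(lengths)) || any(lengths < 0))
    stop("lengths must be five finite nonnegative numbers")
  if (length(qa$weights) == 0L)
    stop("alignment has no sites with observed residues")
  ord <- .TOPO_ORDER[[topology]]
  # pendant lengths are indexed by taxon; reorder with the tips
  br <- c(lengths[seq_len(4L)][ord], lengths[5L])
  .blocks_ll(list(.make_block(qa, model)), ord, br)
}

# Brent ascent of one coordinate on log scale; snaps to the lower bound when
# it is as good as the interior optimum (identical sequences drive branches
# to the bound).
.opt_scalar <- function(f, value, lower, upper, ll_now) {
  o <- optimize(function(x) f(exp(x)), lower = log(lower), upper = log(upper),
                maximum = TRUE, tol = 2e-3)
  cand <- exp(o$maximum)
  obj <- o$objective
  if (cand < 1e-6) {
    at_lower <- f(lower)
    if (at_lower >= obj - 1e-9) { cand <- lower; obj <- at_lower }
  } else if (cand > upper / 2) {
    # saturation plateau: prefer the bound over creeping toward it
    at_upper <- f(upper)
    if (at_upper >= obj - 1e-9) { cand <- upper; obj <- at_upper }
  }
  if (obj > ll_now) list(value = cand, ll = obj) else list(value = value, ll = ll_now)
}

# Coordinate ascent over the five branch lengths (and optionally alpha) for
# one topology, possibly summed over partition blocks (shared branches).
.opt_quartet_core <- function(blocks, ord, br, alpha, optimize_alpha,
                              tol, max_rounds) {
  ll_fun <- function(b) .blocks_ll(blocks, ord, b)
  ll <- ll_fun(br)
  converged <- FALSE
  rounds <- 0L
  repeat {
    rounds <- rounds + 1L
    ll_round <- ll
    for (i in seq_len(5L)) {
      res <- .opt_scalar(function(x) ll_fun(replace(br, i, x)),
                         br[i], .BL_MIN, .BL_MAX, ll)
      br[i] <- res$value
      ll <- res$ll
    }
    if (optimize_alpha) {
      stopifnot(length(blocks) == 1L)
      set_alpha <- function(a) {
        blocks[[1L]]$rates <<- discrete_gamma_rates(a, blocks[[1L]]$ncat,
                                                    blocks[[1L]]$use_median)
      }
      res <- .opt_scalar(function(a) { set_alpha(a); ll_fun(br) },
                         alpha, 0.02, 50, {set_alpha(alpha); ll_fun(br)})
      alpha <- res$value
      set_alpha(alpha)
      ll <- ll_fun(br)
    }
    if (ll - ll_round < tol) { converged <- TRUE; break }
    if (rounds >= max_rounds) break
  }
  list(lengths = br, alpha = alpha, loglik = ll, converged = converged,
       rounds = rounds)
}

#' Fit branch lengths (and optionally the GAMMA shape) for one topology
#'
#' Coordinate ascent with bounded Brent steps on each of the five branch
#' lengths (bounds [1e-8, 100]) and, when requested, the shape alpha.
#' Iterates until the log-likelihood improves by less than \code{tol} or
#' \code{max_rounds} is reached. If the first start does not converge, a
#' second start at shorter initial lengths is tried and the better fit kept.
#'
#' @param qa a \code{quartet_alignment}.
#' @param topology "T1", "T2" or "T3".
#' @param model a \code{substitution_model}.
#' @param optimize_alpha also fit the GAMMA shape.
#' @param inits list (or vector) of starts tried in order; each start is a
#'   single length applied to all five branches or a full length-5 vector
#'   (pendant in the quartet's taxon order, internal last).
#' @param tol log-likelihood convergence tolerance.
#' @param max_rounds maximum ascent rounds per start.
#' @return list with \code{topology}, fitted \code{lengths} (pendant in the
#'   quartet's taxon order, internal last), \code{alpha}, \code{loglik},
#'   \code{converged} and \code{rounds}.
#' @export
optimize_quartet <- function(qa, topology, model, optimize_alpha = FALSE,
                             inits = c(0.1, 0.01), tol = 1e-4,
                             max_rounds = 50L) {
  stopifnot(inherits(qa, "quartet_alignment"))
  topology <- match.arg(topology, .TOPOLOGIES)
  if (qa$n_informative < 1L)
    stop("need at least one site with two or more observed residues")
  ord <- .TOPO_ORDER[[topology]]
  blocks <- list(.make_block(qa, model))
  if (!is.list(inits)) inits <- as.list(inits)
  best <- NULL
  for (init in inits) {
    br0 <- if (length(init) == 5L) c(init[seq_len(4L)][ord], init[5L])
           else rep(init, 5L)
    fit <- .opt_quartet_core(blocks, ord, br0, model$alpha,
                             optimize_alpha, tol, max_rounds)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
    if (best$converged) break
  }
  # kernel order -> quartet taxon order for the pendant branches
  pend <- numeric(4L)
  pend[ord] <- best$lengths[seq_len(4L)]
  list(topology = topology, lengths = c(pend, best$lengths[5L]),
       alpha = best$alpha, loglik = best$loglik,
       converged = best$converged, rounds = best$rounds)
}

#' Maximized log-likelihoods of the three quartet topologies
#'
#' Runs \code{optimize_quartet} for T1, T2 and T3 with identical settings.
#' With \code{alpha = "shared"} (default) the shape is estimated once, on the
#' best topology of a quick first pass, then held fixed for the three final
#' fits so the likelihood triple stays comparable; \code{"per_topology"}
#' refits alpha per topology and \code{"none"} keeps the model's alpha.
#'
#' @param qa a \code{quartet_alignment}.
#' @param model a \code{substitution_model}.
#' @param alpha one of "shared", "none", "per_topology".
#' @param tol,max_rounds passed to the optimizer.
#' @return list with \code{loglik} (named triple, T1 T2 T3 order),
#'   \code{fits} (the three optimizer results), \code{alpha} (value used or
#'   NA for per-topology), \code{converged}.
#' @export
evaluate_three_topologies <- function(qa, model,
                                      alpha = c("shared", "none", "per_topology"),
                                      tol = 1e-4, max_rounds = 50L) {
  alpha <- match.arg(alpha)
  if (alpha == "shared") {
    quick <- lapply(.TOPOLOGIES, function(tp)
      optimize_quartet(qa, tp, model, optimize_alpha = FALSE,
                       inits = 0.1, tol = 1e-2, max_rounds = 2L))
    names(quick) <- .TOPOLOGIES
    best_tp <- .TOPOLOGIES[which.max(vapply(quick, `[[`, numeric(1), "loglik"))]
    afit <- optimize_quartet(qa, best_tp, model, optimize_alpha = TRUE,
                             inits = list(quick[[best_tp]]$lengths, 0.01),
                             tol = tol, max_rounds = max_rounds)
    model <- update_model(model, alpha = afit$alpha)
    alpha_used <- afit$alpha
    fits <- lapply(.TOPOLOGIES, function(tp)
      optimize_quartet(qa, tp, model, optimize_alpha = FALSE,
                       inits = list(quick[[tp]]$lengths, 0.01),
                       tol = tol, max_rounds = max_rounds))
  } else {
    fits <- lapply(.TOPOLOGIES, function(tp)
      optimize_quartet(qa, tp, model, optimize_alpha = (alpha == "per_topology"),
                       tol = tol, max_rounds = max_rounds))
    alpha_used <- if (alpha == "none") model$alpha else NA_real_
  }
  names(fits) <- .TOPOLOGIES
  list(loglik = vapply(fits, `[[`, numeric(1), "loglik"),
       fits = fits, alpha = alpha_used,
       converged = all(vapply(fits, `[[`, logical(1), "converged")))
}
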