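# Four-cluster Likelihood Mapping: enumerate one-per-cluster quartets over a
# supermatrix, maximize the three topology likelihoods per quartet, convert
# the triple to posterior weights, classify, and map into the 2-simplex.

#' Assign supermatrix taxa to four clusters
#'
#' @param taxa character vector of taxon ids.
#' @param cluster parallel vector of cluster memberships: integers 1..4, or
#'   labels matched against \code{cluster_names}.
#' @param cluster_names optional length-4 character vector naming the
#'   clusters (defaults to the labels found, or "cluster1".."cluster4").
#' @return object of class \code{cluster_assignment}: list with
#'   \code{members} (list of four character vectors) and \code{names}.
#' @export
cluster_assignment <- function(taxa, cluster, cluster_names = NULL) {
  taxa <- as.character(taxa)
  if (length(taxa) != length(cluster)) stop("taxa and cluster lengths differ")
  if (anyDuplicated(taxa)) {
    dup <- taxa[duplicated(taxa)][1L]
    stop("taxon assigned more than once: ", dup)
  }
  if (is.numeric(cluster)) {
    idx <- as.integer(cluster)
    if (any(is.na(idx)) || any(idx < 1L) || any(idx > 4L))
      stop("numeric cluster indices must be in 1..4")
    if (is.null(cluster_names)) cluster_names <- paste0("cluster", 1:4)
  } else {
    lab <- as.character(cluster)
    if (is.null(cluster_names)) cluster_names <- unique(lab)
    idx <- match(lab, cluster_names)
    if (any(is.na(idx))) stop("cluster label not in cluster_names: ",
                              lab[is.na(idx)][1L])
  }
  if (length(cluster_names) != 4L) stop("exactly four clusters are required")
  members <- lapply(1:4, function(k) taxa[idx == k])
  if (any(vapply(members, length, integer(1)) == 0L))
    stop("every cluster must contain at least one taxon; empty: ",
         paste(cluster_names[vapply(members, length, integer(1)) == 0L],
               collapse = ", "))
  structure(list(members = members, names = cluster_names),
            class = "cluster_assignment")
}

#' @export
print.cluster_assignment <- function(x, ...) {
  sizes <- vapply(x$members, length, integer(1))
  cat("Four-cluster assignment:",
      paste(sprintf("%s (%d)", x$names, sizes), collapse = ", "),
      "\n", sep = " ")
  invisible(x)
}

#' Read a taxon-to-cluster table
#'
#' Two-column TSV (taxon, cluster), no header required; a header line is
#' detected and skipped if its first field is "taxon".
#'
#' @param path file path.
#' @param cluster_names optional explicit cluster order.
#' @return a \code{cluster_assignment}.
#' @export
read_clusters <- function(path, cluster_names = NULL) {
  d <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                  col.names = c("taxon", "cluster"))
  if (nrow(d) > 0 && tolower(d$taxon[1L]) == "taxon") d <- d[-1L, , drop = FALSE]
  cluster_assignment(d$taxon, d$cluster, cluster_names)
}

#' Enumerate all non-redundant one-per-cluster quartets
#'
#' Every combination of one taxon from each of the four clusters, exactly
#' once, in deterministic lexicographic order (cluster-1 member slowest,
#' cluster-4 member fastest, member order as given in the assignment).
#'
#' @param clusters a \code{cluster_assignment}.
#' @return data.frame with character columns t1..t4; \code{nrow} equals the
#'   product of the cluster sizes.
#' @export
enumerate_quartets <- function(clusters) {
  stopifnot(inherits(clusters, "cluster_assignment"))
  m <- clusters$members
  g <- expand.grid(i4 = seq_along(m[[4]]), i3 = seq_along(m[[3]]),
                   i2 = seq_along(m[[2]]), i1 = seq_along(m[[1]]),
                   KEEP.OUT.ATTRS = FALSE)
  data.frame(t1 = m[[1]][g$i1], t2 = m[[2]][g$i2],
             t3 = m[[3]][g$i3], t4 = m[[4]][g$i4],
             stringsAsFactors = FALSE)
}

#' Posterior weights of the three quartet topologies
#'
#' Normalizes the likelihood triple, \eqn{p_i = \exp(\ell_i - m) / \sum_j
#' \exp(\ell_j - m)} with \eqn{m} the maximum (log-sum-exp stabilized).
#'
#' @param logl numeric length-3 vector of log-likelihoods (finite).
#' @return numeric length-3 weights summing to 1.
#' @export
posterior_weights <- function(logl) {
  if (length(logl) != 3L || any(!is.finite(logl)))
    stop("logl must be three finite log-likelihoods")
  e <- exp(logl - max(logl))
  e / sum(e)
}

#' Classify a quartet's support pattern
#'
#' \code{mode = "argmax"}: label of the largest weight, or "tie" on an exact
#' tie (diagnostic of uninformative quartets). \code{mode = "seven_region"}:
#' "corner_Ti" when \eqn{p_i \ge} \code{tau_corner}, "center" when
#' \eqn{\max p - \min p \le} \code{tau_center}, otherwise "edge_TiTj" for the
#' two largest weights (lowest indices win deterministic tie-breaks).
#'
#' @param p weight triple.
#' @param mode "argmax" or "seven_region".
#' @param tau_corner corner threshold (default 0.9).
#' @param tau_center center threshold on max - min (default 0.05).
#' @return region label (character).
#' @export
classify_quartet <- function(p, mode = c("argmax", "seven_region"),
                             tau_corner = 0.9, tau_center = 0.05) {
  mode <- match.arg(mode)
  if (length(p) != 3L || any(!is.finite(p)) || any(p < 0))
    stop("p must be three finite nonnegative weights")
  tp <- .TOPOLOGIES
  if (mode == "argmax") {
    top <- which(p == max(p))
    return(if (length(top) > 1L) "tie" else tp[top])
  }
  if (any(p >= tau_corner)) return(paste0("corner_", tp[which.max(p)]))
  if (max(p) - min(p) <= tau_center) return("center")
  two <- order(p, decreasing = TRUE)[1:2]
  two <- sort(two)
  paste0("edge_", tp[two[1]], tp[two[2]])
}

#' Barycentric simplex coordinates of a weight triple
#'
#' Reference triangle with vertices T1 = (0, 0), T2 = (1, 0),
#' T3 = (1/2, sqrt(3)/2).
#'
#' @param p weight triple.
#' @return numeric c(x, y).
#' @export
simplex_coordinates <- function(p) {
  if (length(p) != 3L || any(!is.finite(p)))
    stop("p must be three finite weights")
  c(x = p[2] + 0.5 * p[3], y = sqrt(3) / 2 * p[3])
}

.SEVEN_REGIONS <- c("corner_T1", "corner_T2", "corner_T3",
                    "edge_T1T2", "edge_T1T3", "edge_T2T3", "center")

#' Aggregate per-quartet FcLM results
#'
#' @param results data.frame as returned in \code{run_fclm()$results}.
#' @return list with \code{n_quartets}, \code{argmax} (counts and percentages
#'   for T1, T2, T3 and ties) and \code{seven_region} (counts/percentages per
#'   region).
#' @export
summarize_fclm <- function(results) {
  n <- nrow(results)
  if (n == 0L) stop("no quartet results to summarize")
  am <- table(factor(results$argmax, levels = c(.TOPOLOGIES, "tie")))
  sr <- table(factor(results$seven_region, levels = .SEVEN_REGIONS))
  list(n_quartets = n,
       argmax = data.frame(label = names(am), count = as.integer(am),
                           percent = 100 * as.integer(am) / n),
       seven_region = data.frame(label = names(sr), count = as.integer(sr),
                                 percent = 100 * as.integer(sr) / n))
}

#' Run Four-cluster Likelihood Mapping over a supermatrix
#'
#' For every enumerated quartet (optionally a seeded uniform subsample), the
#' four rows are extracted, columns missing in all four taxa are dropped, the
#' three topologies are fitted by maximum likelihood, and the likelihood
#' triple is converted to posterior weights, a region label and simplex
#' coordinates. Quartets without informative sites get weights (1/3, 1/3,
#' 1/3) and are flagged uninformative.
#'
#' @param sm a \code{supermatrix}.
#' @param clusters a \code{cluster_assignment}; all members must be rows of
#'   the supermatrix.
#' @param model a \code{substitution_model}; default LG with empirical
#'   frequencies of the supermatrix, alpha = 1, four median GAMMA categories.
#' @param partitioned evaluate per-partition models with branch lengths
#'   shared across partitions (log-likelihoods summed over partitions).
#' @param partition_models named list (by partition gene id) of
#'   \code{substitution_model}s for \code{partitioned = TRUE}; default: the
#'   unpartitioned model with each partition's empirical frequencies.
#' @param alpha shape handling for the unpartitioned fit, see
#'   \code{\link{evaluate_three_topologies}}; in partitioned mode the shapes
#'   come from the partition models and are not re-fitted.
#' @param max_quartets optional cap; a uniform subsample without replacement
#'   is drawn with \code{seed}.
#' @param seed RNG seed used only for subsampling.
#' @param tau_corner,tau_center seven-region thresholds.
#' @param verbose print progress every 50 quartets.
#' @return list with \code{results} (one row per quartet: ids, logL triple,
#'   weights, argmax and seven-region labels, x, y, flags) and
#'   \code{summary} (see \code{\link{summarize_fclm}}).
#' @export
run_fclm <- function(sm, clusters, model = NULL, partitioned = FALSE,
                     partition_models = NULL,
                     alpha = c("shared", "none", "per_topology"),
                     max_quartets = NULL, seed = NULL,
                     tau_corner = 0.9, tau_center = 0.05, verbose = FALSE) {
  stopifnot(inherits(sm, "supermatrix"), inherits(clusters, "cluster_assignment"))
  alpha <- match.arg(alpha)
  taxa <- unlist(clusters$members)
  missing_taxa <- setdiff(taxa, sm$taxa)
  if (length(missing_taxa) > 0)
    stop("clustered taxa absent from supermatrix: ",
         paste(head(missing_taxa, 5), collapse = ", "))
  if (is.null(model))
    model <- substitution_model("LG", pi = empirical_frequencies(sm$seqs))
  quartets <- enumerate_quartets(clusters)
  n_total <- nrow(quartets)
  if (!is.null(max_quartets) && max_quartets < n_total) {
    if (!is.null(seed)) set.seed(seed)
    quartets <- quartets[sort(sample.int(n_total, max_quartets)), , drop = FALSE]
  }
  codes <- encode_aa(sm$seqs)
  rownames(codes) <- sm$taxa
  if (partitioned) {
    parts <- sm$partitions
    if (is.null(partition_models))
      partition_models <- lapply(seq_len(nrow(parts)), function(i)
        update_model(model, pi = empirical_frequencies(
          substr(sm$seqs, parts$start[i], parts$end[i]))))
    if (length(partition_models) != nrow(parts))
      stop("need one model per partition")
  }

  one_quartet <- function(ids) {
    qa <- .qa_from_codes(ids, codes[ids, , drop = FALSE])
    if (qa$n_informative == 0L) {
      p <- rep(1 / 3, 3)
      ll <- rep(NA_real_, 3)
      conv <- NA
      uninf <- TRUE
    } else if (!partitioned) {
      ev <- evaluate_three_topologies(qa, model, alpha = alpha)
      ll <- ev$loglik
      p <- posterior_weights(ll)
      conv <- ev$converged
      uninf <- FALSE
    } else {
      ll <- .partitioned_triple(ids, codes, sm$partitions, partition_models)
      p <- posterior_weights(ll)
      conv <- TRUE
      uninf <- FALSE
    }
    xy <- simplex_coordinates(p)
    data.frame(t1 = ids[1], t2 = ids[2], t3 = ids[3], t4 = ids[4],
               logL_T1 = ll[1], logL_T2 = ll[2], logL_T3 = ll[3],
               p1 = p[1], p2 = p[2], p3 = p[3],
               argmax = classify_quartet(p, "argmax"),
               seven_region = classify_quartet(p, "seven_region",
                                               tau_corner, tau_center),
               x = xy[1], y = xy[2],
               uninformative = uninf, converged = conv,
               stringsAsFactors = FALSE)
  }

  rows <- vector("list", nrow(quartets))
  for (i in seq_len(nrow(quartets))) {
    rows[[i]] <- one_quartet(as.character(unlist(quartets[i, ])))
    if (verbose && i %% 50 == 0)
      message("  quartet ", i, "/", nrow(quartets))
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  out <- list(results = results, summary = summarize_fclm(results),
              n_enumerated = n_total, clusters = clusters)
  class(out) <- "fclm_result"
  out
}

# Partitioned triple: per-partition quartet alignments and models, branch
# lengths shared across partitions, log-likelihoods summed over partitions.
.partitioned_triple <- function(ids, codes, partitions, partition_models) {
  blocks <- list()
  for (i in seq_len(nrow(partitions))) {
    sub <- codes[ids, partitions$start[i]:partitions$end[i], drop = FALSE]
    qa <- .qa_from_codes(ids, sub)
    if (qa$n_informative == 0L) next
    blocks[[length(blocks) + 1L]] <- .make_block(qa, partition_models[[i]])
  }
  if (length(blocks) == 0L) return(rep(0, 3))
  vapply(.TOPOLOGIES, function(tp) {
    ord <- .TOPO_ORDER[[tp]]
    best <- NULL
    for (init in c(0.1, 0.01)) {
      fit <- .opt_quartet_core(blocks, ord, rep(init, 5L), NA_real_,
                               optimize_alpha = FALSE, tol = 1e-4,
                               max_rounds = 50L)
      if (is.null(best) || fit$loglik > best$loglik) best <- fit
      if (best$converged) break
    }
    best$loglik
  }, numeric(1))
}

#' @export
print.fclm_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("FcLM over %d quartets (%d enumerated)\n",
              s$n_quartets, x$n_enumerated))
  cat("  argmax support: ",
      paste(sprintf("%s %.1f%%", s$argmax$label, s$argmax$percent),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}
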