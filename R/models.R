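#' Read an amino-acid exchangeability matrix in PAML dat layout
#'
#' Parses the standard PAML \code{.dat} layout: 19 rows giving the lower
#' triangle of the symmetric 20x20 exchangeability matrix (residue order
#' A R N D C Q E G H I L K M F P S T W Y V), followed by a line of 20
#' stationary frequencies. Blank lines are ignored.
#'
#' @param path file path.
#' @return list with \code{S} (symmetric 20x20 matrix, zero diagonal) and
#'   \code{pi} (length-20 frequencies, renormalized to sum exactly to 1).
#' @export
read_paml_dat <- function(path) {
  tok <- scan(path, what = numeric(), quiet = TRUE)
  if (length(tok) < 210)
    stop("expected at least 210 numbers (190 exchangeabilities + 20 frequencies), got ",
         length(tok))
  S <- matrix(0, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  k <- 1L
  for (i in 2:20) {
    S[i, 1:(i - 1)] <- tok[k:(k + i - 2)]
    k <- k + i - 1L
  }
  S <- S + t(S)
  pi <- tok[k:(k + 19)]
  if (any(pi <= 0)) stop("frequencies in ", path, " must be strictly positive")
  pi <- pi / sum(pi)
  names(pi) <- AA_ALPHABET
  list(S = S, pi = pi)
}

.load_builtin_model <- function(name) {
  key <- paste0("dat_", name)
  if (!is.null(.fclmap_cache[[key]])) return(.fclmap_cache[[key]])
  m <- if (name == "POISSON") {
    S <- matrix(1, 20, 20, dimnames = list(AA_ALPHABET, AA_ALPHABET))
    diag(S) <- 0
    list(S = S, pi = setNames(rep(1 / 20, 20), AA_ALPHABET))
  } else {
    path <- system.file("extdata", paste0(tolower(name), ".dat"),
                        package = "fclmap", mustWork = TRUE)
    read_paml_dat(path)
  }
  .fclmap_cache[[key]] <- m
  m
}

#' Names of the packaged exchangeability matrices
#' @return character vector.
#' @export
aa_models <- function() c("LG", "WAG", "POISSON")

#' Build a normalized rate matrix from exchangeabilities and frequencies
#'
#' Constructs the GTR-form generator \eqn{Q_{ij} = S_{ij} \pi_j} (i != j),
#' with the diagonal set so rows sum to zero, rescaled so the mean
#' substitution rate \eqn{-\sum_i \pi_i Q_{ii}} is exactly 1, i.e. branch
#' lengths are in expected substitutions per site.
#'
#' @param S symmetric 20x20 exchangeability matrix with nonnegative
#'   off-diagonal entries; the diagonal is ignored.
#' @param pi strictly positive stationary frequencies summing to 1.
#' @return 20x20 rate matrix Q.
#' @export
build_rate_matrix <- function(S, pi) {
  if (!is.matrix(S) || nrow(S) != ncol(S))
    stop("S must be a square matrix")
  n <- nrow(S)
  if (length(pi) != n) stop("length(pi) must match nrow(S)")
  offdiag <- S[row(S) != col(S)]
  if (any(offdiag < 0)) stop("S has negative off-diagonal entries")
  if (max(abs(S - t(S))) > 1e-8) stop("S must be symmetric")
  if (any(pi <= 0)) stop("pi must be strictly positive")
  if (abs(sum(pi) - 1) > 1e-8) stop("pi must sum to 1")
  Q <- S * rep(pi, each = n)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix: zero mean rate")
  Q <- Q / scale
  dimnames(Q) <- dimnames(S)
  Q
}

#' Discrete-GAMMA rate categories
#'
#' Equal-probability discretization of the Gamma(alpha, alpha) site-rate
#' distribution. \code{use_median = FALSE} uses the within-category expected
#' rate (mean mode); \code{use_median = TRUE} uses the category median
#' quantile. Both modes are renormalized to mean exactly 1 so that branch
#' lengths keep their expected-substitutions interpretation (the raw category
#' medians do not average to 1).
#'
#' @param alpha GAMMA shape parameter (> 0).
#' @param ncat number of categories (>= 1).
#' @param use_median logical; use category medians instead of means.
#' @return numeric vector of \code{ncat} nondecreasing rates with mean 1.
#' @export
discrete_gamma_rates <- function(alpha, ncat = 4L, use_median = FALSE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) || alpha <= 0)
    stop("alpha must be a single positive number")
  ncat <- as.integer(ncat)
  if (ncat < 1L) stop("ncat must be >= 1")
  if (ncat == 1L) return(1)
  if (use_median) {
    r <- qgamma((seq_len(ncat) - 0.5) / ncat, shape = alpha, rate = alpha)
  } else {
    # E[X | q_{i-1} < X <= q_i] * ncat via the Gamma(alpha+1, alpha) identity
    bounds <- qgamma(seq(0, 1, length.out = ncat + 1), shape = alpha, rate = alpha)
    p <- pgamma(bounds, shape = alpha + 1, rate = alpha)
    r <- diff(p) * ncat
  }
  r / mean(r)
}

#' Empirical amino-acid frequencies of an alignment
#'
#' Observed residue proportions over all sequences; gaps, 'X' and any symbol
#' outside the 20 canonical residues are excluded. A pseudo-count keeps every
#' frequency strictly positive so the frequencies are usable in a rate matrix.
#'
#' @param seqs character vector of (aligned or unaligned) sequences.
#' @param pseudocount added to each residue count (default 1e-6).
#' @return named length-20 frequency vector summing to 1.
#' @export
empirical_frequencies <- function(seqs, pseudocount = 1e-6) {
  if (length(seqs) == 0) stop("no sequences")
  ch <- unlist(strsplit(toupper(paste(seqs, collapse = "")), "", fixed = TRUE))
  counts <- table(factor(ch, levels = AA_ALPHABET))
  f <- as.numeric(counts) + pseudocount
  setNames(f / sum(f), AA_ALPHABET)
}

# Symmetric eigendecomposition of a reversible Q: with D = diag(sqrt(pi)),
# B = D Q D^{-1} is symmetric; P(t) = U exp(L t) Ui with U = D^{-1} V,
# Ui = V' D. Reused by every transition-probability computation.
.decompose_q <- function(Q, pi) {
  d <- sqrt(pi)
  B <- Q * (d %o% (1 / d))
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(U = e$vectors / d, Ui = t(e$vectors) * rep(d, each = length(d)),
       lambda = e$values)
}

#' Construct an amino-acid substitution model
#'
#' Bundles exchangeabilities, stationary frequencies, the normalized rate
#' matrix, its eigendecomposition, and the discrete-GAMMA rate categories.
#' The default follows the configuration used for large supermatrix work:
#' LG exchangeabilities, empirical (+F) or model frequencies, four GAMMA
#' categories using the category median.
#'
#' @param name one of \code{aa_models()}, or an arbitrary label when
#'   \code{exchange} is supplied.
#' @param pi stationary frequencies; \code{NULL} uses the model's published
#'   frequencies (uniform for POISSON). Supply
#'   \code{empirical_frequencies(seqs)} for the +F variant.
#' @param alpha GAMMA shape (> 0).
#' @param ncat number of GAMMA categories.
#' @param use_median use category medians for the discrete approximation
#'   (default TRUE).
#' @param exchange optional user 20x20 symmetric exchangeability matrix
#'   overriding the packaged ones (e.g. from \code{read_paml_dat}).
#' @return object of class \code{substitution_model}.
#' @export
substitution_model <- function(name = "LG", pi = NULL, alpha = 1, ncat = 4L,
                               use_median = TRUE, exchange = NULL) {
  if (is.null(exchange)) {
    name <- match.arg(toupper(name), aa_models())
    base <- .load_builtin_model(name)
    S <- base$S
    if (is.null(pi)) pi <- base$pi
  } else {
    S <- exchange
    if (is.null(pi)) stop("pi must be supplied with a user exchangeability matrix")
  }
  pi <- pi / sum(pi)
  Q <- build_rate_matrix(S, pi)
  rates <- discrete_gamma_rates(alpha, ncat, use_median)
  structure(list(name = name, S = S, pi = pi, alpha = alpha,
                 ncat = as.integer(ncat), use_median = use_median,
                 Q = Q, eig = .decompose_q(Q, pi), rates = rates),
            class = "substitution_model")
}

#' Replace parameters of a substitution model
#'
#' Rebuilds the derived quantities (Q, eigendecomposition, GAMMA rates) after
#' changing frequencies and/or shape.
#'
#' @param model a \code{substitution_model}.
#' @param pi new frequencies (optional).
#' @param alpha new GAMMA shape (optional).
#' @return updated \code{substitution_model}.
#' @export
update_model <- function(model, pi = NULL, alpha = NULL) {
  stopifnot(inherits(model, "substitution_model"))
  substitution_model(name = model$name,
                     pi = if (is.null(pi)) model$pi else pi,
                     alpha = if (is.null(alpha)) model$alpha else alpha,
                     ncat = model$ncat, use_median = model$use_median,
                     exchange = if (model$name %in% aa_models()) NULL else model$S)
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf("Amino-acid substitution model %s, GAMMA(alpha = %.4g, %d categories, %s)\n",
              x$name, x$alpha, x$ncat, if (x$use_median) "median" else "mean"))
  invisible(x)
}

#' Transition probability matrix P(t r)
#'
#' Matrix exponential \eqn{P = \exp(Q t r)} computed through the
#' pi-symmetrized eigendecomposition of the reversible rate matrix. Tiny
#' negative entries arising from round-off are clamped to zero.
#'
#' @param model a \code{substitution_model} (or a list with elements
#'   \code{eig} as produced internally).
#' @param t branch length (>= 0, finite).
#' @param rate site-rate multiplier (default 1).
#' @return 20x20 row-stochastic matrix.
#' @export
transition_probabilities <- function(model, t, rate = 1) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("t must be a single finite nonnegative number")
  if (!is.finite(rate) || rate < 0) stop("rate must be finite and nonnegative")
  e <- model$eig
  P <- e$U %*% (exp(e$lambda * t * rate) * e$Ui)
  P[P < 0] <- 0
  dimnames(P) <- dimnames(model$Q)
  P
}
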