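# Alignment refinement: stop-codon handling, BLOSUM62-distance outlier
# detection against a reference set, profile re-alignment of flagged rows
# onto the reference backbone, and a two-pass pipeline that removes
# persistent outliers and gap-only columns.

.blosum62 <- function() {
  if (is.null(.fclmap_cache$B62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .fclmap_cache$B62 <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  }
  .fclmap_cache$B62
}

#' Remove terminal and mask internal stop codons
#'
#' Trailing '*' are removed; internal '*' become 'X'.
#'
#' @param sequence amino-acid string, possibly with '*'.
#' @return cleaned string (empty, with a warning, if nothing remains).
#' @export
mask_stops <- function(sequence) {
  out <- sub("\\*+$", "", sequence)
  out <- gsub("*", "X", out, fixed = TRUE)
  if (nchar(out) == 0L && nchar(sequence) > 0L)
    warning("sequence consisted only of stop codons")
  out
}

#' BLOSUM62 distance between two aligned rows
#'
#' Over the overlap (columns where both rows carry one of the 20 residues),
#' \eqn{d = 1 - 2 S_{ab} / (S_{aa} + S_{bb})} with \eqn{S} the summed
#' BLOSUM62 scores. The distance is 0 for identical overlapping residues,
#' symmetric, and undefined (NA) when the overlap is empty or the
#' self-score sum is not positive.
#'
#' @param a,b equal-length aligned amino-acid strings.
#' @return list with \code{distance} (NA when undefined) and \code{overlap}
#'   (number of jointly non-missing columns).
#' @export
blosum62_distance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("aligned rows must have equal length")
  B <- .blosum62()
  ca <- match(strsplit(toupper(a), "", fixed = TRUE)[[1]], AA_ALPHABET)
  cb <- match(strsplit(toupper(b), "", fixed = TRUE)[[1]], AA_ALPHABET)
  ok <- !is.na(ca) & !is.na(cb)
  overlap <- sum(ok)
  if (overlap == 0L) return(list(distance = NA_real_, overlap = 0L))
  ia <- ca[ok]; ib <- cb[ok]
  s_ab <- sum(B[cbind(ia, ib)])
  s_aa <- sum(B[cbind(ia, ia)])
  s_bb <- sum(B[cbind(ib, ib)])
  if (s_aa + s_bb <= 0) return(list(distance = NA_real_, overlap = overlap))
  list(distance = 1 - 2 * s_ab / (s_aa + s_bb), overlap = overlap)
}

#' Outlier-screening policy
#'
#' @param multiplier scale applied to (Q3 - mean) of the reference distances.
#' @param min_overlap minimum jointly aligned sites with the closest
#'   reference; rows below are flagged regardless of distance.
#' @param max_passes passes of the detect/reintegrate cycle.
#' @param cutoff_form "mean_plus_scaled_iqr_arm" (default,
#'   c = mean + multiplier * (Q3 - mean)) or "literal"
#'   (c = multiplier * (Q3 - mean)).
#' @return object of class \code{outlier_policy}.
#' @export
outlier_policy <- function(multiplier = 2.25, min_overlap = 20L,
                           max_passes = 2L,
                           cutoff_form = c("mean_plus_scaled_iqr_arm",
                                           "literal")) {
  stopifnot(multiplier > 0, min_overlap >= 1L)
  structure(list(multiplier = multiplier, min_overlap = as.integer(min_overlap),
                 max_passes = as.integer(max_passes),
                 cutoff_form = match.arg(cutoff_form)),
            class = "outlier_policy")
}

#' Flag outlier sequences by BLOSUM62 distance to a reference set
#'
#' Reference statistics (mean, median, quartiles) are computed from all
#' pairwise reference distances; the cutoff follows the policy's
#' \code{cutoff_form}. Each non-reference row is compared to every
#' reference; it is flagged iff its minimal distance exceeds the cutoff, or
#' its overlap with the closest (by distance) reference is below
#' \code{min_overlap}, or no distance is defined at all ("no_overlap").
#'
#' @param msa named character vector of aligned rows.
#' @param reference_ids at least three rows used as references.
#' @param policy an \code{outlier_policy}.
#' @return object of class \code{outlier_report}: list with \code{table}
#'   (per non-reference row: distance, closest reference, overlap, cutoff,
#'   flagged, reason), \code{reference_stats} and \code{cutoff}.
#' @export
detect_outliers <- function(msa, reference_ids, policy = outlier_policy()) {
  if (is.null(names(msa)) || anyDuplicated(names(msa)))
    stop("msa rows must be uniquely named")
  if (!all(reference_ids %in% names(msa)))
    stop("reference ids missing from alignment")
  if (length(reference_ids) < 3L)
    stop("at least three reference sequences are required for quartiles")
  refs <- msa[reference_ids]
  pairs <- utils::combn(reference_ids, 2L)
  ref_d <- apply(pairs, 2L, function(pr)
    blosum62_distance(refs[[pr[1]]], refs[[pr[2]]])$distance)
  if (all(is.na(ref_d))) stop("no reference pair overlaps")
  ref_d <- ref_d[!is.na(ref_d)]
  q <- quantile(ref_d, c(0.25, 0.5, 0.75), names = FALSE)
  stats <- c(mean = mean(ref_d), median = q[2], q1 = q[1], q3 = q[3])
  arm <- policy$multiplier * (stats[["q3"]] - stats[["mean"]])
  cutoff <- if (policy$cutoff_form == "literal") arm else stats[["mean"]] + arm

  query_ids <- setdiff(names(msa), reference_ids)
  rows <- lapply(query_ids, function(id) {
    d <- vapply(reference_ids, function(r) {
      bd <- blosum62_distance(msa[[id]], refs[[r]])
      c(bd$distance %||% NA_real_, bd$overlap)
    }, numeric(2))
    dist <- d[1L, ]
    if (all(is.na(dist)))
      return(data.frame(id = id, distance = NA_real_,
                        closest_ref = NA_character_, overlap = 0L,
                        cutoff = cutoff, flagged = TRUE,
                        reason = "no_overlap", stringsAsFactors = FALSE))
    best <- which.min(dist)
    ovl <- as.integer(d[2L, best])
    over_cut <- dist[best] > cutoff
    low_ovl <- ovl < policy$min_overlap
    data.frame(id = id, distance = dist[best],
               closest_ref = reference_ids[best], overlap = ovl,
               cutoff = cutoff, flagged = over_cut || low_ovl,
               reason = if (over_cut && low_ovl) "distance+overlap"
                        else if (over_cut) "distance"
                        else if (low_ovl) "overlap"
                        else "pass",
               stringsAsFactors = FALSE)
  })
  table <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(id = character(), distance = numeric(),
               closest_ref = character(), overlap = integer(),
               cutoff = numeric(), flagged = logical(), reason = character(),
               stringsAsFactors = FALSE)
  structure(list(table = table, reference_stats = stats, cutoff = cutoff),
            class = "outlier_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Globally align a sequence to a reference-backbone profile
#'
#' Needleman-Wunsch/Gotoh alignment of an ungapped sequence against the
#' column profile of a fixed backbone alignment (BLOSUM62; a column's score
#' for residue a is the frequency-weighted mean BLOSUM62 score against the
#' column's residues; affine gaps, open 10, extend 1). Insertions relative to
#' the backbone are trimmed so the returned row has exactly the backbone's
#' column count.
#'
#' @param sequence ungapped amino-acid string.
#' @param backbone named character vector: the reference-only alignment.
#' @param gap_open,gap_extend affine gap penalties (positive).
#' @return list with \code{row} (the sequence in backbone coordinates),
#'   \code{score} and \code{n_trimmed} (residues dropped as insertions).
#' @export
profile_align <- function(sequence, backbone, gap_open = 10, gap_extend = 1) {
  if (nchar(sequence) == 0L) stop("empty sequence")
  B <- .blosum62()
  bb <- encode_aa(backbone)
  n <- ncol(bb)                       # backbone columns
  res <- match(strsplit(toupper(sequence), "", fixed = TRUE)[[1]], AA_ALPHABET)
  if (any(is.na(res))) {
    # non-residue symbols (X etc.) score 0 against every column
    B <- rbind(B, 0)
    res[is.na(res)] <- 21L
  }
  m <- length(res)
  # column score profile: n x nrow(B)
  prof <- matrix(0, n, ncol(B))
  for (j in seq_len(n)) {
    col <- bb[, j]
    col <- col[!is.na(col)]
    if (length(col) > 0L) prof[j, ] <- colMeans(B[col, , drop = FALSE])
  }
  S <- t(prof[, res, drop = FALSE])   # m x n substitution scores

  NEG <- -1e18
  # M: res i aligned to col j; X: col j gapped (deletion in sequence);
  # Y: res i is an insertion (no backbone column)
  M <- matrix(NEG, m + 1L, n + 1L)
  X <- matrix(NEG, m + 1L, n + 1L)
  Y <- matrix(NEG, m + 1L, n + 1L)
  M[1L, 1L] <- 0
  X[1L, -1L] <- -gap_open - gap_extend * (seq_len(n) - 1L)
  Y[-1L, 1L] <- -gap_open - gap_extend * (seq_len(m) - 1L)
  for (i in seq_len(m) + 1L) {
    prevM <- M[i - 1L, ]; prevX <- X[i - 1L, ]; prevY <- Y[i - 1L, ]
    diagbest <- pmax(prevM, prevX, prevY)
    Yi <- pmax(pmax(prevM, prevX) - gap_open, prevY - gap_extend)
    Y[i, ] <- Yi
    Mi <- M[i, ]; Xi <- X[i, ]
    srow <- S[i - 1L, ]
    for (j in seq_len(n) + 1L) {
      Mi[j] <- diagbest[j - 1L] + srow[j - 1L]
      Xi[j] <- max(Mi[j - 1L] - gap_open, Yi[j - 1L] - gap_open,
                   Xi[j - 1L] - gap_extend)
    }
    M[i, ] <- Mi; X[i, ] <- Xi
  }
  score <- max(M[m + 1L, n + 1L], X[m + 1L, n + 1L], Y[m + 1L, n + 1L])

  # traceback: recompute state choices greedily from the filled matrices
  out <- rep("-", n)
  i <- m + 1L; j <- n + 1L
  state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
  n_trimmed <- 0L
  aa <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  while (i > 1L || j > 1L) {
    if (state == 1L) {                 # M: consume residue and column
      out[j - 1L] <- aa[i - 1L]
      i <- i - 1L; j <- j - 1L
      state <- which.max(c(M[i, j], X[i, j], Y[i, j]))
    } else if (state == 2L) {          # X: gap in sequence at this column
      j <- j - 1L
      cand <- c(M[i, j] - gap_open, Y[i, j] - gap_open, X[i, j] - gap_extend)
      state <- c(1L, 3L, 2L)[which.max(cand)]
    } else {                           # Y: residue is an insertion; trim it
      n_trimmed <- n_trimmed + 1L
      i <- i - 1L
      cand <- c(M[i, j] - gap_open, X[i, j] - gap_open, Y[i, j] - gap_extend)
      state <- c(1L, 2L, 3L)[which.max(cand)]
    }
  }
  list(row = paste(out, collapse = ""), score = score, n_trimmed = n_trimmed)
}

#' Two-pass outlier screening with re-alignment rescue
#'
#' Pass 1 flags outliers; flagged rows are stripped of gaps, re-aligned to
#' the reference-only backbone and reintegrated; pass 2 re-screens and rows
#' still flagged are removed. Gap-only columns are dropped at the end.
#'
#' @param msa named character vector of aligned rows.
#' @param reference_ids reference rows (never removed).
#' @param policy an \code{outlier_policy}.
#' @return list with \code{msa} (cleaned), \code{removed} (ids),
#'   \code{reports} (per pass), \code{n_gap_columns_dropped} and
#'   \code{reintegrated} (ids re-aligned after pass 1).
#' @export
qc_pipeline <- function(msa, reference_ids, policy = outlier_policy()) {
  rep1 <- detect_outliers(msa, reference_ids, policy)
  flagged <- rep1$table$id[rep1$table$flagged]
  backbone <- msa[reference_ids]
  for (id in flagged) {
    raw <- gsub("[-]", "", msa[[id]])
    if (nchar(raw) == 0L) next
    msa[[id]] <- profile_align(raw, backbone)$row
  }
  rep2 <- detect_outliers(msa, reference_ids, policy)
  persistent <- rep2$table$id[rep2$table$flagged]
  # only rows flagged in pass 1 were re-examined candidates for removal;
  # pass 2 is a fresh screen of everything, matching a repeated check
  msa <- msa[!(names(msa) %in% persistent)]
  gapchar <- do.call(rbind, strsplit(unname(msa), "", fixed = TRUE))
  gap_only <- apply(gapchar == "-", 2L, all)
  if (any(gap_only)) {
    kept <- apply(gapchar[, !gap_only, drop = FALSE], 1L, paste, collapse = "")
    msa <- setNames(kept, names(msa))
  }
  list(msa = msa, removed = persistent,
       reports = list(pass1 = rep1, pass2 = rep2),
       n_gap_columns_dropped = sum(gap_only),
       reintegrated = flagged)
}
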