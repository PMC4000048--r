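# deterministic in-distribution family: closely related rows with known
# pairwise differences
family_msa <- function() {
  base <- "MKVLITAGPTREPLDSVRFISNHSSGKMGFAIAEAAARRGANVTLVSGPVSLPTPPFVERVDVMTALEMEAAV"
  mutate <- function(s, pos, to) {
    ch <- strsplit(s, "")[[1]]; ch[pos] <- to; paste(ch, collapse = "")
  }
  c(ref1 = base,
    ref2 = mutate(base, c(3, 17, 40), c("I", "A", "S")),
    ref3 = mutate(base, c(5, 22, 51, 60), c("L", "T", "A", "K")),
    ref4 = mutate(base, c(9, 30), c("V", "N")),
    ref5 = mutate(base, c(12, 33, 44, 70), c("M", "D", "G", "L")),
    tx1  = mutate(base, c(2, 28), c("R", "Q")),
    tx2  = mutate(base, c(7, 35, 62), c("K", "E", "V")))
}

test_that("stop codons are trimmed terminally and masked internally", {
  expect_equal(mask_stops("MKV*LL*"), "MKVXLL")
  expect_equal(mask_stops("MKVLL"), "MKVLL")
  expect_warning(out <- mask_stops("***"), "stop")
  expect_equal(out, "")
  expect_equal(mask_stops("*MK*"), "XMK")
})

test_that("BLOSUM62 distance matches hand arithmetic and its invariants", {
  # identical residues -> 0
  expect_equal(blosum62_distance("ACDE", "ACDE")$distance, 0)
  # zero overlap through complementary gaps
  z <- blosum62_distance("ACDE----", "----ACDE")
  expect_true(is.na(z$distance))
  expect_equal(z$overlap, 0L)
  # hand computation: S(A,A)=4, S(W,W)=11, S(A,W)=-3
  d <- blosum62_distance("AAAA", "WWWW")
  expect_equal(d$distance, 1 - 2 * (4 * -3) / (4 * 4 + 4 * 11))
  expect_equal(d$distance, 1.4)
  expect_equal(d$overlap, 4L)
  # symmetry, and gaps/X excluded from the overlap
  a <- "ARN-XCQE"; b <- "ARNDC-QE"
  expect_equal(blosum62_distance(a, b)$distance,
               blosum62_distance(b, a)$distance)
  expect_equal(blosum62_distance(a, b)$overlap, 5L)
  expect_error(blosum62_distance("AR", "ARN"), "equal length")
})

test_that("outlier detection flags planted contaminants, not genuine rows", {
  msa <- family_msa()
  refs <- paste0("ref", 1:5)
  # contaminant: a genuine row with shuffled columns
  set.seed(5)
  msa["bad1"] <- paste(sample(strsplit(msa[["ref1"]], "")[[1]]),
                       collapse = "")
  scr <- detect_outliers(msa, refs)
  tab <- scr$table
  expect_true(tab$flagged[tab$id == "bad1"])
  expect_false(any(tab$flagged[tab$id %in% c("tx1", "tx2")]))
  # reference stats agree with direct recomputation from the pairs
  pr <- combn(refs, 2)
  dists <- apply(pr, 2, function(p)
    blosum62_distance(msa[[p[1]]], msa[[p[2]]])$distance)
  expect_equal(unname(scr$reference_stats["mean"]), mean(dists))
  expect_equal(unname(scr$reference_stats["q3"]),
               unname(quantile(dists, 0.75)))
  expect_equal(scr$cutoff,
               mean(dists) + 2.25 * (quantile(dists, 0.75, names = FALSE) -
                                       mean(dists)))
  # the literal cutoff form is selectable and smaller
  rep_lit <- detect_outliers(msa, refs,
                             outlier_policy(cutoff_form = "literal"))
  expect_lt(rep_lit$cutoff, scr$cutoff)
  expect_error(detect_outliers(msa, refs[1:2]), "three")
})

test_that("short overlap with the closest reference is flagged regardless", {
  msa <- family_msa()
  refs <- paste0("ref", 1:5)
  # identical to ref1 over only 10 columns, gaps elsewhere
  stub <- paste0(substr(msa[["ref1"]], 1, 10),
                 strrep("-", nchar(msa[["ref1"]]) - 10))
  msa["short"] <- stub
  tab <- detect_outliers(msa, refs)$table
  row <- tab[tab$id == "short", ]
  expect_true(row$flagged)
  expect_equal(row$reason, "overlap")
  expect_equal(row$overlap, 10L)
  expect_equal(row$distance, 0)   # identical where it overlaps
  # identical full-length copy of a reference passes
  msa2 <- family_msa()
  msa2["copy"] <- msa2[["ref3"]]
  tab2 <- detect_outliers(msa2, refs)$table
  expect_false(tab2$flagged[tab2$id == "copy"])
})

test_that("profile alignment reproduces backbone placement and trims inserts", {
  msa <- family_msa()
  refs <- msa[paste0("ref", 1:5)]
  # introduce a shared gap region into the backbone
  gapped <- vapply(refs, function(s)
    paste0(substr(s, 1, 30), "----", substr(s, 31, nchar(s))),
    character(1))
  # self-alignment: ungapped ref1 must recover its own gap pattern
  res <- profile_align(gsub("-", "", gapped[["ref1"]]), gapped)
  expect_equal(res$row, gapped[["ref1"]])
  expect_equal(res$n_trimmed, 0L)
  # five leading extra residues are trimmed as insertions
  res2 <- profile_align(paste0("MMMMM", gsub("-", "", gapped[["ref2"]])),
                        gapped)
  expect_equal(res2$n_trimmed, 5L)
  expect_equal(res2$row, gapped[["ref2"]])
  expect_error(profile_align("", gapped), "empty")
})

test_that("returned placement scores at least as high as random placements", {
  msa <- family_msa()
  refs <- msa[paste0("ref", 1:5)]
  seq <- substr(msa[["tx1"]], 6, 50)   # a fragment to place
  res <- profile_align(seq, refs)
  # independent scorer for an arbitrary gapped placement
  B <- local({
    e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
    e$BLOSUM62
  })
  alphabet <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  score_row <- function(row) {
    rc <- strsplit(row, "")[[1]]
    bb <- lapply(refs, function(s) strsplit(s, "")[[1]])
    total <- 0
    run <- 0
    for (j in seq_along(rc)) {
      if (rc[j] == "-") { run <- run + 1; next }
      if (run > 0) { total <- total - 10 - 1 * (run - 1); run <- 0 }
      cols <- vapply(bb, `[[`, character(1), j)
      cols <- cols[cols %in% alphabet]
      if (length(cols) > 0)
        total <- total + mean(B[rc[j], cols])
    }
    if (run > 0) total <- total - 10 - 1 * (run - 1)
    total
  }
  set.seed(8)
  n <- nchar(refs[[1]])
  m <- nchar(seq)
  for (i in 1:100) {
    gaps <- sort(sample(n, n - m))
    row <- character(n); row[gaps] <- "-"
    row[setdiff(seq_len(n), gaps)] <- strsplit(seq, "")[[1]]
    expect_gte(res$score + 1e-9, score_row(paste(row, collapse = "")))
  }
})

test_that("two-pass pipeline rescues shifted rows and removes contaminants", {
  msa <- family_msa()
  refs <- paste0("ref", 1:5)
  clean <- qc_pipeline(msa, refs)
  expect_length(clean$removed, 0)
  expect_equal(clean$n_gap_columns_dropped, 0L)
  expect_identical(clean$msa, msa)

  # rescuable row: correct sequence with a corrupted gap pattern
  L <- nchar(msa[["ref1"]])
  shifted <- paste0(strrep("-", 35), substr(msa[["tx1"]], 1, L - 35))
  msa_s <- c(msa, shifted = shifted)
  out <- qc_pipeline(msa_s, refs)
  expect_true("shifted" %in% out$reintegrated)
  expect_false("shifted" %in% out$removed)
  expect_equal(out$msa[["shifted"]],
               paste0(substr(msa[["tx1"]], 1, L - 35), strrep("-", 35)))

  # true contaminant: flagged in both passes, removed, and the columns only
  # it occupied disappear
  set.seed(11)
  contaminated <- vapply(msa, function(s) paste0(s, "---"), character(1))
  bad <- paste(c(sample(strsplit(msa[["ref2"]], "")[[1]], L), "WWW"),
               collapse = "")
  contaminated <- c(contaminated, bad1 = bad)
  out2 <- qc_pipeline(contaminated, refs)
  expect_identical(out2$removed, "bad1")
  expect_equal(out2$n_gap_columns_dropped, 3L)
  expect_equal(unique(nchar(out2$msa)), L)
})

test_that("screen has full sensitivity and low false-positive rate", {
  # simulated families across seeds: references + in-distribution rows +
  # shuffled contaminants
  tr <- ape::read.tree(text = paste0(
    "((r1:0.05,(q1:0.04,q2:0.04):0.02):0.03,((r2:0.05,r3:0.05):0.03,",
    "(r4:0.05,(r5:0.04,q3:0.04):0.02):0.03):0.02);"))
  m <- substitution_model("LG", alpha = 1)
  fp <- 0L; fn <- 0L; n_genuine <- 0L; n_bad <- 0L
  for (seed in 1:10) {
    aln <- simulate_alignment(tr, m, 120, seed = seed)
    inj <- inject_contaminants(aln, k = 2, mode = "shuffled",
                               seed = 1000 + seed)
    tab <- detect_outliers(inj$msa, paste0("r", 1:5))$table
    genuine <- tab$id %in% paste0("q", 1:3)
    bad <- tab$id %in% inj$contaminants
    fp <- fp + sum(tab$flagged[genuine])
    fn <- fn + sum(!tab$flagged[bad])
    n_genuine <- n_genuine + sum(genuine)
    n_bad <- n_bad + sum(bad)
  }
  expect_equal(fn, 0L)                      # sensitivity 100%
  expect_lte(fp / n_genuine, 0.05)          # FPR <= 5%
})

test_that("flagging is invariant to row order and gap-only columns", {
  msa <- family_msa()
  set.seed(12)
  msa["odd"] <- paste(sample(strsplit(msa[["ref4"]], "")[[1]]),
                      collapse = "")
  refs <- paste0("ref", 1:5)
  base_tab <- detect_outliers(msa, refs)$table
  base_tab <- base_tab[order(base_tab$id), ]
  # permute rows
  perm <- detect_outliers(msa[sample(length(msa))], refs)$table
  perm <- perm[order(perm$id), ]
  rownames(base_tab) <- rownames(perm) <- NULL
  expect_equal(perm, base_tab)
  # splice gap-only columns into every row
  spliced <- vapply(msa, function(s)
    paste0(substr(s, 1, 20), "----", substr(s, 21, nchar(s))),
    character(1))
  gap_tab <- detect_outliers(spliced, refs)$table
  gap_tab <- gap_tab[order(gap_tab$id), ]
  rownames(gap_tab) <- NULL
  expect_equal(gap_tab, base_tab)
})
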