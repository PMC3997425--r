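mirna21 <- "UGACAGAAGAGAGUGAGCACA"

test_that("site scoring applies the weighted mismatch/wobble/gap scheme", {
  perfect <- revcomp(mirna21)
  expect_equal(score_site(mirna21, perfect)$penalty, 0)

  # single G:U wobble facing miRNA position 5 -> 0.5 x 2 (seed weighting)
  L <- nchar(mirna21)
  stopifnot(substr(mirna21, 5, 5) == "A")  # A has no wobble partner;
  # use position 6 (G) instead: site base C -> U gives G:U
  stopifnot(substr(mirna21, 6, 6) == "G")
  ch <- strsplit(perfect, "")[[1]]
  ch[L - 6 + 1] <- "U"
  expect_equal(score_site(mirna21, paste(ch, collapse = ""))$penalty, 1.0)

  # single mismatch at position 20 -> 1.0; at position 10 -> 2.0
  mk_mismatch <- function(k) {
    ch <- strsplit(perfect, "")[[1]]
    mb <- substr(mirna21, k, k)
    ch[L - k + 1] <- setdiff(c("A", "C", "G", "U"),
                             c(ch[L - k + 1], chartr("ACGU", "UGCA", mb),
                               if (mb == "G") "U" else if (mb == "U") "G"))[1]
    paste(ch, collapse = "")
  }
  expect_equal(score_site(mirna21, mk_mismatch(20))$penalty, 1.0)
  expect_equal(score_site(mirna21, mk_mismatch(10))$penalty, 2.0)
  expect_error(score_site(mirna21, substr(perfect, 1, L - 3)), "within 1")
})

test_that("silencing mode flips to repression on a broken duplex centre", {
  perfect <- revcomp(mirna21)
  expect_equal(call_mode(score_site(mirna21, perfect)$alignment), "C")
  L <- nchar(mirna21)
  flip <- function(k) {
    ch <- strsplit(perfect, "")[[1]]
    mb <- substr(mirna21, k, k)
    ch[L - k + 1] <- setdiff(c("A", "C", "G", "U"),
                             c(ch[L - k + 1], chartr("ACGU", "UGCA", mb),
                               if (mb == "G") "U" else if (mb == "U") "G"))[1]
    paste(ch, collapse = "")
  }
  expect_equal(call_mode(score_site(mirna21, flip(10))$alignment), "T")
  expect_equal(call_mode(score_site(mirna21, flip(2))$alignment), "C")
})

test_that("expected cleavage falls between the bases facing positions 10/11", {
  al <- score_site(mirna21, revcomp(mirna21))$alignment
  expect_equal(expected_cleavage(al, c(100, 120)), c(110, 111))
  expect_equal(expected_cleavage(al, c(1, 21)), c(11, 12))
  L <- nchar(mirna21)
  broken <- local({
    ch <- strsplit(revcomp(mirna21), "")[[1]]
    mb <- substr(mirna21, 10, 10)
    ch[L - 10 + 1] <- setdiff(c("A", "C", "G", "U"),
                              c(ch[L - 10 + 1], chartr("ACGU", "UGCA", mb),
                                if (mb == "G") "U" else if (mb == "U") "G"))[1]
    paste(ch, collapse = "")
  })
  expect_error(expected_cleavage(score_site(mirna21, broken)$alignment,
                                 c(1, 21)), "translational")
})

test_that("transcript scanning reports exactly the sub-cutoff sites in order", {
  set.seed(71)
  perfect <- as_dna(revcomp(mirna21))
  tx1 <- paste0(random_dna_str(300), perfect, random_dna_str(200))
  hits <- scan_transcripts(mirna21, c(T1 = tx1), cutoff = 3)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$penalty, 0)
  expect_equal(hits$start, 300)
  expect_equal(hits$mode, "C")
  expect_equal(hits$cleave_5p, 300 + 21 - 10)  # pairs of positions 11/10

  # a site at penalty 3.5 is not reported at cutoff 3.0
  bad <- local({
    ch <- strsplit(revcomp(mirna21), "")[[1]]
    for (k in c(3, 20)) {  # seed mismatch (2) + 3' mismatch (1) + wobble...
      mb <- substr(mirna21, k, k)
      ch[21 - k + 1] <- setdiff(c("A", "C", "G", "U"),
                                c(ch[21 - k + 1], chartr("ACGU", "UGCA", mb),
                                  if (mb == "G") "U" else if (mb == "U") "G"))[1]
    }
    mb <- substr(mirna21, 16, 16)
    if (mb %in% c("G", "U"))
      ch[21 - 16 + 1] <- if (mb == "G") "U" else "G"
    paste(ch, collapse = "")
  })
  p_bad <- score_site(mirna21, bad)$penalty
  tx2 <- paste0(random_dna_str(100), as_dna(bad), random_dna_str(100))
  hits2 <- scan_transcripts(mirna21, c(T2 = tx2), cutoff = p_bad - 0.25)
  expect_equal(nrow(hits2), 0)

  # multiple planted sites come back ordered by penalty
  one <- local({
    ch <- strsplit(revcomp(mirna21), "")[[1]]
    mb <- substr(mirna21, 20, 20)
    ch[2] <- setdiff(c("A", "C", "G", "U"),
                     c(ch[2], chartr("ACGU", "UGCA", mb),
                       if (mb == "G") "U" else if (mb == "U") "G"))[1]
    paste(ch, collapse = "")
  })
  tx3 <- c(T1 = paste0(random_dna_str(50), as_dna(one), random_dna_str(50)),
           T2 = paste0(random_dna_str(50), perfect, random_dna_str(50)))
  hits3 <- scan_transcripts(mirna21, tx3, cutoff = 3)
  expect_equal(hits3$transcript[1], "T2")
  expect_true(all(diff(hits3$penalty) >= 0))
})

test_that("scanning equals exhaustive window scoring", {
  set.seed(72)
  for (trial in 1:3) {
    mir <- random_rna(21)
    tx <- random_dna_str(250)
    # plant a near-perfect site so at least one window scores low
    site <- as_dna(revcomp(mir))
    substr(tx, 101, 100 + nchar(site)) <- site
    oracle <- oracle_all_windows(mir, as_rna(tx))
    got <- scan_transcripts(mir, c(T = tx), cutoff = 3)
    # the scanner's best hit equals the oracle's best window
    expect_equal(min(got$penalty), min(oracle$penalty))
    # every reported hit's penalty equals the oracle value for that window
    for (r in seq_len(nrow(got))) {
      w <- oracle[oracle$start1 == got$start[r] + 1 &
                    oracle$len == got$end[r] - got$start[r], ]
      expect_equal(got$penalty[r], w$penalty)
    }
    # no sub-cutoff oracle window is missed entirely (after overlap collapse)
    sub <- oracle[oracle$penalty <= 3, ]
    for (r in seq_len(nrow(sub))) {
      s0 <- sub$start1[r] - 1; e0 <- s0 + sub$len[r]
      covered <- any(got$start < e0 & got$end > s0 &
                       got$penalty <= sub$penalty[r] + 1e-9)
      expect_true(covered)
    }
  }
})

test_that("penalty never decreases when a mismatch is added", {
  set.seed(73)
  for (trial in 1:25) {
    mir <- random_rna(21)
    site <- revcomp(mir)
    p0 <- score_site(mir, site)$penalty
    ch <- strsplit(site, "")[[1]]
    k <- sample(21, 1)
    ch[k] <- setdiff(c("A", "C", "G", "U"), ch[k])[sample(3, 1)]
    p1 <- score_site(mir, paste(ch, collapse = ""))$penalty
    expect_gte(p1, p0)
  }
})

test_that("generator-planted sites are recovered according to penalty class", {
  gen <- make_genome(n_hairpins = 8, seed = 74)
  truth <- design_truth(gen$truth, n_known = 2, n_variant = 2, n_candidate = 2)
  txm <- make_transcriptome(truth, n_transcripts = 10, seed = 74)
  for (r in seq_len(nrow(txm$sites))) {
    s <- txm$sites[r, ]
    mat <- truth$mature[truth$name == s$mirna]
    hits <- scan_transcripts(mat, txm$transcripts, cutoff = 3)
    on_site <- hits[hits$transcript == s$transcript &
                      hits$start < s$start + nchar(mat) &
                      hits$end > s$start, ]
    if (s$penalty_design <= 3) {
      expect_gte(nrow(on_site), 1)
      expect_lte(min(on_site$penalty), s$penalty_design + 1e-9)
    } else {
      expect_equal(nrow(on_site), 0)
    }
  }
})
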