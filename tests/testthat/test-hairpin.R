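test_that("precursor extraction window arithmetic and clipping", {
  set.seed(41)
  ctg <- random_rna(400)
  hit <- data.frame(contig = "c", start = 150, end = 171, strand = "+",
                    seq = substr(ctg, 151, 171), stringsAsFactors = FALSE)
  p <- extract_precursor(hit, ctg, flank = 100)
  expect_equal(c(p$start, p$end), c(50, 271))
  expect_equal(nchar(p$seq), 221)
  expect_equal(p$mature_offset, 100)
  expect_equal(p$mature, as_rna(hit$seq))

  hit2 <- data.frame(contig = "c", start = 10, end = 31, strand = "+",
                     seq = substr(ctg, 11, 31), stringsAsFactors = FALSE)
  p2 <- extract_precursor(hit2, ctg, flank = 100)
  expect_equal(p2$start, 0)
  expect_equal(p2$mature_offset, 10)

  hit3 <- data.frame(contig = "c", start = 150, end = 171, strand = "-",
                     seq = revcomp(substr(ctg, 151, 171)),
                     stringsAsFactors = FALSE)
  p3 <- extract_precursor(hit3, ctg, flank = 50)
  expect_equal(p3$seq, as_rna(revcomp(substr(ctg, 101, 221))))
  expect_equal(p3$mature, as_rna(hit3$seq))
  expect_equal(substr(p3$seq, p3$mature_offset + 1,
                      p3$mature_offset + 21), p3$mature)
})

test_that("star prediction returns the planted star in the Dicer register", {
  set.seed(42)
  for (i in 1:20) {
    mature <- random_rna(21)
    prec <- make_construct(mature, loop = random_rna(sample(8:20, 1)))
    fr <- fold_hairpin(prec)
    ps <- predict_star(fr, c(1, 21), prec)
    expect_false(is.null(ps))
    truth_star <- paste0(substr(revcomp(mature), 3, 21), "GU")
    expect_equal(ps$star, truth_star)
    expect_equal(duplex_mismatches(mature, ps$star), 0)
  }
  # a fully unpaired mature yields no star
  flat <- list(structure = strrep(".", 60), score = 0,
               pair_table = rep(NA_integer_, 60))
  expect_null(predict_star(flat, c(1, 21), strrep("A", 60)))
})

test_that("duplex mismatch counting is exact, bounded and symmetric", {
  mature <- "UGACAAGUAUUUUCGGACGGA"
  star0 <- paste0(substr(revcomp(mature), 3, 21), "GU")
  expect_equal(duplex_mismatches(mature, star0), 0)

  # two substitutions at duplex-internal star positions -> 2 mismatches
  ch <- strsplit(star0, "")[[1]]
  ch[5] <- setdiff(c("A", "C", "G", "U"),
                   c(ch[5], "U", "G"))[1]  # avoid wobble with any partner
  ch[9] <- setdiff(c("A", "C", "G", "U"), c(ch[9], "U", "G"))[1]
  star2 <- paste(ch, collapse = "")
  expect_gte(duplex_mismatches(mature, star2), 2)

  # published true-novel pair passes the 4-mismatch screen
  expect_lte(duplex_mismatches("UGAUAAGUAUUUUCGGACGGA",
                               "UCCGUCCGGAAAUACUUGUCA"), 4)

  set.seed(43)
  for (i in 1:50) {
    a <- random_rna(sample(19:24, 1))
    b <- random_rna(sample(19:24, 1))
    expect_equal(duplex_mismatches(a, b), duplex_mismatches(b, a))
  }
  expect_error(duplex_mismatches(random_rna(18), random_rna(21)), "19-24")
})

test_that("hairpin screening accepts clean duplexes and rejects broken ones", {
  set.seed(44)
  mature <- random_rna(21)
  prec <- make_construct(mature, loop = random_rna(10))
  hp <- evaluate_hairpin(
    structure(list(contig = "c", start = 0, end = nchar(prec), strand = "+",
                   seq = prec, mature_offset = 0, mature = mature),
              class = "precursor"),
    fold_hairpin(prec))
  expect_true(hp$accepted)
  expect_equal(hp$duplex$mismatches, 0)
  expect_equal(hp$duplex$star, paste0(substr(revcomp(mature), 3, 21), "GU"))
  expect_true(hp$gc >= 0 && hp$gc <= 100)

  # mature placed across the terminal loop -> rejected
  off <- 14  # mature then spans stem end + loop
  hp2 <- evaluate_hairpin(
    structure(list(contig = "c", start = 0, end = nchar(prec), strand = "+",
                   seq = prec, mature_offset = off,
                   mature = substr(prec, off + 1, off + 21)),
              class = "precursor"),
    fold_hairpin(prec))
  expect_false(hp2$accepted)
})

test_that("acceptance is monotone in star-arm mutation count", {
  set.seed(45)
  for (trial in 1:100) {
    mature <- random_rna(21)
    loop <- random_rna(10)
    arm <- revcomp(mature)
    order_pos <- sample(nchar(arm))
    accepted_before <- TRUE
    seen_reject <- FALSE
    for (nm in c(0, 2, 4, 6)) {
      ch <- strsplit(arm, "")[[1]]
      for (p in order_pos[seq_len(nm)]) {
        ch[p] <- setdiff(c("A", "C", "G", "U"), ch[p])[1]
      }
      prec <- paste0(mature, loop, paste(ch, collapse = ""), "GU")
      hp <- evaluate_hairpin(
        structure(list(contig = "c", start = 0, end = nchar(prec),
                       strand = "+", seq = prec, mature_offset = 0,
                       mature = mature), class = "precursor"),
        fold_hairpin(prec))
      if (seen_reject) expect_false(hp$accepted)
      if (!hp$accepted) seen_reject <- TRUE
    }
  }
})

test_that("precursor summary statistics cover length and GC ranges", {
  set.seed(46)
  cands <- lapply(1:3, function(i) {
    mature <- random_rna(21)
    prec <- make_construct(mature, loop = random_rna(10 + 10 * i))
    evaluate_hairpin(structure(list(contig = "c", start = 0,
                                    end = nchar(prec), strand = "+",
                                    seq = prec, mature_offset = 0,
                                    mature = mature), class = "precursor"),
                     fold_hairpin(prec))
  })
  st <- precursor_stats(cands)
  expect_equal(st$n, sum(vapply(cands, `[[`, logical(1), "accepted")))
  expect_true(st$length_range[1] <= st$length_range[2])
  expect_true(st$gc_range[1] >= 0 && st$gc_range[2] <= 100)
  expect_error(precursor_stats(list()), "no accepted")
})
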