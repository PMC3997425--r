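test_that("adapter trimming keeps the insert before the exact seed", {
  expect_equal(trim_adapter("ACGTACGTAGATCGGAAG", "AGATCGGAAGAGC", seed_len = 8),
               "ACGTACGT")
  expect_true(is.na(trim_adapter("ACGTACGTACGTACGT", "AGATCGGAAGAGC",
                                 require_adapter = TRUE)))
  expect_equal(trim_adapter("ACGTACGTACGTACGT", "AGATCGGAAGAGC",
                            require_adapter = FALSE), "ACGTACGTACGTACGT")
  # read equal to adapter -> empty insert, later removed by length filter
  expect_equal(trim_adapter("AGATCGGAAGAGC", "AGATCGGAAGAGC"), "")
})

test_that("length filter is boundary-inclusive at 16 and 30 nt", {
  reads <- c(strrep("A", 15), strrep("C", 16), strrep("G", 30), strrep("U", 31))
  res <- filter_length(reads)
  expect_equal(nchar(res$kept), c(16, 30))
  expect_equal(res$removed_count, 2)
  empty <- filter_length(character(0))
  expect_equal(empty$kept, character(0))
  expect_equal(empty$removed_count, 0)
  expect_error(filter_length(reads, min = 20, max = 10), "min")
})

test_that("invalid-sequence rule flags non-ACGU and empty reads", {
  expect_equal(is_invalid(c("ACGUN", "ACGU", "", "ACGT", "ACRGU")),
               c(TRUE, FALSE, TRUE, FALSE, TRUE))
})

test_that("low-complexity rule matches its brute-force definition", {
  expect_true(is_low_complexity(strrep("A", 20)))
  expect_true(is_low_complexity(strrep("AU", 10)))
  expect_true(is_low_complexity(strrep("GCA", 7)))
  expect_false(is_low_complexity("ACGUGGCAUCGAUCCGUAAGC"))
  # screened fast path must agree with the exact rule on random reads
  set.seed(101)
  reads <- vapply(1:400, function(i) random_rna(sample(16:30, 1)), character(1))
  reads <- c(reads, strrep("A", 24), strrep("CU", 11), strrep("AGG", 8),
             paste0(strrep("AU", 9), "GGC"))
  expect_equal(is_low_complexity(reads),
               unname(hexamir:::is_low_complexity_exact(reads)))
})

test_that("contaminant filter removes exact substrings on both strands", {
  set.seed(7)
  contam <- c(rrna1 = paste0(random_rna(200)))
  inside <- substr(contam[[1]], 50, 70)
  rc_inside <- revcomp(substr(contam[[1]], 100, 120))
  absent <- random_rna(21)
  res <- filter_contaminants(c(inside, rc_inside, absent), contam)
  expect_equal(res$kept, absent)
  expect_equal(res$removed_count, 2)
  expect_warning(out <- filter_contaminants(c("ACGU"), character(0)), "empty")
  expect_equal(out$removed_count, 0)
})

test_that("collapsing preserves per-library counts and totals", {
  res <- collapse_unique(list(A = c("ACGU", "ACGU", "GGCC"), B = "ACGU"))
  expect_equal(nrow(res), 2)
  top <- res[res$seq == "ACGU", ]
  expect_equal(top$A, 2); expect_equal(top$B, 1); expect_equal(top$total_count, 3)
  expect_equal(res[res$seq == "GGCC", "total_count"], 1)

  # conservation: expanding by counts reproduces the cleaned multiset
  set.seed(11)
  libs <- list(L1 = replicate(300, random_rna(sample(16:24, 1))),
               L2 = replicate(200, random_rna(sample(16:24, 1))))
  col <- collapse_unique(libs)
  expect_equal(sum(col$total_count), 500)
  for (l in names(libs)) {
    expect_equal(sort(rep(col$seq, col[[l]])), sort(as_rna(libs[[l]])))
  }
})

test_that("elimination accounting satisfies the conservation identity", {
  s <- elimination_summary(
    total = c(redundant = 59541021, unique = 32574580),
    length_filtered = c(redundant = 15178457, unique = 11922873),
    low_complexity = c(redundant = 21131, unique = 6522),
    invalid = c(redundant = 300657, unique = 229912),
    rRNA_tRNA = c(redundant = 2455844, unique = 66367))
  expect_equal(s$unique[s$category == "putative_population"], 20348906)
  expect_equal(s$redundant[s$category == "putative_population"], 41584932)

  z <- elimination_summary(total = c(redundant = 10, unique = 5),
                           length_filtered = c(redundant = 0, unique = 0),
                           low_complexity = c(redundant = 0, unique = 0),
                           invalid = c(redundant = 0, unique = 0),
                           rRNA_tRNA = c(redundant = 0, unique = 0))
  expect_equal(z$redundant[z$category == "putative_population"], 10)
  expect_error(elimination_summary(
    total = c(redundant = 5, unique = 5),
    length_filtered = c(redundant = 10, unique = 0),
    low_complexity = c(redundant = 0, unique = 0),
    invalid = c(redundant = 0, unique = 0),
    rRNA_tRNA = c(redundant = 0, unique = 0)), "exceed")
})

test_that("length distribution tallies and percentages are exact", {
  ur <- data.frame(seq = c(strrep("A", 24), strrep("C", 24)),
                   total_count = c(6, 4))
  ld <- length_distribution(ur)
  expect_equal(ld$redundant_pct[ld$length == 24], 100)
  expect_equal(sum(ld$redundant_pct), 100)
  ur2 <- data.frame(seq = c(random_rna(21), random_rna(24)),
                    total_count = c(5, 5))
  ld2 <- length_distribution(ur2)
  expect_equal(ld2$redundant_pct[ld2$length %in% c(21, 24)], c(50, 50))

  # empirical lengths of a simulated pure-degradation library track the
  # generator weights within sampling error (3 s.d. of a binomial)
  gen <- make_genome(n_hairpins = 2, seed = 3)
  truth <- design_truth(gen$truth, n_known = 1, n_variant = 0,
                        n_candidate = 1, libs = "L1")
  sim <- simulate_libraries(truth, depth = 1e4, seed = 3,
                            libs = "L1",
                            proportions = c(mirna = 0, contaminant = 0,
                                            degradation = 1, junk = 0,
                                            invalid = 0))
  lens <- nchar(sim$reads$L1)
  w <- hexamir:::default_length_weights()
  for (L in c(21, 23, 24)) {
    p <- w[[as.character(L)]]
    tol <- 3 * sqrt(p * (1 - p) / length(lens))
    expect_lt(abs(mean(lens == L) - p), tol + 1e-9)
  }
})

test_that("the elimination pipeline is deterministic and conserves reads", {
  set.seed(21)
  contam <- stats::setNames(replicate(3, random_rna(300)), paste0("c", 1:3))
  libs <- list(
    A = c(replicate(50, random_rna(sample(16:28, 1))),
          replicate(10, random_rna(10)),                 # junk length
          vapply(1:10, function(i) {                      # contaminant windows
            s <- sample(300 - 20, 1); substr(contam[[sample(3, 1)]], s, s + 19)
          }, character(1)),
          rep(strrep("AG", 10), 5),                       # low complexity
          rep("ACGUNACGUACGUACGUACG", 3)),                # invalid
    B = replicate(40, random_rna(sample(16:28, 1))))
  r1 <- eliminate_reads(libs, contaminants = contam)
  r2 <- eliminate_reads(libs, contaminants = contam)
  expect_identical(r1$summary, r2$summary)
  s <- r1$summary
  for (tal in c("redundant", "unique")) {
    v <- function(cat) s[[tal]][s$category == cat]
    expect_equal(v("putative_population"),
                 v("total") - v("length_filtered") - v("low_complexity") -
                   v("invalid") - v("rRNA_tRNA"))
  }
  expect_equal(s$redundant[s$category == "length_filtered"], 10)
  expect_equal(s$redundant[s$category == "invalid"], 3)
  expect_equal(s$redundant[s$category == "low_complexity"], 5)
  expect_equal(sum(r1$library_totals), sum(r1$unique_reads$total_count))
})
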