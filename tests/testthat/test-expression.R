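test_that("TPM normalisation follows count / library total x 10^6", {
  counts <- matrix(c(0, 5, 1e6, 10, 0, 20), nrow = 3,
                   dimnames = list(c("m1", "m2", "m3"), c("A", "B")))
  tot <- c(A = 1e6, B = 2e6)
  tpm <- tpm_normalize(counts, tot)
  expect_equal(tpm["m1", "A"], 0)
  expect_equal(tpm["m2", "A"], 5)
  expect_equal(tpm["m3", "A"], 1e6)
  expect_equal(tpm["m3", "B"], 10)
  expect_error(tpm_normalize(counts, c(A = 0, B = 1)), "positive")
  expect_error(tpm_normalize(counts, c(A = 1e6)), "no library total")

  # column conservation: the full putative population sums to 10^6
  set.seed(61)
  full <- matrix(rpois(300, 40), ncol = 3,
                 dimnames = list(NULL, c("A", "B", "C")))
  tpm_full <- tpm_normalize(full, colSums(full))
  expect_equal(unname(colSums(tpm_full)), rep(1e6, 3), tolerance = 1e-9)
  expect_true(all((tpm_full == 0) == (full == 0)))
})

test_that("log2 fold change is exact, flagged on zeros, and antisymmetric", {
  expect_equal(log2_fold_change(4, 4)$value, 0)
  expect_equal(log2_fold_change(8, 2)$value, 2)
  z <- log2_fold_change(0, 5)
  expect_true(is.na(z$value))
  expect_equal(z$status, "undefined_zero")
  set.seed(62)
  a <- runif(50, 0.1, 100); b <- runif(50, 0.1, 100)
  expect_equal(log2_fold_change(a, b)$value, -log2_fold_change(b, a)$value)
})

test_that("differential selection is >= 2-fold, boundary inclusive", {
  fc <- matrix(c(1.0, 0.9, NA, -1.2, 0.5, NA), ncol = 2,
               dimnames = list(c("m1", "m2", "m3"), c("HS", "SS")))
  # m1: 1.0 (boundary) and -1.2 both qualify; m2 peaks at 0.9 -> excluded
  expect_equal(select_de(fc), "m1")
  expect_equal(select_de(fc, threshold = 1.3), character(0))
  allna <- matrix(NA_real_, 2, 1, dimnames = list(c("a", "b"), "HS"))
  expect_warning(out <- select_de(allna), "undefined")
  expect_equal(out, character(0))
})

test_that("Venn partitioning assigns each detected miRNA to one region", {
  counts <- matrix(c(
    5, 3, 2, 1,   # everywhere
    4, 0, 0, 0,   # shoot only
    0, 2, 0, 2,   # root & spikelet
    1, 1, 3, 0,   # shoot, root, leaf
    0, 0, 0, 0,   # undetected
    2, 0, 4, 0),  # shoot & leaf
    ncol = 4, byrow = TRUE,
    dimnames = list(paste0("m", 1:6),
                    c("shoot", "root", "leaf", "spikelet")))
  sets <- list(shoot = "shoot", root = "root", leaf = "leaf",
               spikelet = "spikelet")
  vp <- venn_partition(counts, sets)
  expect_equal(sum(vp), 5)  # m5 undetected
  expect_equal(unname(vp["shoot&root&leaf&spikelet"]), 1)
  expect_equal(unname(vp["shoot"]), 1)
  expect_equal(unname(vp["root&spikelet"]), 1)
  expect_equal(unname(vp["shoot&root&leaf"]), 1)
  expect_equal(unname(vp["shoot&leaf"]), 1)

  # brute-force region counts over random detection patterns
  set.seed(63)
  rnd <- matrix(rbinom(4 * 40, 1, 0.5) * rpois(160, 3), ncol = 4,
                dimnames = list(paste0("x", 1:40), names(sets)))
  vp2 <- venn_partition(rnd, sets)
  detected <- rowSums(rnd > 0) > 0
  expect_equal(sum(vp2), sum(detected))
  for (r in seq_len(nrow(rnd))) {
    if (!detected[r]) next
    region <- paste(names(sets)[rnd[r, ] > 0], collapse = "&")
    expect_gte(vp2[[region]], 1)
  }

  # tissue-vs-stress two-set overlap
  tv <- venn_partition(counts, list(veg = c("shoot", "root"),
                                    rep = c("leaf", "spikelet")))
  expect_equal(unname(tv["veg"] + tv["rep"] + tv["veg&rep"]), 5)
  expect_error(venn_partition(counts, rep(sets, 2)), "6 sets")
})

test_that("uncentered Pearson distance matches its formula", {
  m <- rbind(a = c(1, 0), b = c(0, 1), c = c(2, 0))
  D <- as.matrix(uncentered_pearson_dist(m))
  expect_equal(D["a", "b"], 1)   # orthogonal profiles
  expect_equal(D["a", "c"], 0)   # proportional profiles
  expect_error(uncentered_pearson_dist(rbind(a = c(0, 0), b = c(1, 1))),
               "all-zero profile 'a'")
})

test_that("average-linkage clustering agrees with brute-force UPGMA", {
  m <- rbind(a = c(10, 10, 1), b = c(10, 9, 1), c = c(1, 10, 10),
             d = c(1, 9, 10))
  h <- cluster_uncentered_average(m)
  # identical-shape profiles merge first, heights are monotone
  expect_equal(sort(h$labels[abs(h$merge[1, ])]), c("a", "b"))
  expect_true(all(diff(h$height) >= -1e-12))

  two <- cluster_uncentered_average(rbind(a = c(1, 2), b = c(2, 4)))
  expect_equal(two$height, 0)

  set.seed(64)
  for (trial in 1:100) {
    mat <- matrix(runif(64, 0.1, 10), 8, 8,
                  dimnames = list(paste0("r", 1:8), NULL))
    h <- cluster_uncentered_average(mat)
    D <- as.matrix(uncentered_pearson_dist(mat[order(rownames(mat)), ]))
    coph_pkg <- as.matrix(stats::cophenetic(h))
    coph_oracle <- oracle_upgma_cophenetic(D)
    dimnames(coph_oracle) <- dimnames(D)
    expect_equal(coph_pkg[rownames(D), colnames(D)], coph_oracle,
                 tolerance = 1e-9)
  }
})

test_that("fold-change tables and dendrogram export work together", {
  counts <- matrix(c(100, 50, 400, 50, 100, 50, 100, 200), ncol = 4,
                   dimnames = list(c("m1", "m2"),
                                   c("C", "HS", "SS", "WDS")))
  tpm <- tpm_normalize(counts, c(C = 1000, HS = 1000, SS = 1000, WDS = 1000))
  fc <- fold_change_table(tpm, list(HS = c("HS", "C"), SS = c("SS", "C"),
                                    WDS = c("WDS", "C")))
  expect_equal(fc["m1", "HS"], 2)
  expect_equal(fc["m2", "SS"], 0)
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(cluster_uncentered_average(tpm), f)
  tr <- ape::read.tree(f)
  expect_setequal(tr$tip.label, c("m1", "m2"))
})
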