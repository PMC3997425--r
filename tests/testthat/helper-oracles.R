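# Independent oracles: deliberately written with different
# decompositions/data structures than the package implementations.

# maximum pairing score over all nested structures (terminal loop >= 3),
# recursing on the LAST base (the package DP recurses on the first)
oracle_fold_score <- function(seq) {
  rna <- chartr("Tt", "Uu", toupper(seq))
  ch <- strsplit(rna, "")[[1]]
  n <- length(ch)
  sc <- function(a, b) {
    key <- paste(sort(c(a, b)), collapse = "")
    switch(key, "CG" = 3, "AU" = 2, "GU" = 1, 0)
  }
  memo <- new.env(parent = emptyenv())
  best <- function(i, j) {
    if (j - i < 4) return(0)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- best(i, j - 1)                 # j unpaired
    for (k in i:(j - 4)) {              # j pairs k
      s <- sc(ch[k], ch[j])
      if (s > 0) {
        left <- if (k > i) best(i, k - 1) else 0
        v <- max(v, s + left + best(k + 1, j - 1))
      }
    }
    memo[[key]] <- v
    v
  }
  if (n < 5) return(0)
  best(1, n)
}

# check a fold_result is a well-formed nested structure for seq
expect_valid_structure <- function(fr, seq) {
  rna <- chartr("T", "U", toupper(seq))
  ch <- strsplit(rna, "")[[1]]
  pt <- fr$pair_table
  expect_length(pt, nchar(rna))
  paired <- which(!is.na(pt))
  expect_true(all(pt[pt[paired]] == paired))          # symmetric
  opens <- which(!is.na(pt) & seq_along(pt) < pt)
  for (a in opens) {
    b <- pt[a]
    expect_gt(b - a, 3)                               # loop >= 3
    expect_true(paste(sort(c(ch[a], ch[b])), collapse = "") %in%
                  c("CG", "AU", "GU"))                # legal pair
  }
  # nesting (no pseudoknots)
  if (length(opens) > 1) {
    for (a in opens) for (a2 in opens) {
      if (a < a2 && a2 < pt[a])
        expect_lt(pt[a2], pt[a])
    }
  }
  # dot-bracket consistent with pair table
  db <- strsplit(fr$structure, "")[[1]]
  expect_identical(which(db == "("), opens)
}

# naive exact scan of one read over contigs, both strands
oracle_scan <- function(read, contigs) {
  dna <- chartr("Uu", "Tt", toupper(read))
  rc <- function(x) paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]),
                          collapse = "")
  L <- nchar(dna)
  out <- NULL
  for (cid in names(contigs)) {
    cs <- chartr("Uu", "Tt", toupper(contigs[[cid]]))
    n <- nchar(cs)
    if (n < L) next
    starts <- seq_len(n - L + 1)
    wins <- substring(cs, starts, starts + L - 1)
    for (q in c("+", "-")) {
      pat <- if (q == "+") dna else rc(dna)
      at <- starts[wins == pat]
      if (length(at))
        out <- rbind(out, data.frame(contig = cid, start = at - 1L,
                                     strand = q, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) return(data.frame(contig = character(), start = integer(),
                                      strand = character()))
  out[order(out$contig, out$start, out$strand), ]
}

# brute-force UPGMA: explicit cluster sets, returns the cophenetic matrix
oracle_upgma_cophenetic <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  clusters <- lapply(seq_len(n), identity)
  coph <- matrix(0, n, n)
  active <- seq_len(n)
  dist_cl <- function(a, b) mean(D[clusters[[a]], clusters[[b]]])
  while (length(active) > 1) {
    bestv <- Inf; bi <- bj <- NA
    for (x in seq_along(active)) for (y in seq_along(active)) {
      if (x >= y) next
      v <- dist_cl(active[x], active[y])
      if (v < bestv) { bestv <- v; bi <- active[x]; bj <- active[y] }
    }
    for (p in clusters[[bi]]) for (q in clusters[[bj]]) {
      coph[p, q] <- coph[q, p] <- bestv
    }
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    active <- setdiff(active, bj)
  }
  coph
}

# independent target-site penalty (plain scalar loops)
oracle_site_penalty <- function(mirna, site) {
  rna <- function(x) chartr("Tt", "Uu", toupper(x))
  mc <- strsplit(rna(mirna), "")[[1]]
  sc <- strsplit(rna(site), "")[[1]]
  L <- length(mc); Ls <- length(sc)
  wt <- function(k) if (k >= 2 && k <= 13) 2 else 1
  cost <- function(a, b) {
    if ((a == "A" && b == "U") || (a == "U" && b == "A") ||
        (a == "G" && b == "C") || (a == "C" && b == "G")) return(0)
    if ((a == "G" && b == "U") || (a == "U" && b == "G")) return(0.5)
    1
  }
  if (Ls == L) {
    return(sum(vapply(1:L, function(k) cost(mc[k], sc[L - k + 1]) * wt(k),
                      numeric(1))))
  }
  if (Ls == L - 1) {
    best <- Inf
    for (g in 1:L) {
      p <- 2 * wt(g)
      for (k in seq_len(L)) {
        if (k == g) next
        sp <- if (k < g) Ls - k + 1 else Ls - k + 2
        p <- p + cost(mc[k], sc[sp]) * wt(k)
      }
      best <- min(best, p)
    }
    return(best)
  }
  if (Ls == L + 1) {
    best <- Inf
    for (p_ins in 1:Ls) {
      k_adj <- Ls - p_ins + 1
      p <- 2 * wt(min(k_adj, L))
      for (sp in seq_len(Ls)) {
        if (sp == p_ins) next
        k <- if (sp > p_ins) L - sp + 2 else L - sp + 1
        p <- p + cost(mc[k], sc[sp]) * wt(k)
      }
      best <- min(best, p)
    }
    return(best)
  }
  stop("oracle_site_penalty: bad lengths")
}

# min penalty over every window of a transcript (all 3 length classes)
oracle_all_windows <- function(mirna, tseq) {
  L <- nchar(mirna)
  n <- nchar(tseq)
  out <- NULL
  for (Ls in (L - 1):(L + 1)) {
    if (Ls > n) next
    for (s in seq_len(n - Ls + 1)) {
      out <- rbind(out, data.frame(
        start1 = s, len = Ls,
        penalty = oracle_site_penalty(mirna, substr(tseq, s, s + Ls - 1))))
    }
  }
  out
}

# a clean hairpin construct: mature + loop + (mutated) revcomp arm + 2 nt
make_construct <- function(mature, loop = "AUGCAUGC", arm_mut = 0,
                           tail = "GU") {
  arm <- revcomp(mature)
  if (arm_mut > 0) {
    ch <- strsplit(arm, "")[[1]]
    pos <- sample(length(ch), arm_mut)
    for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "U"), ch[p]), 1)
    arm <- paste(ch, collapse = "")
  }
  paste0(mature, loop, arm, tail)
}

random_rna <- function(len) {
  paste(sample(c("A", "C", "G", "U"), len, replace = TRUE), collapse = "")
}

random_dna_str <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
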