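#' Fold an RNA sequence into its maximum-pairing-score nested structure
#'
#' Dynamic program over nested (pseudoknot-free) structures with pair
#' scores GC = 3, AU = 2, GU = 1 and a minimum hairpin loop of 3
#' unpaired bases. The score is a stability surrogate ranking structures
#' the way a minimum-free-energy folder ranks them (higher = more
#' stable); an external thermodynamic folder can be plugged in through
#' `folder` as long as it honours the same output contract.
#'
#' The traceback is deterministic: at every subproblem the left-most
#' base is paired whenever pairing it achieves the optimum, with the
#' nearest (smallest) admissible partner.
#'
#' @param seq a single nucleotide sequence, at most 500 nt (T and U
#'   accepted).
#' @param folder optional plug-in: a `function(seq)` returning a list
#'   with elements `structure`, `score`, `pair_table`.
#' @return list of class `fold_result`: `structure` (dot-bracket
#'   string), `score` (total pairing score), `pair_table` (integer
#'   vector, `pair_table[i]` = partner of position i or `NA`).
#' @export
fold <- function(seq, folder = NULL) {
  stopifnot(length(seq) == 1)
  rna <- as_rna(seq)
  n <- nchar(rna)
  if (n < 1 || n > 500) stop("fold: sequence length must be 1-500 nt")
  if (grepl("[^ACGU]", rna)) stop("fold: invalid characters in sequence")
  if (!is.null(folder)) {
    res <- folder(rna)
    stopifnot(is.list(res), all(c("structure", "score", "pair_table") %in% names(res)))
    class(res) <- "fold_result"
    return(res)
  }

  code <- match(seq_chars(rna), c("A", "C", "G", "U"))
  S <- matrix(0, 4, 4)
  S[2, 3] <- S[3, 2] <- 3  # C:G
  S[1, 4] <- S[4, 1] <- 2  # A:U
  S[3, 4] <- S[4, 3] <- 1  # G:U
  P <- S[code, ][, code]   # n x n pair-score matrix

  minloop <- 3
  M <- matrix(0, n + 1, n + 1)  # M[a, b] = best score on [a, b]; a > b empty
  if (n > minloop + 1) for (d in (minloop + 1):(n - 1)) {
    for (i in seq_len(n - d)) {
      j <- i + d
      best <- M[i + 1, j]
      ks <- (i + minloop + 1):j
      ps <- P[i, ks]
      ok <- ps > 0
      if (any(ok)) {
        kk <- ks[ok]
        cand <- ps[ok] + M[i + 1, pmax(kk - 1, i)] * (kk - 1 >= i + 1) + M[cbind(kk + 1, j)]
        best <- max(best, max(cand))
      }
      M[i, j] <- best
    }
  }

  # deterministic traceback: pair left-most base first, nearest partner
  pt <- rep(NA_integer_, n)
  stack <- list(c(1L, n))
  while (length(stack)) {
    iv <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    i <- iv[1]; j <- iv[2]
    while (i < j && j - i > minloop) {
      target <- M[i, j]
      if (target == 0) break
      ks <- (i + minloop + 1):j
      paired <- FALSE
      for (k in ks) {
        if (P[i, k] > 0) {
          left <- if (k - 1 >= i + 1) M[i + 1, k - 1] else 0
          right <- if (k + 1 <= j) M[k + 1, j] else 0
          if (P[i, k] + left + right == target) {
            pt[i] <- k; pt[k] <- i
            if (k + 1 <= j) stack[[length(stack) + 1]] <- c(k + 1L, as.integer(j))
            j <- k - 1L; i <- i + 1L
            paired <- TRUE
            break
          }
        }
      }
      if (!paired) i <- i + 1L
    }
  }

  db <- rep(".", n)
  db[!is.na(pt) & seq_len(n) < pt] <- "("
  db[!is.na(pt) & seq_len(n) > pt] <- ")"
  structure(list(structure = paste(db, collapse = ""),
                 score = M[1, n],
                 pair_table = pt),
            class = "fold_result")
}

# score a given dot-bracket structure under the same pairing scores
# (used for internal consistency checks)
structure_score <- function(seq, pt) {
  rna <- as_rna(seq)
  ch <- seq_chars(rna)
  i <- which(!is.na(pt) & seq_len(length(pt)) < pt)
  if (!length(i)) return(0)
  sum(vapply(i, function(a) {
    p <- sort(c(ch[a], ch[pt[a]]))
    key <- paste(p, collapse = "")
    switch(key, "CG" = 3, "AU" = 2, "GU" = 1, 0)
  }, numeric(1)))
}
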