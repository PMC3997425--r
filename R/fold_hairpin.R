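#' Fold a precursor as a single stem-loop
#'
#' Restricted folding for hairpin screening: the structure is a single
#' stem-loop (one terminal loop, no branching) built from the same pair
#' scores as [fold()] (GC = 3, AU = 2, GU = 1, terminal loop >= 3).
#' Interior loops and bulges are allowed up to `max_bulge` unpaired
#' bases per side per step and each unpaired stem-internal base costs
#' `skip_penalty`; bases outside the outermost pair dangle free.
#'
#' A general maximum-score nested fold has no notion of helix stacking,
#' so on windows of a few hundred bases it happily shreds a genuine
#' pre-miRNA stem into scattered short helices; constraining the
#' structure to one gap-penalised stem-loop is what makes miRNA hairpin
#' screening behave like thermodynamic folding while staying a small
#' deterministic DP.
#'
#' @param seq nucleotide sequence, 16-500 nt.
#' @param skip_penalty cost per unpaired base enclosed by the stem. The
#'   default 3 (the strongest pair score) keeps a diffuse, bulge-ridden
#'   pairing from outscoring a genuine contiguous helix.
#' @param max_bulge maximum unpaired bases per side between consecutive
#'   pairs.
#' @return a `fold_result` (see [fold()]): `structure`, `score`,
#'   `pair_table`.
#' @export
fold_hairpin <- function(seq, skip_penalty = 3, max_bulge = 6) {
  rna <- as_rna(seq)
  n <- nchar(rna)
  if (n < 16 || n > 500) stop("fold_hairpin: sequence length must be 16-500 nt")
  if (grepl("[^ACGU]", rna)) stop("fold_hairpin: invalid characters in sequence")
  code <- match(seq_chars(rna), c("A", "C", "G", "U"))
  S <- matrix(0, 4, 4)
  S[2, 3] <- S[3, 2] <- 3
  S[1, 4] <- S[4, 1] <- 2
  S[3, 4] <- S[4, 3] <- 1
  P <- S[code, ][, code]
  minloop <- 3

  # D[[d]][i] = best stem-loop score with outermost pair (i, i + d)
  D <- vector("list", n - 1)
  empty <- function(d) rep(-Inf, max(0L, n - d))
  for (d in seq(minloop + 1, n - 1)) {
    i <- seq_len(n - d)
    ps <- P[cbind(i, i + d)]
    inner_best <- rep(0, length(i))  # terminal loop closes the stem
    for (b1 in 0:max_bulge) {
      for (b2 in 0:max_bulge) {
        d2 <- d - 2L - b1 - b2
        if (d2 < minloop + 1) next
        prev <- D[[d2]]
        cand <- prev[i + 1L + b1] - skip_penalty * (b1 + b2)
        inner_best <- pmax(inner_best, cand, na.rm = TRUE)
      }
    }
    v <- ifelse(ps > 0, ps + inner_best, -Inf)
    D[[d]] <- v
  }

  # highest score wins; ties go to the smallest span, then 5'-most start
  best <- 0; bi <- NA; bd <- NA
  for (d in seq(minloop + 1, n - 1)) {
    v <- D[[d]]
    if (!length(v)) next
    m <- max(v)
    if (m > best) {
      best <- m; bd <- d; bi <- which.max(v)
    }
  }

  pt <- rep(NA_integer_, n)
  if (!is.na(bi)) {
    i <- bi; d <- bd
    repeat {
      pt[i] <- i + d; pt[i + d] <- i
      target <- D[[d]][i] - P[i, i + d]
      if (target <= 0) break
      found <- FALSE
      for (b1 in 0:max_bulge) {
        for (b2 in 0:max_bulge) {
          d2 <- d - 2L - b1 - b2
          if (d2 < minloop + 1) next
          val <- D[[d2]][i + 1L + b1]
          if (is.finite(val) && val - skip_penalty * (b1 + b2) == target) {
            i <- i + 1L + b1; d <- d2
            found <- TRUE
            break
          }
        }
        if (found) break
      }
      if (!found) break
    }
  }
  db <- rep(".", n)
  db[!is.na(pt) & seq_len(n) < pt] <- "("
  db[!is.na(pt) & seq_len(n) > pt] <- ")"
  structure(list(structure = paste(db, collapse = ""),
                 score = best, pair_table = pt),
            class = "fold_result")
}
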