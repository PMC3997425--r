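#' Extract the candidate precursor window around a genome hit
#'
#' Takes the mapped mature locus plus `flank` nucleotides on each side
#' (clipped at contig bounds). Minus-strand hits are reverse-complemented
#' so the mature always reads 5'->3' within the returned precursor.
#'
#' @param hit one row of a [map_exact()] hit table (`contig`, `start`,
#'   `end` 0-based half-open, `strand`, `seq`).
#' @param contig_seq the full sequence of `hit$contig`.
#' @param flank flank width in nt (default 100).
#' @param flank_3p optional distinct flank on the mature's 3' side
#'   (defaults to `flank`; both flanks are in mature orientation, so on
#'   a minus-strand hit the 3' flank extends toward lower coordinates).
#' @return list of class `precursor`: `contig`, `start`, `end` (0-based
#'   half-open window on the forward strand), `strand`, `seq` (RNA,
#'   mature-oriented), `mature_offset` (0-based offset of the mature
#'   within `seq`), `mature` (RNA).
#' @export
extract_precursor <- function(hit, contig_seq, flank = 100, flank_3p = flank) {
  n <- nchar(contig_seq)
  if (hit$strand == "+") {
    w_start <- max(0L, hit$start - flank)
    w_end <- min(n, hit$end + flank_3p)
  } else {
    w_start <- max(0L, hit$start - flank_3p)
    w_end <- min(n, hit$end + flank)
  }
  window <- substr(as_dna(contig_seq), w_start + 1, w_end)
  if (hit$strand == "+") {
    offset <- hit$start - w_start
  } else {
    window <- revcomp(window)
    offset <- w_end - hit$end
  }
  mature <- substr(window, offset + 1, offset + (hit$end - hit$start))
  structure(list(contig = hit$contig, start = w_start, end = w_end,
                 strand = hit$strand, seq = as_rna(window),
                 mature_offset = offset, mature = as_rna(mature)),
            class = "precursor")
}

#' Predict the star sequence of a mature miRNA from the fold
#'
#' The star span is read off the pair table in the canonical Dicer
#' register: the positions pairing with the mature, shifted so both
#' duplex 3' ends carry 2-nt overhangs (star runs from the partner of
#' mature position L-2 to the partner of mature position 1, plus 2 nt).
#' In an antiparallel helix every pair (t, partner) shares the same
#' antidiagonal `t + partner`; the register is taken as the most common
#' antidiagonal over the mature's paired positions, which makes the
#' boundary partners robust to unpaired ends and chance one-base helix
#' extensions.
#'
#' @param fold_result a [fold()] result for the precursor.
#' @param mature_span integer vector `c(start, end)`, 1-based inclusive
#'   positions of the mature within the folded sequence.
#' @param precursor_seq the folded sequence (needed to extract the star).
#' @return list with `star` (RNA sequence), `start`, `end` (1-based span
#'   within the precursor), or `NULL` when the mature's paired region is
#'   shorter than mature length - 4 or the register leaves the sequence.
#' @export
predict_star <- function(fold_result, mature_span, precursor_seq) {
  pt <- fold_result$pair_table
  i <- mature_span[1]; j <- mature_span[2]
  L <- j - i + 1
  partners <- pt[i:j]
  if (sum(!is.na(partners)) < L - 4) return(NULL)
  anti <- table((i:j + partners)[!is.na(partners)])
  reg <- as.integer(names(anti)[which.max(anti)])
  a <- reg - (j - 2L)                         # partner of mature pos j-2
  b <- reg - i                                # partner of mature pos i
  s_start <- min(a, b)
  s_end <- max(a, b) + 2L
  if (s_start < 1 || s_end > length(pt)) return(NULL)
  list(star = substr(as_rna(precursor_seq), s_start, s_end),
       start = s_start, end = s_end)
}

#' Count duplex mismatches between a mature miRNA and its star
#'
#' Aligns the mature 5'->3' against the star antiparallel. A position
#' counts as a mismatch unless it forms a Watson-Crick or G:U pair; when
#' lengths differ, each unpaired base beyond the 3' overhangs counts 1.
#' Duplex annotation tools print stars in two registers -- the canonical
#' Dicer register with 2-nt 3' overhangs (mature position m pairs star
#' position L-1-m) and the blunt full-overlap register (m pairs L+1-m)
#' -- so the count is the minimum over both, anchored at either end,
#' which also makes it symmetric in its arguments.
#'
#' @param mature,star RNA sequences, 19-24 nt.
#' @return integer mismatch count.
#' @export
duplex_mismatches <- function(mature, star) {
  m <- as_rna(mature); s <- as_rna(star)
  Lm <- nchar(m); Ls <- nchar(s)
  if (Lm < 19 || Lm > 24 || Ls < 19 || Ls > 24)
    stop("duplex_mismatches: sequences must be 19-24 nt")
  mc <- seq_chars(m); sc <- seq_chars(s)
  count_register <- function(r) {
    # mature position k pairs star position r - k
    ks <- seq_len(Lm)
    partners <- r - ks
    inplay <- partners >= 1 & partners <= Ls
    mm <- sum(!pairs_with(mc[ks[inplay]], sc[partners[inplay]]))
    mm + abs(Ls - Lm)
  }
  registers <- unique(c(Lm - 1L, Ls - 1L, Lm + 1L, Ls + 1L))
  min(vapply(registers, count_register, numeric(1)))
}

#' Screen a folded precursor against plant miRNA annotation criteria
#'
#' Applies the community (Meyers) screening rules: mature and star must
#' sit on opposite arms of a stem-loop (the mature may not pair with
#' itself across a terminal loop), the mature may be unpaired over at
#' most 4 bases, the duplex register must carry 2-nt 3' overhangs (by
#' construction of [predict_star()], which returns `NULL` when the
#' register cannot be realised), and the mature:star duplex may contain
#' at most `max_mismatch` mismatches. The reported precursor is trimmed
#' to the maximal stem-loop enclosing the duplex.
#'
#' @param precursor an [extract_precursor()] object.
#' @param fold_result a [fold()] result for `precursor$seq` (computed
#'   when omitted).
#' @param max_mismatch duplex mismatch cap (default 4).
#' @param max_unpaired maximum unpaired mature bases (default 4).
#' @return list of class `hairpin_candidate`: the precursor, fold,
#'   duplex report (`star`, `star_span`, `mismatches`, `overhang`,
#'   `arms_ok`), trimmed precursor bounds and sequence, `gc` (%),
#'   `accepted` flag and `reason` for rejections.
#' @export
evaluate_hairpin <- function(precursor, fold_result = NULL,
                             max_mismatch = 4, max_unpaired = 4) {
  if (is.null(fold_result)) fold_result <- fold(precursor$seq)
  n <- nchar(precursor$seq)
  if (length(fold_result$pair_table) != n)
    stop("evaluate_hairpin: fold and precursor lengths differ")
  i <- precursor$mature_offset + 1L
  j <- precursor$mature_offset + nchar(precursor$mature)
  pt <- fold_result$pair_table

  reject <- function(reason) {
    structure(list(precursor = precursor, fold = fold_result,
                   duplex = NULL, trimmed = NULL, gc = NA_real_,
                   accepted = FALSE, reason = reason),
              class = "hairpin_candidate")
  }

  unpaired <- sum(is.na(pt[i:j]))
  if (unpaired > max_unpaired) return(reject("mature mostly unpaired"))
  partners <- pt[i:j][!is.na(pt[i:j])]
  if (any(partners >= i & partners <= j))
    return(reject("mature pairs with itself (spans the terminal loop)"))
  if (!(all(partners > j) || all(partners < i)))
    return(reject("mature partners on both sides (spans the terminal loop)"))

  star <- predict_star(fold_result, c(i, j), precursor$seq)
  if (is.null(star)) return(reject("no star register"))
  if (star$start <= j && star$end >= i)
    return(reject("star overlaps mature"))
  if (nchar(precursor$mature) < 19 || nchar(precursor$mature) > 24 ||
      nchar(star$star) < 19 || nchar(star$star) > 24)
    return(reject("mature or star outside the 19-24 nt duplex range"))
  mm <- duplex_mismatches(precursor$mature, star$star)
  accepted <- mm <= max_mismatch

  # trim to the maximal stem-loop enclosing the duplex
  lo <- min(i, star$start); hi <- max(j, star$end)
  repeat {
    enclosing <- which(!is.na(pt) & seq_len(n) < lo & pt >= hi)
    if (!length(enclosing)) break
    a <- min(enclosing)
    lo <- a; hi <- pt[a]
  }
  trimmed_seq <- substr(precursor$seq, lo, hi)

  structure(list(
    precursor = precursor, fold = fold_result,
    duplex = list(star = star$star, star_span = c(star$start, star$end),
                  mismatches = mm, overhang = c(2L, 2L), arms_ok = TRUE),
    trimmed = list(start = lo, end = hi, seq = trimmed_seq),
    gc = gc_content(trimmed_seq),
    accepted = accepted,
    reason = if (accepted) NA_character_ else "duplex mismatches exceed cap"
  ), class = "hairpin_candidate")
}

#' Summary statistics over accepted hairpin candidates
#'
#' @param candidates list of `hairpin_candidate` objects.
#' @return list with `n`, `length_range` (trimmed precursor lengths) and
#'   `gc_range` (%).
#' @export
precursor_stats <- function(candidates) {
  acc <- Filter(function(x) isTRUE(x$accepted), candidates)
  if (!length(acc)) stop("precursor_stats: no accepted candidates")
  lens <- vapply(acc, function(x) nchar(x$trimmed$seq), numeric(1))
  gcs <- vapply(acc, function(x) x$gc, numeric(1))
  list(n = length(acc),
       length_range = range(lens),
       gc_range = range(gcs))
}
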