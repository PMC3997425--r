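# position weights: penalties double over miRNA positions 2-13
target_weight <- function(k) ifelse(k >= 2 & k <= 13, 2, 1)

# per-position base cost between a miRNA base and the target base it
# faces: Watson-Crick 0, G:U wobble 0.5, anything else 1
target_cost <- local({
  bases <- c("A", "C", "G", "U")
  M <- matrix(1, 4, 4, dimnames = list(bases, bases))
  M["A", "U"] <- M["U", "A"] <- M["G", "C"] <- M["C", "G"] <- 0
  M["G", "U"] <- M["U", "G"] <- 0.5
  M
})

#' Score a miRNA against one candidate target site
#'
#' Complementarity ("expectation") penalty in the style of plant target
#' finders: per miRNA position (1 = 5' end) a mismatch costs 1, a G:U
#' wobble 0.5 and a gap 2, every cost doubled over positions 2-13; a
#' perfect Watson-Crick pair costs 0. The site is the transcript window
#' read 5'->3'; the miRNA pairs antiparallel (miRNA position 1 faces the
#' site's last base). At most one gap is allowed, so the site may be one
#' base shorter (a miRNA base bulges out) or longer (a site base bulges)
#' than the miRNA.
#'
#' @param mirna miRNA sequence (RNA, 5'->3').
#' @param site transcript window (RNA, 5'->3'), length within miRNA
#'   length +- 1.
#' @return list: `penalty` and `alignment` (data.frame with `mir_pos`,
#'   `site_pos` (1-based within the site, `NA` for a bulged miRNA base),
#'   `mir_base`, `site_base`, `kind` in match/wobble/mismatch/gap_site/
#'   gap_mir).
#' @export
score_site <- function(mirna, site) {
  m <- as_rna(mirna); s <- as_rna(site)
  L <- nchar(m); Ls <- nchar(s)
  if (abs(Ls - L) > 1)
    stop("score_site: site length must be within 1 of the miRNA length")
  mc <- seq_chars(m); sc <- seq_chars(s)
  kind_of <- function(a, b) {
    cost <- target_cost[a, b]
    if (cost == 0) "match" else if (cost == 0.5) "wobble" else "mismatch"
  }
  ungapped_rows <- function(site_pos_of_k) {
    data.frame(mir_pos = seq_len(L), site_pos = site_pos_of_k,
               mir_base = mc, site_base = sc[site_pos_of_k],
               kind = mapply(kind_of, mc, sc[site_pos_of_k]),
               stringsAsFactors = FALSE, row.names = NULL)
  }
  pen_of <- function(al) {
    sum(vapply(seq_len(nrow(al)), function(r) {
      w <- target_weight(al$mir_pos[r])
      switch(al$kind[r], match = 0, wobble = 0.5 * w, mismatch = 1 * w,
             gap_site = 2 * w, gap_mir = 2 * w)
    }, numeric(1)))
  }

  if (Ls == L) {
    al <- ungapped_rows(L - seq_len(L) + 1L)
    return(list(penalty = pen_of(al), alignment = al))
  }

  best <- NULL
  if (Ls == L - 1) {
    # one miRNA base bulged out (gap on the site side)
    for (g in seq_len(L)) {
      k <- seq_len(L)
      sp <- ifelse(k < g, Ls - k + 1L, Ls - k + 2L)
      sp[g] <- NA
      al <- data.frame(mir_pos = k, site_pos = sp, mir_base = mc,
                       site_base = ifelse(is.na(sp), "-", sc[sp]),
                       kind = ifelse(is.na(sp), "gap_site",
                                     mapply(kind_of, mc, sc[ifelse(is.na(sp), 1L, sp)])),
                       stringsAsFactors = FALSE)
      p <- pen_of(al)
      if (is.null(best) || p < best$penalty) best <- list(penalty = p, alignment = al)
    }
  } else {
    # one extra site base (gap on the miRNA side); the gap inherits the
    # weight of the miRNA position 3' of the insertion (k_adj)
    for (p_ins in seq_len(Ls)) {
      k_of_s <- integer(Ls)
      for (sp in seq_len(Ls)) {
        if (sp == p_ins) { k_of_s[sp] <- NA; next }
        k_of_s[sp] <- if (sp > p_ins) L - sp + 2L else L - sp + 1L
      }
      k_adj <- sum(seq_len(Ls) > p_ins) + 1L  # mir position after the gap
      if (k_adj > L) k_adj <- L
      rows <- data.frame(mir_pos = k_of_s[!is.na(k_of_s)],
                         site_pos = which(!is.na(k_of_s)),
                         stringsAsFactors = FALSE)
      rows$mir_base <- mc[rows$mir_pos]
      rows$site_base <- sc[rows$site_pos]
      rows$kind <- mapply(kind_of, rows$mir_base, rows$site_base)
      gap_row <- data.frame(mir_pos = k_adj, site_pos = p_ins,
                            mir_base = "-", site_base = sc[p_ins],
                            kind = "gap_mir", stringsAsFactors = FALSE)
      al <- rbind(rows, gap_row)
      al <- al[order(al$site_pos, decreasing = TRUE), ]
      rownames(al) <- NULL
      p <- pen_of(al)
      if (is.null(best) || p < best$penalty) best <- list(penalty = p, alignment = al)
    }
  }
  best
}

#' Predicted silencing mode from a target alignment
#'
#' Cleavage requires an intact duplex centre: a mismatch or gap at any
#' of miRNA positions 9-11 blocks slicing and the call is translational
#' repression.
#'
#' @param alignment alignment data.frame from [score_site()].
#' @return "C" (mRNA cleavage) or "T" (translational repression).
#' @export
call_mode <- function(alignment) {
  central <- alignment$mir_pos %in% 9:11
  bad <- alignment$kind %in% c("mismatch", "gap_site", "gap_mir")
  if (any(central & bad)) "T" else "C"
}

#' Expected cleavage coordinate on the transcript
#'
#' The slicer cuts the mRNA opposite miRNA positions 10/11; the function
#' walks the alignment and returns the two 1-based transcript positions
#' paired to miRNA positions 11 and 10, between which cleavage falls.
#'
#' @param alignment alignment data.frame from [score_site()].
#' @param site_span integer `c(start, end)`, 1-based inclusive transcript
#'   coordinates of the site.
#' @return integer vector of the two transcript positions (increasing).
#' @export
expected_cleavage <- function(alignment, site_span) {
  if (call_mode(alignment) == "T")
    stop("expected_cleavage: mode is translational repression")
  p10 <- alignment$site_pos[alignment$mir_pos == 10 & alignment$kind != "gap_mir"]
  p11 <- alignment$site_pos[alignment$mir_pos == 11 & alignment$kind != "gap_mir"]
  if (!length(p10) || !length(p11) || anyNA(c(p10, p11)))
    stop("expected_cleavage: central positions unpaired")
  sort(site_span[1] - 1L + c(p11[1], p10[1]))
}

# vectorized penalties of all windows of one length class on a transcript
# tc: transcript as RNA char vector; offset: site local position of miRNA
# base k is Ls - k + delta, split around a gap for the gapped classes.
scan_windows <- function(mc, tc, type = c("ungapped", "gap_site", "gap_mir")) {
  type <- match.arg(type)
  L <- length(mc)
  Ls <- switch(type, ungapped = L, gap_site = L - 1L, gap_mir = L + 1L)
  Tn <- length(tc)
  W <- Tn - Ls + 1L
  if (W < 1) return(numeric(0))
  ws <- seq_len(W)
  wt <- target_weight(seq_len(L))
  costs_at <- function(local_off) {
    # matrix L x W of weighted costs; mir base k faces transcript
    # position (w - 1) + local_off[k]; out-of-range rows are masked by
    # the caller, so indices are clamped to stay in bounds
    idx <- outer(local_off, ws - 1L, "+")
    idx <- pmin(pmax(idx, 1L), Tn)
    cm <- matrix(target_cost[cbind(rep(mc, W), tc[idx])], nrow = L)
    cm * wt
  }
  if (type == "ungapped") {
    return(colSums(costs_at(Ls - seq_len(L) + 1L)))
  }
  if (type == "gap_site") {
    # miRNA base g bulges out: k < g faces site Ls-k+1, k > g faces Ls-k+2
    A <- costs_at(Ls - seq_len(L) + 1L)
    A[L, ] <- 0   # k = L is never in the k < g branch
    B <- costs_at(Ls - seq_len(L) + 2L)
    B[1, ] <- 0   # k = 1 is never in the k > g branch
    prefA <- apply(A, 2, cumsum)
    sufB <- apply(B[L:1, , drop = FALSE], 2, cumsum)[L:1, , drop = FALSE]
    best <- rep(Inf, W)
    for (g in seq_len(L)) {
      pen <- 2 * target_weight(g) +
        (if (g > 1) prefA[g - 1, ] else 0) +
        (if (g < L) sufB[g + 1, ] else 0)
      best <- pmin(best, pen)
    }
    return(best)
  }
  # gap_mir: one extra site base. With the insertion 5' of miRNA
  # position k_adj, mir k < k_adj faces site Ls-k+1 and mir k >= k_adj
  # faces site Ls-k (k_adj = L+1 puts the extra base at the site 5' end)
  A <- costs_at(Ls - seq_len(L) + 1L)
  B <- costs_at(Ls - seq_len(L))
  prefA <- apply(A, 2, cumsum)
  sufB <- apply(B[L:1, , drop = FALSE], 2, cumsum)[L:1, , drop = FALSE]
  best <- rep(Inf, W)
  for (k_adj in seq_len(L + 1L)) {
    pen <- 2 * target_weight(min(k_adj, L)) +
      (if (k_adj > 1) prefA[k_adj - 1, ] else 0) +
      (if (k_adj <= L) sufB[k_adj, ] else 0)
    best <- pmin(best, pen)
  }
  best
}

#' Scan a transcriptome for targets of one miRNA
#'
#' All windows (miRNA length +- 1 for the single allowed gap) with
#' expectation penalty at or below `cutoff` are evaluated; overlapping
#' windows are collapsed to the best-scoring one. Hits are ordered by
#' (penalty, transcript id, position), so each transcript's best site
#' comes first.
#'
#' @param mirna miRNA sequence (RNA, 5'->3').
#' @param transcriptome named character vector or data.frame
#'   (`id`, `seq`) of transcript sequences.
#' @param cutoff maximum expectation penalty (default 3.0).
#' @param mirna_name label used in the output (defaults to the sequence).
#' @return data.frame of target hits: `mirna`, `transcript`, `start`,
#'   `end` (0-based half-open), `penalty`, `mode` ("C"/"T"),
#'   `cleave_5p`, `cleave_3p` (1-based positions flanking the expected
#'   cut, `NA` for mode "T"), `align_mirna`, `align_pairs`, `align_site`.
#' @export
scan_transcripts <- function(mirna, transcriptome, cutoff = 3.0,
                             mirna_name = NULL) {
  if (is.data.frame(transcriptome))
    transcriptome <- stats::setNames(transcriptome$seq, transcriptome$id)
  if (!length(transcriptome)) stop("scan_transcripts: empty transcriptome")
  if (is.null(mirna_name)) mirna_name <- as_rna(mirna)
  m <- as_rna(mirna)
  mc <- seq_chars(m)
  L <- length(mc)

  hits <- list()
  for (tid in names(transcriptome)) {
    tseq <- as_rna(transcriptome[[tid]])
    tc <- seq_chars(tseq)
    if (any(!tc %in% rownames(target_cost))) {
      tc[!tc %in% rownames(target_cost)] <- "A"  # N bases can never pair
    }
    cand <- list()
    for (type in c("ungapped", "gap_site", "gap_mir")) {
      Ls <- switch(type, ungapped = L, gap_site = L - 1L, gap_mir = L + 1L)
      pen <- scan_windows(mc, tc, type)
      ok <- which(pen <= cutoff)
      if (length(ok))
        cand[[type]] <- data.frame(start1 = ok, len = Ls, penalty = pen[ok])
    }
    if (!length(cand)) next
    cand <- do.call(rbind, cand)
    cand <- cand[order(cand$penalty, cand$start1, cand$len), ]
    kept <- cand[0, ]
    for (r in seq_len(nrow(cand))) {
      s <- cand$start1[r]; e <- s + cand$len[r] - 1L
      if (!nrow(kept) || all(s > kept$start1 + kept$len - 1L | e < kept$start1))
        kept <- rbind(kept, cand[r, ])
    }
    for (r in seq_len(nrow(kept))) {
      s1 <- kept$start1[r]; Ls <- kept$len[r]
      site <- substr(tseq, s1, s1 + Ls - 1L)
      det <- score_site(m, site)
      mode <- call_mode(det$alignment)
      cleave <- if (mode == "C")
        tryCatch(expected_cleavage(det$alignment, c(s1, s1 + Ls - 1L)),
                 error = function(e) c(NA_integer_, NA_integer_))
        else c(NA_integer_, NA_integer_)
      strs <- alignment_strings(det$alignment)
      hits[[length(hits) + 1]] <- data.frame(
        mirna = mirna_name, transcript = tid,
        start = s1 - 1L, end = s1 - 1L + Ls,
        penalty = det$penalty, mode = mode,
        cleave_5p = cleave[1], cleave_3p = cleave[2],
        align_mirna = strs[1], align_pairs = strs[2], align_site = strs[3],
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits))
    return(data.frame(mirna = character(), transcript = character(),
                      start = integer(), end = integer(), penalty = numeric(),
                      mode = character(), cleave_5p = integer(),
                      cleave_3p = integer(), align_mirna = character(),
                      align_pairs = character(), align_site = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, hits)
  out <- out[order(out$penalty, out$transcript, out$start), ]
  rownames(out) <- NULL
  out
}

# render the alignment as a 3-line triple: miRNA 3'->5' on top, pairing
# row (| = Watson-Crick, o = wobble, space otherwise), site 5'->3' below
alignment_strings <- function(al) {
  Ls <- suppressWarnings(max(al$site_pos, na.rm = TRUE))
  # a bulged miRNA base sits between site positions Ls-g+1 and Ls-g+2
  key <- ifelse(is.na(al$site_pos), Ls - al$mir_pos + 1.5, al$site_pos)
  al2 <- al[order(key), ]
  pair_row <- paste(vapply(al2$kind, function(k)
    switch(k, match = "|", wobble = "o", " "), character(1)), collapse = "")
  c(paste(al2$mir_base, collapse = ""), pair_row,
    paste(al2$site_base, collapse = ""))
}
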