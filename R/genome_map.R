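#' Build an exact-match index over reference contigs
#'
#' Hash-of-k-mers index with verification: every forward-strand k-mer
#' start position is recorded, queries are anchored at their first k
#' bases and verified by direct substring comparison. Minus-strand hits
#' are found by querying the reverse complement, so only the forward
#' strand is indexed.
#'
#' @param contigs named character vector or data.frame (`id`, `seq`) of
#'   reference contigs (DNA or RNA; stored as DNA).
#' @param k seed length (default 16, the minimum retained read length).
#' @return an opaque index handle for [map_exact()] / [map_reads()].
#' @export
build_index <- function(contigs, k = 16) {
  if (is.data.frame(contigs)) contigs <- stats::setNames(contigs$seq, contigs$id)
  if (length(contigs) == 0) stop("build_index: empty contig set")
  ids <- names(contigs)
  if (is.null(ids) || any(ids == "")) stop("build_index: contigs must be named")
  if (anyDuplicated(ids)) stop("build_index: duplicate contig ids")
  seqs <- as_dna(contigs)
  ht <- new.env(parent = emptyenv(), size = sum(nchar(seqs)))
  for (ci in seq_along(seqs)) {
    n <- nchar(seqs[ci])
    if (n < k) next
    starts <- seq_len(n - k + 1)
    kmers <- substring(seqs[ci], starts, starts + k - 1)
    sp <- split(starts, kmers)
    for (w in names(sp)) {
      prev <- ht[[w]]
      entry <- rbind(cbind(ci, sp[[w]]))
      ht[[w]] <- if (is.null(prev)) entry else rbind(prev, entry)
    }
  }
  structure(list(ht = ht, seqs = unname(seqs), ids = ids, k = k),
            class = "hexamir_index")
}

# candidate (contig, start1) anchor positions for one DNA query
index_candidates <- function(query, index) {
  if (nchar(query) < index$k) return(NULL)
  index$ht[[substr(query, 1, index$k)]]
}

# verified 1-based forward-strand occurrences of a DNA query
index_occurrences <- function(query, index) {
  cand <- index_candidates(query, index)
  if (is.null(cand)) return(NULL)
  L <- nchar(query)
  ok <- substring(index$seqs[cand[, 1]], cand[, 2], cand[, 2] + L - 1) == query
  cand[ok, , drop = FALSE]
}

#' Map one read exactly onto the reference, both strands
#'
#' @param read a single read sequence (RNA or DNA).
#' @param index an index from [build_index()].
#' @return data.frame of hits: `contig`, `start`, `end` (0-based
#'   half-open on the forward strand), `strand`, `seq` (the read as
#'   given); zero rows when the read is absent. Sorted by
#'   (contig, start, strand).
#' @export
map_exact <- function(read, index) {
  stopifnot(inherits(index, "hexamir_index"), length(read) == 1)
  q <- as_dna(read)
  L <- nchar(q)
  rows <- list()
  fw <- index_occurrences(q, index)
  if (!is.null(fw) && nrow(fw))
    rows$fw <- data.frame(contig = index$ids[fw[, 1]], start = fw[, 2] - 1L,
                          strand = "+", stringsAsFactors = FALSE)
  rv <- index_occurrences(revcomp(q), index)
  if (!is.null(rv) && nrow(rv))
    rows$rv <- data.frame(contig = index$ids[rv[, 1]], start = rv[, 2] - 1L,
                          strand = "-", stringsAsFactors = FALSE)
  hits <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig = character(), start = integer(), strand = character(),
               stringsAsFactors = FALSE)
  hits$end <- hits$start + L
  hits$seq <- rep(read, nrow(hits))
  hits <- hits[order(hits$contig, hits$start, hits$strand),
               c("contig", "start", "end", "strand", "seq")]
  rownames(hits) <- NULL
  hits
}

#' Map a batch of reads, keeping all hits per read
#'
#' @param reads character vector of read sequences.
#' @param index an index from [build_index()].
#' @return data.frame of hits for all reads (columns as [map_exact()]).
#' @export
map_reads <- function(reads, index) {
  out <- lapply(reads, map_exact, index = index)
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# fast any-hit test used by the contaminant filter
has_hit <- function(reads, index) {
  q <- as_dna(reads)
  rc <- revcomp(q)
  vapply(seq_along(q), function(i) {
    occ <- index_occurrences(q[i], index)
    if (!is.null(occ) && nrow(occ)) return(TRUE)
    occ <- index_occurrences(rc[i], index)
    !is.null(occ) && nrow(occ) > 0
  }, logical(1))
}
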