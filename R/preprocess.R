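#' Trim the 3' sequencing adapter from reads
#'
#' Finds the left-most exact match of the first `seed_len` bases of the
#' adapter and returns the insert preceding it. Adapter trimming here is
#' deliberately exact-seed and deterministic: no mismatch-tolerant
#' alignment is attempted.
#'
#' @param seqs character vector of raw read sequences.
#' @param adapter_3p the 3' adapter sequence (non-empty).
#' @param seed_len number of adapter 5' bases used as the exact seed.
#' @param require_adapter if `TRUE`, reads without an adapter match are
#'   rejected (returned as `NA`); if `FALSE` they pass through untrimmed.
#' @return character vector of trimmed inserts; `NA` marks rejected reads.
#'   An insert may be empty (read was pure adapter); the length filter
#'   removes such reads downstream.
#' @export
trim_adapter <- function(seqs, adapter_3p, seed_len = 8, require_adapter = TRUE) {
  if (!nzchar(adapter_3p)) stop("trim_adapter: adapter must be non-empty")
  seed <- toupper(substr(adapter_3p, 1, min(seed_len, nchar(adapter_3p))))
  seqs <- toupper(seqs)
  pos <- regexpr(seed, seqs, fixed = TRUE)
  out <- ifelse(pos > 0, substr(seqs, 1, pos - 1),
                if (require_adapter) NA_character_ else seqs)
  out
}

#' Length filter for small RNA reads
#'
#' @param reads character vector of read sequences.
#' @param min,max inclusive length bounds (defaults 16 and 30 nt).
#' @return list with `kept` (character vector) and `removed_count`.
#' @export
filter_length <- function(reads, min = 16, max = 30) {
  if (min > max) stop("filter_length: min must not exceed max")
  n <- nchar(reads)
  keep <- n >= min & n <= max
  list(kept = reads[keep], removed_count = sum(!keep))
}

#' Invalid-sequence test
#'
#' A read is invalid if, after RNA normalisation, it contains any
#' character outside A/C/G/U (N included) or is empty.
#'
#' @param seqs character vector.
#' @return logical vector.
#' @export
is_invalid <- function(seqs) {
  r <- as_rna(seqs)
  nchar(r) == 0 | grepl("[^ACGU]", r)
}

#' Low-complexity (SSR / tandem repeat) test
#'
#' A read is low-complexity if, for some k in 1..3, tandem runs (two or
#' more back-to-back copies) of a single k-mer cover at least
#' `threshold` of the read length. This captures simple sequence repeats
#' and tandem repeats while remaining brute-force verifiable.
#'
#' @param seqs character vector.
#' @param threshold minimum covered fraction (default 0.8).
#' @return logical vector.
#' @export
is_low_complexity <- function(seqs, threshold = 0.8) {
  out <- logical(length(seqs))
  if (!length(seqs)) return(out)
  # vectorized necessary-condition screen: a k-mer tandem covering
  # c >= threshold*n bases forces >= c/2 self-matches at lag k, so only
  # sequences with that many lag-1/2/3 matches need the exact check
  up <- toupper(seqs)
  n <- nchar(up)
  maybe <- logical(length(seqs))
  for (L in unique(n)) {
    ii <- which(n == L)
    if (L == 0) next
    M <- matrix(unlist(strsplit(up[ii], "", fixed = TRUE), use.names = FALSE),
                ncol = L, byrow = TRUE)
    hit <- rep(FALSE, length(ii))
    for (k in 1:3) {
      if (L <= k) next
      lagmatch <- if (L - k == 1) {
        as.numeric(M[, 1] == M[, 1 + k])
      } else {
        rowSums(M[, 1:(L - k), drop = FALSE] == M[, (k + 1):L, drop = FALSE])
      }
      hit <- hit | (lagmatch >= threshold * L / 2)
    }
    maybe[ii] <- hit
  }
  out[maybe] <- is_low_complexity_exact(up[maybe], threshold)
  out
}

# exact tandem-coverage rule, one sequence at a time
is_low_complexity_exact <- function(seqs, threshold = 0.8) {
  vapply(seqs, function(s) {
    n <- nchar(s)
    if (n == 0) return(FALSE)
    best <- 0
    for (k in 1:3) {
      if (n < 2 * k) next
      starts <- seq_len(n - k + 1)
      kmers <- substring(s, starts, starts + k - 1)
      # phase-wise tandem runs: consecutive identical k-mers at step k
      cov <- new.env(parent = emptyenv())
      for (r in seq_len(k)) {
        idx <- seq(r, n - k + 1, by = k)
        if (length(idx) < 2) next
        runs <- rle(kmers[idx])
        for (j in seq_along(runs$lengths)) {
          if (runs$lengths[j] >= 2) {
            w <- runs$values[j]
            prev <- if (is.null(cov[[w]])) 0 else cov[[w]]
            cov[[w]] <- prev + runs$lengths[j] * k
          }
        }
      }
      vals <- unlist(as.list(cov), use.names = FALSE)
      if (length(vals)) best <- max(best, max(vals))
    }
    best >= threshold * n
  }, logical(1), USE.NAMES = FALSE)
}

#' Remove reads matching a contaminant (t/rRNA) reference set
#'
#' A read is removed iff it occurs as an exact substring of any
#' contaminant sequence or its reverse complement. Matching reuses the
#' exact k-mer mapper (see [build_index()]); no alignment is performed.
#'
#' @param reads character vector of read sequences.
#' @param contaminant_set named character vector or data.frame
#'   (`id`, `seq`) of contaminant reference sequences.
#' @return list with `kept` reads and `removed_count`.
#' @export
filter_contaminants <- function(reads, contaminant_set) {
  if (is.data.frame(contaminant_set)) {
    refs <- stats::setNames(contaminant_set$seq, contaminant_set$id)
  } else refs <- contaminant_set
  if (length(refs) == 0) {
    warning("filter_contaminants: empty contaminant set; passing all reads through")
    return(list(kept = reads, removed_count = 0L))
  }
  idx <- build_index(refs)
  hit <- has_hit(reads, idx)
  list(kept = reads[!hit], removed_count = sum(hit))
}

#' Collapse cleaned reads to unique sequences with per-library counts
#'
#' @param per_library_reads named list: library id -> character vector of
#'   cleaned read sequences (RNA or DNA; stored as RNA).
#' @return data.frame with column `seq`, one count column per library,
#'   and `total_count`; rows ordered by descending `total_count`, ties
#'   broken lexicographically by sequence.
#' @export
collapse_unique <- function(per_library_reads) {
  if (is.null(names(per_library_reads)) || any(names(per_library_reads) == ""))
    stop("collapse_unique: libraries must be named")
  libs <- names(per_library_reads)
  per_library_reads <- lapply(per_library_reads, as_rna)
  seqs <- sort(unique(unlist(per_library_reads, use.names = FALSE)))
  counts <- vapply(per_library_reads, function(r) {
    tabulate(match(r, seqs), nbins = length(seqs))
  }, integer(length(seqs)))
  if (length(seqs) == 1L) counts <- matrix(counts, nrow = 1, dimnames = list(NULL, libs))
  total <- as.integer(rowSums(counts))
  ord <- order(-total, seqs)
  out <- data.frame(seq = seqs[ord], stringsAsFactors = FALSE)
  for (l in libs) out[[l]] <- counts[ord, l]
  out$total_count <- total[ord]
  out
}

#' Elimination-pipeline accounting
#'
#' Builds the per-category read-accounting summary. The conservation
#' identity `putative = total - (length + low-complexity + invalid +
#' t/rRNA)` is enforced for redundant and unique tallies independently.
#'
#' @param total,length_filtered,low_complexity,invalid,rRNA_tRNA named
#'   numeric vectors `c(redundant = , unique = )`.
#' @param genome_mapped optional, same shape (NA when mapping has not run).
#' @return an object of class `elimination_summary`: a data.frame with
#'   columns `category`, `redundant`, `unique`.
#' @export
elimination_summary <- function(total, length_filtered, low_complexity,
                                invalid, rRNA_tRNA,
                                genome_mapped = c(redundant = NA, unique = NA)) {
  pick <- function(x) c(redundant = unname(x["redundant"]), unique = unname(x["unique"]))
  m <- rbind(total = pick(total), length_filtered = pick(length_filtered),
             low_complexity = pick(low_complexity), invalid = pick(invalid),
             rRNA_tRNA = pick(rRNA_tRNA))
  if (any(is.na(m))) stop("elimination_summary: tallies must be named (redundant, unique)")
  if (any(m < 0)) stop("elimination_summary: negative tally")
  putative <- m["total", ] - colSums(m[2:5, , drop = FALSE])
  if (any(putative < 0))
    stop("elimination_summary: eliminations exceed total reads")
  out <- data.frame(
    category = c(rownames(m), "putative_population", "genome_mapped"),
    redundant = c(m[, "redundant"], putative["redundant"], unname(pick(genome_mapped)["redundant"])),
    unique = c(m[, "unique"], putative["unique"], unname(pick(genome_mapped)["unique"])),
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("elimination_summary", "data.frame")
  out
}

summary_count <- function(summary, category, tally = c("redundant", "unique")) {
  tally <- match.arg(tally)
  summary[[tally]][summary$category == category]
}

#' Length distribution of a unique-read table
#'
#' @param unique_reads a [collapse_unique()] table (or any data.frame
#'   with `seq` and `total_count`).
#' @param range inclusive length range to tabulate (default 16:30).
#' @return data.frame with per-length redundant/unique tallies and
#'   percentages (each percentage column sums to 100).
#' @export
length_distribution <- function(unique_reads, range = 16:30) {
  len <- nchar(unique_reads$seq)
  if (any(len < min(range) | len > max(range)))
    stop("length_distribution: reads outside ", min(range), "-", max(range), " nt")
  red <- vapply(range, function(L) sum(unique_reads$total_count[len == L]), numeric(1))
  uni <- vapply(range, function(L) sum(len == L), numeric(1))
  data.frame(length = range, redundant = red, unique = uni,
             redundant_pct = 100 * red / sum(red),
             unique_pct = 100 * uni / sum(uni))
}

#' Run the full elimination pipeline over per-library reads
#'
#' Applies, in fixed first-match priority order, the length filter,
#' low-complexity filter, invalid-sequence filter and t/rRNA contaminant
#' filter, so every read lands in exactly one category; survivors are
#' collapsed to the unique putative small RNA population.
#'
#' @param libraries named list: library id -> character vector of read
#'   sequences. If `adapter_3p` is given, reads are adapter-trimmed first
#'   and unmatched reads are dropped before accounting starts.
#' @param contaminants contaminant reference sequences (see
#'   [filter_contaminants()]); `NULL` disables the t/rRNA stage.
#' @param adapter_3p optional 3' adapter for [trim_adapter()].
#' @param min_len,max_len length-filter bounds.
#' @param seed_len,require_adapter adapter-trimming parameters.
#' @return list with `unique_reads` (collapsed putative population),
#'   `summary` (an `elimination_summary`), and `library_totals`
#'   (putative redundant reads per library, the TPM denominator).
#' @export
eliminate_reads <- function(libraries, contaminants = NULL, adapter_3p = NULL,
                            min_len = 16, max_len = 30,
                            seed_len = 8, require_adapter = TRUE) {
  if (!length(libraries)) stop("eliminate_reads: no libraries")
  if (!is.null(adapter_3p)) {
    libraries <- lapply(libraries, function(r) {
      t <- trim_adapter(r, adapter_3p, seed_len, require_adapter)
      t[!is.na(t)]
    })
  }
  libraries <- lapply(libraries, as_rna)

  # categorise each distinct sequence once; categories are functions of
  # the sequence alone, so redundant tallies follow by count aggregation
  all_seqs <- unique(unlist(libraries, use.names = FALSE))
  cat_of <- rep("putative", length(all_seqs))
  len <- nchar(all_seqs)
  cat_of[len < min_len | len > max_len] <- "length_filtered"
  open <- cat_of == "putative"
  cat_of[open][is_low_complexity(all_seqs[open])] <- "low_complexity"
  open <- cat_of == "putative"
  cat_of[open][is_invalid(all_seqs[open])] <- "invalid"
  if (!is.null(contaminants)) {
    open <- cat_of == "putative"
    if (any(open)) {
      res <- filter_contaminants(all_seqs[open], contaminants)
      removed <- setdiff(all_seqs[open], res$kept)
      cat_of[match(removed, all_seqs)] <- "rRNA_tRNA"
    }
  }
  names(cat_of) <- all_seqs

  red_tally <- function(category) {
    sum(vapply(libraries, function(r) sum(cat_of[match(r, all_seqs)] == category),
               numeric(1)))
  }
  uni_tally <- function(category) sum(cat_of == category)
  both <- function(category) c(redundant = red_tally(category), unique = uni_tally(category))

  total <- c(redundant = sum(lengths(libraries)), unique = length(all_seqs))
  summ <- elimination_summary(
    total = total,
    length_filtered = both("length_filtered"),
    low_complexity = both("low_complexity"),
    invalid = both("invalid"),
    rRNA_tRNA = both("rRNA_tRNA")
  )

  keep <- lapply(libraries, function(r) r[cat_of[match(r, all_seqs)] == "putative"])
  unique_reads <- collapse_unique(keep)
  list(unique_reads = unique_reads,
       summary = summ,
       library_totals = vapply(keep, length, numeric(1)))
}
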