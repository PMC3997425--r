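#' Read a FASTA file into a record table
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that enforces the
#' pipeline's record contract: ids unique within a file, sequences
#' non-empty, case normalised to upper. Both T and U are accepted and
#' preserved as written; use [as_rna()] / [as_dna()] to convert.
#'
#' @param path path to a FASTA file (plain or gzipped).
#' @return a data.frame with columns `id`, `seq`, `quality`
#'   (`quality` is `NA` for FASTA input).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path, format = "fasta"),
    error = function(e) stop("FASTA parse error in '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("^([^ \t]*).*$", "\\1", names(set))  # id = first header token
  seqs <- toupper(as.character(set))
  if (any(nchar(seqs) == 0)) {
    bad <- ids[nchar(seqs) == 0][1]
    stop("FASTA parse error in '", path, "' at line ",
         fasta_header_line(path, bad), ": record '", bad,
         "' has an empty sequence")
  }
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    stop("FASTA parse error in '", path, "' at line ",
         fasta_header_line(path, dup, occurrence = 2L),
         ": duplicate record id '", dup, "'")
  }
  data.frame(id = ids, seq = unname(seqs), quality = NA_character_,
             stringsAsFactors = FALSE)
}

# locate the file line of the n-th header with a given id (error reporting)
fasta_header_line <- function(path, id, occurrence = 1L) {
  lines <- readLines(path, warn = FALSE)
  hdr <- which(startsWith(lines, ">"))
  hid <- sub("^>([^ \t]*).*$", "\\1", lines[hdr])
  hit <- hdr[hid == id]
  if (length(hit) >= occurrence) hit[occurrence] else NA_integer_
}

#' Read a FASTQ file into a record table
#'
#' Strict 4-line-record parser. Sequence and quality strings must have
#' equal length; violations raise a parse error naming the offending
#' record's first line.
#'
#' @param path path to a FASTQ file (plain or gzipped).
#' @return a data.frame with columns `id`, `seq`, `quality`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("FASTQ file not found: ", path)
  con <- if (grepl("\\.gz$", path)) gzfile(path) else file(path)
  lines <- readLines(con, warn = FALSE)
  close(con)
  if (length(lines) == 0) {
    return(data.frame(id = character(), seq = character(),
                      quality = character(), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4 != 0) {
    stop("FASTQ parse error in '", path, "': line count ", length(lines),
         " is not a multiple of 4")
  }
  i <- seq(1, length(lines), by = 4)
  hdr <- lines[i]; seqs <- lines[i + 1]; plus <- lines[i + 2]; qual <- lines[i + 3]
  bad <- which(!startsWith(hdr, "@") | !startsWith(plus, "+"))
  if (length(bad)) {
    stop("FASTQ parse error in '", path, "' at line ", i[bad[1]],
         ": malformed record header")
  }
  bad <- which(nchar(seqs) != nchar(qual) | nchar(seqs) == 0)
  if (length(bad)) {
    stop("FASTQ parse error in '", path, "' at line ", i[bad[1]],
         ": sequence and quality lengths differ (",
         nchar(seqs[bad[1]]), " vs ", nchar(qual[bad[1]]), ")")
  }
  data.frame(id = sub("^@([^ \t]*).*$", "\\1", hdr),
             seq = toupper(seqs), quality = qual, stringsAsFactors = FALSE)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector, or a data.frame with `id` and `seq`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) {
    ids <- seqs$id; s <- seqs$seq
  } else {
    ids <- names(seqs); s <- unname(seqs)
  }
  if (is.null(ids) || any(is.na(ids)) || any(ids == ""))
    stop("write_fasta: every sequence needs an id")
  writeLines(paste0(">", ids, "\n", s), path, sep = "\n")
  invisible(path)
}

#' Write genomic features as GFF3
#'
#' Features are supplied with 1-based inclusive coordinates (the
#' package's internal 0-based half-open coordinates must be converted by
#' the caller or via `from_halfopen = TRUE`).
#'
#' @param records data.frame with columns `contig`, `start`, `end`,
#'   `strand`, `type`, `ID` and optionally `Parent`.
#' @param path output path.
#' @param from_halfopen if `TRUE`, `start`/`end` are interpreted as
#'   0-based half-open and converted to 1-based inclusive.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(records, path, from_halfopen = FALSE) {
  start <- records$start
  end <- records$end
  if (from_halfopen) {
    start <- start + 1L  # 0-based half-open -> 1-based inclusive
  }
  if (any(start < 1) || any(end < start))
    stop("write_gff3: coordinates must satisfy 1 <= start <= end")
  gr <- GenomicRanges::GRanges(
    seqnames = records$contig,
    ranges = IRanges::IRanges(start = start, end = end),
    strand = records$strand
  )
  gr$type <- records$type
  gr$ID <- records$ID
  if (!is.null(records$Parent)) gr$Parent <- records$Parent
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write a tree in Newick format
#'
#' @param tree an [ape::phylo] object or an [stats::hclust] object
#'   (converted with [ape::as.phylo()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (inherits(tree, "hclust")) tree <- ape::as.phylo(tree)
  if (!inherits(tree, "phylo")) stop("write_newick: need a phylo or hclust object")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read/write tab-separated tables
#'
#' Round-trip-safe TSV helpers used for all tabular artifacts.
#'
#' @param table a data.frame.
#' @param path file path.
#' @return `write_tsv` returns `path` invisibly; `read_tsv_file` a data.frame.
#' @export
write_tsv <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv_file <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}
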