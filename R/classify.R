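#' Ungapped mismatch count between two mature sequences
#'
#' Equal-length sequences are compared end-to-end; length-mismatched
#' pairs are compared at the best ungapped offset, each overhanging base
#' counting one mismatch.
#'
#' @param a,b RNA sequences.
#' @return integer mismatch count.
#' @export
mature_mismatches <- function(a, b) {
  a <- as_rna(a); b <- as_rna(b)
  if (nchar(a) > nchar(b)) { tmp <- a; a <- b; b <- tmp }
  la <- nchar(a); lb <- nchar(b)
  ac <- seq_chars(a); bc <- seq_chars(b)
  best <- Inf
  for (off in 0:(lb - la)) {
    mm <- sum(ac != bc[(off + 1):(off + la)]) + (lb - la)
    if (mm < best) best <- mm
  }
  as.integer(best)
}

#' Classify a mature miRNA against a reference catalog
#'
#' Category thresholds follow the mismatch bands used for wheat:
#' identical to a catalog entry = known, 1-2 mismatches = variant,
#' 3 or more (or no catalog at all) = novel.
#'
#' @param mature RNA sequence of the mature miRNA.
#' @param catalog named character vector (id -> mature sequence) or
#'   data.frame (`id`, `seq`), miRBase-style ids.
#' @return list: `category` ("known", "variant" or "novel"),
#'   `best_match` (catalog id or `NA`), `mismatches`.
#' @export
match_reference <- function(mature, catalog) {
  if (is.data.frame(catalog)) catalog <- stats::setNames(catalog$seq, catalog$id)
  if (length(catalog) == 0)
    return(list(category = "novel", best_match = NA_character_, mismatches = NA_integer_))
  mm <- vapply(catalog, mature_mismatches, integer(1), a = mature)
  k <- which.min(mm)
  n <- mm[[k]]
  category <- if (n == 0) "known" else if (n <= 2) "variant" else "novel"
  list(category = category, best_match = names(catalog)[k], mismatches = n)
}

#' Test whether a predicted star sequence was sequenced
#'
#' @param star_seq predicted star sequence (or `NULL`/`NA`).
#' @param unique_reads a [collapse_unique()] table of cleaned reads.
#' @return `TRUE` iff the star occurs exactly among the unique reads
#'   with count >= 1 in any library.
#' @export
detect_star <- function(star_seq, unique_reads) {
  if (is.null(star_seq) || is.na(star_seq)) return(FALSE)
  as_rna(star_seq) %in% unique_reads$seq
}

# family label from a miRBase-style id: strip species prefix, arm suffix
# and paralog letters, e.g. "zma-miR156i-5p" -> "MIR156"
family_from_id <- function(id) {
  vapply(id, function(one) {
    if (is.na(one)) return(NA_character_)
    x <- sub("^[a-z]{3,4}-", "", one)
    x <- sub("-(5p|3p)$", "", x)
    m <- regmatches(x, regexpr("[0-9]+", x))
    if (length(m)) paste0("MIR", m) else toupper(x)
  }, character(1), USE.NAMES = FALSE)
}

#' Assign names and families to classified miRNA records
#'
#' True novels are named `tae_1..tae_N` and candidate novels
#' `tae_C1..tae_CM`, both in descending total-count order (ties broken
#' lexicographically by sequence). Known and variant miRNAs keep their
#' catalog match's name; families are inherited from the catalog name
#' where available.
#'
#' @param records data.frame with at least `seq`, `category`
#'   (known/variant/true_novel/candidate_novel), `best_match`,
#'   `total_count`.
#' @return the records with `name` and `family` columns filled.
#' @export
assign_names <- function(records) {
  records$name <- NA_character_
  records$family <- NA_character_
  from_catalog <- records$category %in% c("known", "variant")
  records$name[from_catalog] <- records$best_match[from_catalog]
  records$family[from_catalog] <- family_from_id(records$best_match[from_catalog])
  for (grp in list(c("true_novel", "tae_"), c("candidate_novel", "tae_C"))) {
    idx <- which(records$category == grp[1])
    if (!length(idx)) next
    ord <- idx[order(-records$total_count[idx], records$seq[idx])]
    records$name[ord] <- paste0(grp[2], seq_along(ord))
    records$family[ord] <- records$name[ord]
  }
  records
}

#' Classify accepted miRNAs and build the record table
#'
#' Combines catalog matching, star detection among the sequenced reads
#' and naming into the final record table. Novel miRNAs whose predicted
#' star was sequenced are `true_novel`; the rest are `candidate_novel`.
#'
#' @param accepted data.frame with columns `seq` (mature), `star`
#'   (predicted star or `NA`), `total_count`, and optionally per-library
#'   count columns and locus columns.
#' @param catalog reference catalog (see [match_reference()]).
#' @param unique_reads the cleaned unique-read table for star detection.
#' @return data.frame of miRNA records with `name`, `seq`, `category`,
#'   `best_match`, `mismatches`, `family`, `star`, `star_detected`.
#' @export
classify_mirnas <- function(accepted, catalog, unique_reads) {
  res <- lapply(accepted$seq, match_reference, catalog = catalog)
  accepted$best_match <- vapply(res, `[[`, character(1), "best_match")
  accepted$mismatches <- vapply(res, function(r) as.integer(r$mismatches), integer(1))
  base_cat <- vapply(res, `[[`, character(1), "category")
  accepted$star_detected <- vapply(accepted$star, detect_star,
                                   logical(1), unique_reads = unique_reads)
  accepted$category <- ifelse(base_cat != "novel", base_cat,
                              ifelse(accepted$star_detected, "true_novel",
                                     "candidate_novel"))
  assign_names(accepted)
}

#' Presence/absence of mature miRNAs across related species
#'
#' Presence is exact substring occurrence (both strands) of the mature
#' sequence in the species' sequence set, the same criterion as genome
#' mapping.
#'
#' @param records miRNA record table (needs `name`, `seq`, `category`).
#' @param species_sequence_sets named list: species -> named character
#'   vector of sequences.
#' @return list: `matrix` (logical, miRNAs x species) and `totals`
#'   (per-species presence counts by category, species x category).
#' @export
map_conservation <- function(records, species_sequence_sets) {
  if (!length(species_sequence_sets)) stop("map_conservation: no species sets")
  pres <- vapply(species_sequence_sets, function(set) {
    idx <- build_index(set)
    has_hit(records$seq, idx)
  }, logical(nrow(records)))
  if (nrow(records) == 1L)
    pres <- matrix(pres, nrow = 1,
                   dimnames = list(NULL, names(species_sequence_sets)))
  rownames(pres) <- records$name
  cats <- sort(unique(records$category))
  totals <- t(vapply(names(species_sequence_sets), function(sp) {
    vapply(cats, function(cc) sum(pres[records$category == cc, sp]), numeric(1))
  }, numeric(length(cats))))
  colnames(totals) <- cats
  list(matrix = pres, totals = totals)
}
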