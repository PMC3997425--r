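#' Packaged reference tables from the wheat small RNA study
#'
#' Two small fixtures ship with the package: the read-accounting table of
#' the elimination pipeline (redundant and unique tallies per category)
#' and the table of 49 true novel wheat miRNAs with their star sequences
#' and predicted targets. They allow the pipeline's bookkeeping and
#' duplex logic to be checked against published numbers without any
#' download.
#'
#' @return `load_table1_fixture()` returns an `elimination_summary`
#'   object (see [elimination_summary()]); `load_table2_fixture()` a
#'   data.frame with columns `name`, `mature`, `length`, `star`,
#'   `target`, `action`.
#' @name fixtures
NULL

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "hexamir")
  if (!nzchar(p) || !file.exists(p)) stop("packaged fixture missing: ", file)
  p
}

#' @rdname fixtures
#' @export
load_table1_fixture <- function() {
  tab <- read_tsv_file(fixture_path("table1.tsv"))
  need <- c("total", "length_filtered", "low_complexity", "invalid",
            "rRNA_tRNA", "putative_population", "genome_mapped")
  if (!all(need %in% tab$category))
    stop("table1 fixture corrupt: missing categories")
  rownames(tab) <- tab$category
  elimination_summary(
    total           = c(redundant = tab["total", "redundant"],
                        unique    = tab["total", "unique"]),
    length_filtered = c(redundant = tab["length_filtered", "redundant"],
                        unique    = tab["length_filtered", "unique"]),
    low_complexity  = c(redundant = tab["low_complexity", "redundant"],
                        unique    = tab["low_complexity", "unique"]),
    invalid         = c(redundant = tab["invalid", "redundant"],
                        unique    = tab["invalid", "unique"]),
    rRNA_tRNA       = c(redundant = tab["rRNA_tRNA", "redundant"],
                        unique    = tab["rRNA_tRNA", "unique"]),
    genome_mapped   = c(redundant = tab["genome_mapped", "redundant"],
                        unique    = tab["genome_mapped", "unique"])
  )
}

#' @rdname fixtures
#' @export
load_table2_fixture <- function() {
  tab <- read_tsv_file(fixture_path("table2.tsv"))
  tab$action[tab$action == "NA"] <- NA_character_
  if (nrow(tab) == 0) stop("table2 fixture corrupt: no rows")
  if (any(is.na(tab$star) | tab$star == ""))
    stop("table2 fixture corrupt: a true novel record lacks a star sequence")
  if (any(nchar(tab$mature) != tab$length))
    stop("table2 fixture corrupt: printed length disagrees with mature sequence")
  tab
}
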