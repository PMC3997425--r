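#' Discover miRNA hairpins from mapped unique reads
#'
#' Every unique putative read that maps exactly onto the reference seeds
#' one precursor candidate per locus. The mature +- `flank` nt window is
#' the search region; because a maximum-pairing-score fold of a long
#' window can bury a genuine hairpin under alternative flank pairings,
#' the locus is evaluated over a cascade of sub-windows (the full
#' symmetric window first, then asymmetric windows sized for terminal
#' loops up to `flank` - 23 nt on either arm), and the first sub-window
#' whose fold passes the annotation screen wins.
#' Accepted candidates are de-duplicated at the sequence level; when two
#' accepted candidates form each other's duplex (one read is the other's
#' predicted star), the more abundant read is kept as the mature and the
#' other dropped, mirroring the convention that the dominant arm is the
#' miRNA and the minor arm its star.
#'
#' @param unique_reads a [collapse_unique()] table of the putative
#'   population.
#' @param genome named character vector of reference contigs (or a
#'   prebuilt [build_index()] handle via `index`).
#' @param flank precursor flank width (default 100 nt).
#' @param max_mismatch duplex mismatch cap (default 4).
#' @param max_loci per-read cap on genomic loci evaluated (guards
#'   against highly repetitive reads).
#' @param index optional prebuilt index.
#' @return list: `mirnas` (data.frame: seq, star, total_count,
#'   per-library counts, contig, start, end, strand, n_loci,
#'   precursor_len, gc), `candidates` (all evaluated
#'   `hairpin_candidate` objects), `n_mapped` (unique reads with >= 1
#'   genome hit), `n_mapped_redundant`.
#' @export
discover_mirnas <- function(unique_reads, genome, flank = 100,
                            max_mismatch = 4, max_loci = 10, index = NULL) {
  if (is.null(index)) index <- build_index(genome)
  genome <- stats::setNames(index$seqs, index$ids)
  mapped <- has_hit(unique_reads$seq, index)
  n_mapped <- sum(mapped)
  n_mapped_redundant <- sum(unique_reads$total_count[mapped])

  lib_cols <- setdiff(names(unique_reads), c("seq", "total_count"))
  candidates <- list()
  rows <- list()
  for (ri in which(mapped)) {
    read <- unique_reads$seq[ri]
    hits <- map_exact(read, index)
    if (nrow(hits) > max_loci) hits <- hits[seq_len(max_loci), ]
    best <- NULL
    n_acc <- 0L
    for (hi in seq_len(nrow(hits))) {
      cand <- screen_locus(hits[hi, ], genome[[hits$contig[hi]]],
                           flank = flank, max_mismatch = max_mismatch)
      candidates[[length(candidates) + 1]] <- cand
      if (isTRUE(cand$accepted)) {
        n_acc <- n_acc + 1L
        if (is.null(best)) best <- cand
      }
    }
    if (!is.null(best)) {
      row <- data.frame(seq = read, star = best$duplex$star,
                        total_count = unique_reads$total_count[ri],
                        stringsAsFactors = FALSE)
      for (l in lib_cols) row[[l]] <- unique_reads[[l]][ri]
      row$contig <- best$precursor$contig
      row$start <- best$precursor$start + best$trimmed$start - 1L
      row$end <- best$precursor$start + best$trimmed$end
      row$strand <- best$precursor$strand
      row$n_loci <- n_acc
      row$precursor_len <- nchar(best$trimmed$seq)
      row$gc <- best$gc
      rows[[length(rows) + 1]] <- row
    }
  }
  mirnas <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(mirnas)) {
    # arm-dominance resolution: drop a call whose mature is the predicted
    # star of a more abundant accepted call
    keep <- rep(TRUE, nrow(mirnas))
    ord <- order(-mirnas$total_count, mirnas$seq)
    seen_star <- character(0)
    for (i in ord) {
      if (mirnas$seq[i] %in% seen_star) { keep[i] <- FALSE; next }
      seen_star <- c(seen_star, mirnas$star[i])
    }
    mirnas <- mirnas[keep, ]
    rownames(mirnas) <- NULL
  }
  list(mirnas = mirnas, candidates = candidates,
       n_mapped = n_mapped, n_mapped_redundant = n_mapped_redundant)
}

#' Screen one genome hit for an acceptable miRNA hairpin
#'
#' Evaluates the locus over the sub-window cascade (see
#' [discover_mirnas()]) with the stem-loop folder. A mismatch-free
#' candidate whose trimmed stem-loop sits strictly inside its window
#' ("complete") wins immediately; otherwise all windows are screened and
#' the best accepted candidate is kept (complete before clipped, then
#' fewest duplex mismatches), so a hairpin clipped at a window edge or a
#' spurious flank stem never shadows the genuine call from another
#' window.
#'
#' @param hit one row of a [map_exact()] hit table.
#' @param contig_seq sequence of the hit's contig.
#' @param flank search-region half-width (default 100 nt).
#' @param max_mismatch duplex mismatch cap.
#' @return the best `hairpin_candidate` for the locus (check
#'   `$accepted`).
#' @export
screen_locus <- function(hit, contig_seq, flank = 100, max_mismatch = 4) {
  best <- NULL
  best_key <- c(Inf, Inf)   # (0 if complete else 1, mismatches)
  last <- NULL
  for (w in precursor_windows(flank)) {
    prec <- extract_precursor(hit, contig_seq, flank = w[1], flank_3p = w[2])
    cand <- evaluate_hairpin(prec, fold_hairpin(prec$seq),
                             max_mismatch = max_mismatch)
    last <- cand
    if (!isTRUE(cand$accepted)) next
    complete <- cand$trimmed$start > 1 &&
      cand$trimmed$end < nchar(prec$seq)
    if (complete && cand$duplex$mismatches == 0) return(cand)
    key <- c(if (complete) 0 else 1, cand$duplex$mismatches)
    if (key[1] < best_key[1] ||
        (key[1] == best_key[1] && key[2] < best_key[2])) {
      best <- cand
      best_key <- key
    }
  }
  if (!is.null(best)) best else last
}

# sub-window cascade over the +-flank search region: tight asymmetric
# windows first (least flank noise; the short side carries the mature
# arm, the long side must hold loop + star arm + overhang), the full
# symmetric window as the fallback for the longest loops
precursor_windows <- function(flank = 100) {
  ws <- list()
  for (r in seq(31, flank, by = 15)) {
    ws[[length(ws) + 1]] <- c(8, r)
    ws[[length(ws) + 1]] <- c(r, 8)
  }
  ws[[length(ws) + 1]] <- c(flank, flank)
  ws
}

#' Validate a pipeline configuration
#'
#' @param config a named list (or path to a YAML file) with elements
#'   `libraries` (named list of FASTQ/FASTA paths or read vectors),
#'   `genome`, `contaminants`, `catalog`, `transcriptome` (paths or
#'   objects; contaminants/catalog/transcriptome optional), `outdir`,
#'   `params` (optional overrides) and `seed`.
#' @return the normalised config list; errors of class
#'   `hexamir_config_error` on any violation.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) config <- yaml::read_yaml(config)
  fail <- function(...) stop(errorCondition(paste0(...),
                                            class = c("hexamir_config_error", "error")))
  if (is.null(config$libraries) || !length(config$libraries))
    fail("config: 'libraries' is required")
  if (is.null(config$genome)) fail("config: 'genome' is required")
  # a length-1 string with a sequence-file extension is a path; anything
  # else character is taken as in-memory sequence data
  looks_path <- function(v) {
    is.character(v) && length(v) == 1 &&
      grepl("\\.(fa|fasta|fq|fastq|tsv|txt)(\\.gz)?$", v, ignore.case = TRUE)
  }
  for (field in c("genome", "contaminants", "catalog", "transcriptome")) {
    v <- config[[field]]
    if (looks_path(v) && !file.exists(v))
      fail("config: ", field, " path does not exist: ", v)
  }
  for (l in names(config$libraries)) {
    v <- config$libraries[[l]]
    if (looks_path(v) && !file.exists(v))
      fail("config: library ", l, " path does not exist: ", v)
  }
  defaults <- list(min_len = 16, max_len = 30, flank = 100, max_mismatch = 4,
                   variant_max = 2, novel_min = 3, de_threshold = 1.0,
                   target_cutoff = 3.0, detection_threshold = 0,
                   adapter_3p = NULL, seed_len = 8)
  params <- utils::modifyList(defaults, config$params %||% list())
  for (p in c("min_len", "max_len", "flank", "max_mismatch", "de_threshold",
              "target_cutoff")) {
    if (!is.numeric(params[[p]]) || params[[p]] < 0)
      fail("config: parameter ", p, " must be a non-negative number")
  }
  if (params$min_len > params$max_len) fail("config: min_len > max_len")
  config$params <- params
  if (is.null(config$seed)) config$seed <- 1L
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a

read_seq_input <- function(x, as = c("vector", "reads")) {
  as <- match.arg(as)
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    rec <- if (grepl("\\.(fq|fastq)(\\.gz)?$", x)) read_fastq(x) else read_fasta(x)
    if (as == "vector") return(stats::setNames(rec$seq, rec$id))
    return(rec$seq)
  }
  if (is.data.frame(x)) return(stats::setNames(x$seq, x$id))
  if (as == "vector") return(x)
  unname(x)
}

#' Run the full small RNA analysis pipeline
#'
#' Executes clean -> map -> discover -> classify -> express -> targets
#' and writes every artifact (elimination summary, collapsed putative
#' FASTA, hairpin GFF3/TSV, classification TSV, TPM/fold-change/Venn
#' TSVs, dendrogram Newick, target TSV) plus a YAML run report into
#' `config$outdir`.
#'
#' @param config see [validate_config()].
#' @return the run report (a named list), invisibly; the report is also
#'   written to `outdir/report.yaml`.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(config)
  p <- config$params
  outdir <- config$outdir %||% tempfile("hexamir_run_")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  libraries <- stage("load", lapply(config$libraries, read_seq_input, as = "reads"))
  genome <- stage("load", read_seq_input(config$genome))
  contaminants <- if (!is.null(config$contaminants))
    stage("load", read_seq_input(config$contaminants)) else NULL
  catalog <- if (!is.null(config$catalog))
    stage("load", read_seq_input(config$catalog)) else character(0)
  transcriptome <- if (!is.null(config$transcriptome))
    stage("load", read_seq_input(config$transcriptome)) else NULL

  clean <- stage("clean", eliminate_reads(
    libraries, contaminants = contaminants, adapter_3p = p$adapter_3p,
    min_len = p$min_len, max_len = p$max_len, seed_len = p$seed_len))
  ur <- clean$unique_reads

  index <- stage("map", build_index(genome, k = min(16, p$min_len)))
  disc <- stage("discover", discover_mirnas(
    ur, genome, flank = p$flank, max_mismatch = p$max_mismatch, index = index))

  summ <- clean$summary
  summ$redundant[summ$category == "genome_mapped"] <- disc$n_mapped_redundant
  summ$unique[summ$category == "genome_mapped"] <- disc$n_mapped
  write_tsv(summ, file.path(outdir, "elimination_summary.tsv"))
  write_tsv(length_distribution(ur, p$min_len:p$max_len),
            file.path(outdir, "length_distribution.tsv"))
  write_fasta(stats::setNames(ur$seq,
                              paste0("seq", seq_len(nrow(ur)), "_x", ur$total_count)),
              file.path(outdir, "putative_unique.fasta"))

  report <- list(parameters = p, seed = config$seed,
                 libraries = names(libraries),
                 elimination = stats::setNames(
                   lapply(seq_len(nrow(summ)), function(i)
                     list(redundant = summ$redundant[i], unique = summ$unique[i])),
                   summ$category))

  if (is.null(disc$mirnas) || nrow(disc$mirnas) == 0) {
    report$mirnas <- list(total = 0L)
    yaml::write_yaml(report, file.path(outdir, "report.yaml"))
    return(invisible(report))
  }

  records <- stage("classify", classify_mirnas(disc$mirnas, catalog, ur))
  write_gff3(data.frame(contig = records$contig, start = records$start,
                        end = records$end, strand = records$strand,
                        type = "miRNA_primary_transcript", ID = records$name,
                        stringsAsFactors = FALSE),
             file.path(outdir, "hairpins.gff3"), from_halfopen = TRUE)
  write_tsv(records[, setdiff(names(records), "quality")],
            file.path(outdir, "mirna_records.tsv"))

  lib_cols <- intersect(names(libraries), names(records))
  counts <- as.matrix(records[, lib_cols, drop = FALSE])
  rownames(counts) <- records$name
  tpm <- stage("express", tpm_normalize(counts, clean$library_totals))
  write_tsv(data.frame(name = rownames(tpm), tpm, check.names = FALSE),
            file.path(outdir, "tpm.tsv"))

  stress <- intersect(c("HS", "SS", "WDS"), colnames(tpm))
  de <- character(0); venn_tissue <- NULL; venn_ts <- NULL
  if ("C" %in% colnames(tpm) && length(stress)) {
    contrasts <- stats::setNames(lapply(stress, function(s) c(s, "C")), stress)
    fc <- fold_change_table(tpm, contrasts)
    write_tsv(data.frame(name = rownames(fc), fc, check.names = FALSE),
              file.path(outdir, "fold_change.tsv"))
    de <- select_de(fc, p$de_threshold)
    if (length(de) >= 2) {
      dend <- cluster_uncentered_average(tpm[de, c("C", stress), drop = FALSE])
      write_newick(dend, file.path(outdir, "dendrogram.nwk"))
    }
  }
  tissues <- intersect(c("shoot", "root", "leaf", "spikelet"), colnames(counts))
  if (length(tissues) >= 2) {
    venn_tissue <- venn_partition(counts,
                                  sets = stats::setNames(as.list(tissues), tissues),
                                  threshold = p$detection_threshold)
    write_tsv(data.frame(region = names(venn_tissue), count = venn_tissue),
              file.path(outdir, "venn_tissue.tsv"))
  }
  if (length(tissues) >= 1 && length(stress) >= 1) {
    venn_ts <- venn_partition(counts,
                              sets = list(tissue = tissues,
                                          stress = c("C", stress)),
                              threshold = p$detection_threshold)
  }

  targets <- NULL
  if (!is.null(transcriptome)) {
    targets <- stage("targets", do.call(rbind, lapply(seq_len(nrow(records)),
      function(i) scan_transcripts(records$seq[i], transcriptome,
                                   cutoff = p$target_cutoff,
                                   mirna_name = records$name[i]))))
    write_tsv(targets, file.path(outdir, "targets.tsv"))
  }

  cat_tab <- table(factor(records$category,
                          c("known", "variant", "true_novel", "candidate_novel")))
  report$mirnas <- list(total = nrow(records),
                        known = unname(cat_tab[["known"]]),
                        variant = unname(cat_tab[["variant"]]),
                        true_novel = unname(cat_tab[["true_novel"]]),
                        candidate_novel = unname(cat_tab[["candidate_novel"]]))
  report$expression <- list(
    de_count = length(de),
    de = as.list(de),
    venn_tissue = if (!is.null(venn_tissue)) as.list(venn_tissue),
    venn_tissue_stress = if (!is.null(venn_ts)) as.list(venn_ts))
  if (!is.null(targets))
    report$targets <- list(hits = nrow(targets),
                           mirnas_with_target = length(unique(targets$mirna)))
  yaml::write_yaml(report, file.path(outdir, "report.yaml"))
  invisible(report)
}

#' Generate a complete synthetic input bundle
#'
#' One call produces genome, truth design, contaminants, catalog,
#' transcriptome and the eight simulated libraries, i.e. everything
#' [run_pipeline()] needs, either in memory or written to `dir`.
#'
#' @param seed master seed; stage seeds are derived from it.
#' @param n_hairpins,depth,n_transcripts scale knobs.
#' @param dir when given, FASTA/FASTQ/TSV artifacts are written there.
#' @param adapter_3p adapter appended to simulated reads (`NULL` = none).
#' @return list with `genome`, `truth`, `contaminants`, `catalog`,
#'   `transcripts`, `sites`, `sim` (see [simulate_libraries()]) and
#'   `config` (ready for [run_pipeline()]).
#' @export
simulate_inputs <- function(seed = 1, n_hairpins = 20, depth = 2e5,
                            n_transcripts = 30, dir = NULL,
                            adapter_3p = NULL) {
  gen <- make_genome(n_hairpins = n_hairpins, seed = seed)
  truth <- design_truth(gen$truth,
                        n_known = max(1, round(0.3 * n_hairpins)),
                        n_variant = max(1, round(0.2 * n_hairpins)),
                        n_candidate = max(1, round(0.2 * n_hairpins)))
  contaminants <- make_contaminants(seed = seed + 1)
  catalog <- make_catalog(truth, seed = seed + 2)
  txm <- make_transcriptome(truth, n_transcripts = n_transcripts,
                            seed = seed + 3)
  sim <- simulate_libraries(truth, depth = depth, seed = seed + 4,
                            contaminants = contaminants,
                            transcripts = txm$transcripts,
                            adapter_3p = adapter_3p,
                            out_dir = if (!is.null(dir)) file.path(dir, "reads"))
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(gen$genome, file.path(dir, "genome.fasta"))
    write_fasta(contaminants, file.path(dir, "contaminants.fasta"))
    write_fasta(catalog, file.path(dir, "catalog.fasta"))
    write_fasta(txm$transcripts, file.path(dir, "transcriptome.fasta"))
    write_tsv(truth, file.path(dir, "truth.tsv"))
  }
  config <- list(
    libraries = if (!is.null(dir)) as.list(sim$files) else sim$reads,
    genome = if (!is.null(dir)) file.path(dir, "genome.fasta") else gen$genome,
    contaminants = if (!is.null(dir)) file.path(dir, "contaminants.fasta") else contaminants,
    catalog = if (!is.null(dir)) file.path(dir, "catalog.fasta") else catalog,
    transcriptome = if (!is.null(dir)) file.path(dir, "transcriptome.fasta") else txm$transcripts,
    outdir = if (!is.null(dir)) file.path(dir, "out"),
    params = if (!is.null(adapter_3p)) list(adapter_3p = adapter_3p) else list(),
    seed = seed)
  list(genome = gen$genome, truth = truth, contaminants = contaminants,
       catalog = catalog, transcripts = txm$transcripts, sites = txm$sites,
       sim = sim, config = config)
}
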