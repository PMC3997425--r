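# run expr with a private RNG stream, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

random_dna <- function(n, len, gc = 0.45) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(names(p), len, replace = TRUE, prob = p), collapse = ""),
    character(1))
}

mutate_bases <- function(seq, n_mut) {
  if (n_mut == 0) return(seq)
  alphabet <- if (grepl("U", toupper(seq), fixed = TRUE))
    c("A", "C", "G", "U") else c("A", "C", "G", "T")
  ch <- seq_chars(seq)
  pos <- sample(length(ch), n_mut)
  for (p in pos) ch[p] <- sample(setdiff(alphabet, ch[p]), 1)
  paste(ch, collapse = "")
}

# read-length weights of a plant small RNA library: 24-mers dominate,
# then 23 and 21 (heterochromatic siRNA background plus miRNA classes)
default_length_weights <- function() {
  w <- stats::setNames(rep(0.01, 15), 16:30)
  w["20"] <- 0.05; w["21"] <- 0.10; w["22"] <- 0.07
  w["23"] <- 0.11; w["24"] <- 0.55
  w / sum(w)
}

#' Default eight-library study design
#'
#' Four tissue libraries (shoot, root, leaf, spikelet), a control and
#' three abiotic stress libraries (high temperature HS, salinity SS,
#' water-deficit WDS), mirroring a tissue/stress small RNA atlas design.
#'
#' @return character vector of library ids.
#' @export
default_libraries <- function() c("C", "HS", "SS", "WDS",
                                  "shoot", "root", "leaf", "spikelet")

# expression archetypes: per-library abundance multipliers
profile_multipliers <- function(profile, libs) {
  m <- stats::setNames(rep(1, length(libs)), libs)
  switch(profile,
         constant = m,
         hs_induced = { m["HS"] <- 4; m },
         ss_repressed = { m["SS"] <- 0.25; m },
         wds_induced = { m["WDS"] <- 4; m },
         root_specific = { m[c("shoot", "leaf", "spikelet")] <- 0; m },
         leaf_enriched = { m["leaf"] <- 4; m },
         m)
}

#' Generate a synthetic genome with planted miRNA hairpins
#'
#' Contigs are uniform-random background (wheat-like 45% GC by default)
#' with hairpin inserts `mature + loop + arm`, where the arm is the
#' reverse complement of the mature carrying 0-2 substitutions and the
#' loop is 8-60 nt. The planted star is the arm's 3' portion plus the
#' two following bases, i.e. exactly the sequence the 2-nt-overhang
#' duplex register excises.
#'
#' @param n_contigs,contig_len genome shape (`contig_len` >= 500).
#' @param n_hairpins number of planted hairpins (>= 1).
#' @param seed RNG seed; all randomness is private to this call.
#' @param gc background GC fraction.
#' @param arm_mut substitutions allowed in the star arm (sampled 0-2 by
#'   default; pass `0` for perfect hairpins).
#' @param loop_range terminal-loop length range.
#' @return list: `genome` (named character vector of contigs, DNA) and
#'   `truth` (data.frame: name, contig, start, end (0-based half-open
#'   mature locus), strand, mature, star (RNA), arm_mutations, plus
#'   design columns filled by [design_truth()]).
#' @export
make_genome <- function(n_contigs = 2, contig_len = 10000, n_hairpins = 20,
                        seed = 1, gc = 0.45, arm_mut = NULL,
                        loop_range = c(8, 60)) {
  if (contig_len < 500) stop("make_genome: contig_len must be >= 500")
  if (n_hairpins < 1) stop("make_genome: need at least one hairpin")
  with_seed(seed, {
    contigs <- random_dna(n_contigs, contig_len, gc)
    names(contigs) <- paste0("ctg", seq_len(n_contigs))
    occupied <- lapply(seq_len(n_contigs), function(i) integer(0))
    rows <- list()
    # matures kept mutually distant so catalog classes cannot collide
    matures <- character(0)
    for (h in seq_len(n_hairpins)) {
      L <- sample(c(20, 21, 22), 1, prob = c(0.2, 0.6, 0.2))
      repeat {
        mat <- random_dna(1, L, gc = 0.5)
        if (!length(matures) ||
            min(vapply(matures, mature_mismatches, integer(1), a = mat)) >= 6)
          break
      }
      matures <- c(matures, mat)
      loop_len <- sample(loop_range[1]:loop_range[2], 1)
      nm <- if (is.null(arm_mut)) sample(0:2, 1) else arm_mut
      arm <- mutate_bases(revcomp(mat), nm)
      insert <- paste0(mat, loop_len_seq <- random_dna(1, loop_len, gc), arm)
      ilen <- nchar(insert)
      placed <- FALSE
      for (try in 1:200) {
        ci <- sample(n_contigs, 1)
        pos <- sample(120:(contig_len - ilen - 120), 1)  # 0-based insert start
        span <- pos:(pos + ilen + 2)
        if (!any(span %in% occupied[[ci]])) {
          substr(contigs[ci], pos + 1, pos + ilen) <- insert
          occupied[[ci]] <- c(occupied[[ci]],
                              (pos - 110):(pos + ilen + 110))
          star_start <- pos + L + loop_len + 2     # 0-based
          star <- substr(contigs[ci], star_start + 1, star_start + L)
          rows[[h]] <- data.frame(
            name = paste0("mir_", h), contig = names(contigs)[ci],
            start = pos, end = pos + L, strand = "+",
            mature = as_rna(mat), star = as_rna(star),
            arm_mutations = nm, loop_len = loop_len,
            stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("make_genome: could not place hairpin ", h,
                        " without overlap; enlarge the genome")
    }
    list(genome = contigs, truth = do.call(rbind, rows))
  })
}

#' Attach a catalog/star/expression design to a truth set
#'
#' Splits the planted hairpins into the four downstream categories
#' (known = exact catalog copy, variant = 1-2-mismatch catalog homolog,
#' true novel = absent from the catalog but star sequenced, candidate
#' novel = absent and star never sequenced) and assigns each an
#' expression archetype with per-library abundance multipliers.
#'
#' @param truth truth data.frame from [make_genome()].
#' @param n_known,n_variant,n_candidate category design (the remainder
#'   are true novels).
#' @param star_ratio star:mature abundance ratio for star-producing
#'   hairpins (candidate novels get 0).
#' @param libs library ids.
#' @return the truth table with `category_design`, `star_ratio`,
#'   `profile` and one `mult_<lib>` column per library.
#' @export
design_truth <- function(truth, n_known = 6, n_variant = 4, n_candidate = 4,
                         star_ratio = 0.1, libs = default_libraries()) {
  n <- nrow(truth)
  if (n_known + n_variant + n_candidate > n)
    stop("design_truth: category design exceeds hairpin count")
  cat <- rep("true_novel", n)
  cat[seq_len(n_known)] <- "known"
  cat[n_known + seq_len(n_variant)] <- "variant"
  cat[(n - n_candidate + 1):n] <- "candidate_novel"
  truth$category_design <- cat
  truth$star_ratio <- ifelse(cat == "candidate_novel", 0, star_ratio)
  # one hairpin per differential archetype, the rest constant: keeping
  # differential mass small keeps the compositional shift of the TPM
  # denominator well below the fold-change recovery tolerance
  diff_profiles <- c("hs_induced", "ss_repressed", "wds_induced",
                     "leaf_enriched", "root_specific")
  truth$profile <- "constant"
  slots <- unique(round(seq(1, n, length.out = min(n, length(diff_profiles)))))
  truth$profile[slots] <- diff_profiles[seq_along(slots)]
  for (l in libs) truth[[paste0("mult_", l)]] <-
    vapply(truth$profile, function(p) profile_multipliers(p, libs)[l], numeric(1))
  truth
}

#' Generate a contaminant (t/rRNA stand-in) reference set
#'
#' @param n number of contaminant sequences.
#' @param len length of each.
#' @param seed RNG seed.
#' @return named character vector of DNA sequences.
#' @export
make_contaminants <- function(n = 10, len = 1500, seed = 1) {
  with_seed(seed, stats::setNames(random_dna(n, len, gc = 0.52),
                                  paste0("rrna_trna_", seq_len(n))))
}

#' Simulate the eight small RNA libraries
#'
#' Reads are drawn per library from the mixture: planted matures (with
#' per-library differential-abundance multipliers and per-hairpin
#' star:mature ratios), contaminant fragments, degradation fragments
#' (windows of transcripts, or random sequence when no transcriptome is
#' given), junk-length reads (< 16 or > 30 nt) and invalid reads
#' (N-containing). A 3' adapter is appended when supplied, so the
#' output goes through [trim_adapter()] like real sequencer output.
#'
#' @param truth designed truth table (see [design_truth()]).
#' @param depth reads per library (>= 1e4).
#' @param seed RNG seed.
#' @param libs library ids (need `mult_<lib>` columns in `truth`).
#' @param proportions mixture weights over categories
#'   (mirna/contaminant/degradation/junk/invalid); must sum to 1.
#' @param contaminants contaminant reference set (fragments are sampled
#'   from it so the t/rRNA filter can remove them).
#' @param transcripts optional named vector of transcript sequences for
#'   degradation fragments.
#' @param adapter_3p optional adapter to append.
#' @param out_dir when given, one FASTQ per library is written there.
#' @return list: `reads` (named list of per-library DNA read vectors),
#'   `category_counts` (libraries x categories), `mature_counts` and
#'   `star_counts` (hairpins x libraries true counts), `files`.
#' @export
simulate_libraries <- function(truth, depth = 2e5, seed = 1,
                               libs = default_libraries(),
                               proportions = c(mirna = 0.5, contaminant = 0.2,
                                               degradation = 0.2, junk = 0.05,
                                               invalid = 0.05),
                               contaminants = make_contaminants(seed = seed),
                               transcripts = NULL, adapter_3p = NULL,
                               out_dir = NULL) {
  if (depth < 1e4) stop("simulate_libraries: depth must be >= 1e4")
  if (abs(sum(proportions) - 1) > 1e-9)
    stop("simulate_libraries: proportions must sum to 1")
  lw <- default_length_weights()
  with_seed(seed, {
    reads <- list()
    category_counts <- matrix(0L, length(libs), length(proportions),
                              dimnames = list(libs, names(proportions)))
    H <- nrow(truth)
    mature_counts <- matrix(0L, H, length(libs),
                            dimnames = list(truth$name, libs))
    star_counts <- mature_counts
    mat_dna <- as_dna(truth$mature)
    star_dna <- as_dna(truth$star)
    for (lib in libs) {
      n_cat <- stats::rmultinom(1, depth, proportions)[, 1]
      names(n_cat) <- names(proportions)
      category_counts[lib, ] <- n_cat
      out <- character(0)

      # planted miRNAs: hairpin chosen by multiplier weight, then the
      # read is the mature or (with probability ratio/(1+ratio)) the star
      w <- truth[[paste0("mult_", lib)]]
      if (n_cat["mirna"] > 0 && sum(w) > 0) {
        hp <- sample.int(H, n_cat["mirna"], replace = TRUE, prob = w)
        p_star <- truth$star_ratio[hp] / (1 + truth$star_ratio[hp])
        is_star <- stats::runif(length(hp)) < p_star
        out <- c(out, ifelse(is_star, star_dna[hp], mat_dna[hp]))
        mature_counts[, lib] <- tabulate(hp[!is_star], nbins = H)
        star_counts[, lib] <- tabulate(hp[is_star], nbins = H)
      }
      # contaminant fragments (removed by the t/rRNA filter)
      if (n_cat["contaminant"] > 0) {
        src <- sample(contaminants, n_cat["contaminant"], replace = TRUE)
        len <- as.integer(sample(names(lw), n_cat["contaminant"], TRUE, lw))
        st <- floor(stats::runif(n_cat["contaminant"]) * (nchar(src) - len)) + 1
        out <- c(out, substr(src, st, st + len - 1))
      }
      # degradation background: transcript windows (or random sequence)
      if (n_cat["degradation"] > 0) {
        len <- as.integer(sample(names(lw), n_cat["degradation"], TRUE, lw))
        if (!is.null(transcripts)) {
          src <- as_dna(sample(transcripts, n_cat["degradation"], replace = TRUE))
          st <- floor(stats::runif(n_cat["degradation"]) * (nchar(src) - len)) + 1
          out <- c(out, substr(src, st, st + len - 1))
        } else {
          out <- c(out, vapply(len, function(l) random_dna(1, l), character(1)))
        }
      }
      # junk lengths
      if (n_cat["junk"] > 0) {
        len <- sample(c(10:15, 31:40), n_cat["junk"], replace = TRUE)
        out <- c(out, vapply(len, function(l) random_dna(1, l), character(1)))
      }
      # invalid (N-containing) reads
      if (n_cat["invalid"] > 0) {
        base <- vapply(sample(20:24, n_cat["invalid"], TRUE),
                       function(l) random_dna(1, l), character(1))
        pos <- sample(10, n_cat["invalid"], replace = TRUE)
        substr(base, pos, pos) <- "N"
        out <- c(out, base)
      }
      out <- sample(out)  # shuffle categories together
      if (!is.null(adapter_3p)) out <- paste0(out, as_dna(adapter_3p))
      reads[[lib]] <- out
    }
    files <- NULL
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      files <- vapply(libs, function(lib) {
        path <- file.path(out_dir, paste0(lib, ".fastq"))
        r <- reads[[lib]]
        writeLines(paste0("@", lib, "_", seq_along(r), "\n", r, "\n+\n",
                          strrep("I", nchar(r))), path)
        path
      }, character(1))
    }
    list(reads = reads, category_counts = category_counts,
         mature_counts = mature_counts, star_counts = star_counts,
         files = files)
  })
}

#' Build a miRBase-style catalog matching the truth design
#'
#' Hairpins designed `known` get an exact catalog copy, `variant` ones a
#' 1-2-substitution homolog, novels are omitted; unrelated decoy entries
#' (kept >= 3 mismatches from every planted mature) pad the catalog.
#'
#' @param truth designed truth table.
#' @param seed RNG seed.
#' @param n_decoys number of unrelated catalog entries.
#' @return named character vector (miRBase-style id -> mature RNA).
#' @export
make_catalog <- function(truth, seed = 1, n_decoys = 10) {
  with_seed(seed, {
    prefixes <- c("osa", "zma", "bdi", "hvu", "ata", "tae")
    fams <- sample(100:999, nrow(truth) + n_decoys)
    mk_id <- function(i) paste0(sample(prefixes, 1), "-miR", fams[i],
                                sample(letters[1:9], 1),
                                sample(c("", "-5p", "-3p"), 1, prob = c(.5, .3, .2)))
    entries <- character(0)
    for (i in seq_len(nrow(truth))) {
      cd <- truth$category_design[i]
      if (cd == "known") {
        entries[mk_id(i)] <- truth$mature[i]
      } else if (cd == "variant") {
        entries[mk_id(i)] <- as_rna(mutate_bases(truth$mature[i], sample(1:2, 1)))
      }
    }
    d <- 0
    while (d < n_decoys) {
      cand <- as_rna(random_dna(1, 21))
      if (min(vapply(truth$mature, mature_mismatches, integer(1), a = cand)) >= 5) {
        entries[mk_id(nrow(truth) + d + 1)] <- cand
        d <- d + 1
      }
    }
    entries
  })
}

#' Build a synthetic transcriptome with planted target sites
#'
#' Plants near-complementary sites of designed penalty classes
#' (0 = perfect, ~1 = one seed wobble or 3' mismatch, ~2.5 = wobble plus
#' mismatches, above-cutoff = two seed mismatches) for a rotating subset
#' of the planted matures.
#'
#' @param truth designed truth table.
#' @param n_transcripts number of transcripts (>= 1).
#' @param seed RNG seed.
#' @param tx_len transcript length.
#' @return list: `transcripts` (named character vector, DNA) and
#'   `sites` (data.frame: transcript, mirna name, start 0-based,
#'   penalty_design).
#' @export
make_transcriptome <- function(truth, n_transcripts = 30, seed = 1,
                               tx_len = 800) {
  if (n_transcripts < 1) stop("make_transcriptome: need >= 1 transcript")
  with_seed(seed, {
    tx <- random_dna(n_transcripts, tx_len, gc = 0.47)
    names(tx) <- paste0("TX", sprintf("%03d", seq_len(n_transcripts)))
    classes <- c(0, 1, 2.5, 4)
    sites <- list()
    H <- nrow(truth)
    for (i in seq_len(min(H, n_transcripts))) {
      mat <- truth$mature[i]
      L <- nchar(mat)
      cls <- classes[(i - 1) %% length(classes) + 1]
      site <- revcomp(mat)                      # perfect WC site, RNA
      ch <- seq_chars(site)
      flip_mismatch <- function(k) {            # mismatch facing mir pos k
        sp <- L - k + 1
        ch[sp] <<- setdiff(c("A", "C", "G", "U"),
                           c(ch[sp], comp_base(substr(mat, k, k)),
                             wobble_partner(substr(mat, k, k))))[1]
      }
      make_wobble <- function(k) {              # G:U wobble facing mir pos k
        sp <- L - k + 1
        ch[sp] <<- wobble_partner(substr(mat, k, k))
      }
      if (cls == 1) flip_mismatch(L - 1) else if (cls == 2.5) {
        make_wobble(5)                          # 0.5 x 2
        flip_mismatch(L - 1)                    # 1
        make_wobble(L - 2)                      # 0.5
      } else if (cls == 4) { flip_mismatch(5); flip_mismatch(8) }
      if (cls == 2.5) {
        # a G/C without a wobble partner makes the class unattainable at
        # that position; fall back to mismatches worth the same penalty
        if (is.na(ch[L - 5 + 1]) || is.na(ch[L - (L - 2) + 1])) {
          ch <- seq_chars(revcomp(mat)); flip_mismatch(L - 1); flip_mismatch(L)
          cls <- 2  # two 3' mismatches: 1 + 1
        }
      }
      site <- paste(ch, collapse = "")
      pos <- sample(50:(tx_len - L - 50), 1)    # 0-based
      ti <- names(tx)[i %% n_transcripts + 1]
      substr(tx[ti], pos + 1, pos + L) <- as_dna(site)
      sites[[length(sites) + 1]] <- data.frame(
        transcript = ti, mirna = truth$name[i], start = pos,
        penalty_design = cls, stringsAsFactors = FALSE)
    }
    list(transcripts = tx, sites = do.call(rbind, sites))
  })
}

comp_base <- function(b) chartr("ACGU", "UGCA", as_rna(b))
wobble_partner <- function(b) {
  b <- as_rna(b)
  if (b == "G") "U" else if (b == "U") "G" else NA_character_
}
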