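#' Tags-per-million normalisation
#'
#' TPM divides each miRNA's read count by the putative small RNA
#' population size of its library and multiplies by 10^6, so the TPM of
#' the full putative population sums to 10^6 per library.
#'
#' @param counts numeric matrix (miRNAs x libraries) of raw read counts.
#' @param library_totals named numeric vector: putative population size
#'   per library (must cover every column of `counts`, all > 0).
#' @return numeric matrix of TPM values, same dimensions as `counts`.
#' @export
tpm_normalize <- function(counts, library_totals) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts))) stop("tpm_normalize: counts needs library column names")
  missing <- setdiff(colnames(counts), names(library_totals))
  if (length(missing)) stop("tpm_normalize: no library total for ", missing[1])
  tot <- library_totals[colnames(counts)]
  if (any(tot <= 0)) stop("tpm_normalize: library totals must be positive")
  sweep(counts, 2, tot, "/") * 1e6
}

#' Log2 fold change between treatment and control TPM
#'
#' No pseudo-count is added: a zero on either side makes the ratio
#' undefined and is flagged rather than imputed.
#'
#' @param treatment_tpm,control_tpm non-negative numeric vectors.
#' @return data.frame with `value` (log2 ratio, `NA` when undefined) and
#'   `status` ("finite" or "undefined_zero").
#' @export
log2_fold_change <- function(treatment_tpm, control_tpm) {
  if (any(treatment_tpm < 0) || any(control_tpm < 0))
    stop("log2_fold_change: TPM values must be non-negative")
  finite <- treatment_tpm > 0 & control_tpm > 0
  data.frame(value = ifelse(finite, log2(treatment_tpm / control_tpm), NA_real_),
             status = ifelse(finite, "finite", "undefined_zero"))
}

#' Build a fold-change table over a set of contrasts
#'
#' @param tpm TPM matrix (miRNAs x libraries).
#' @param contrasts named list: contrast -> `c(treatment, control)`
#'   library names.
#' @return numeric matrix (miRNAs x contrasts) of log2 fold changes,
#'   `NA` where undefined.
#' @export
fold_change_table <- function(tpm, contrasts) {
  out <- vapply(contrasts, function(tc) {
    log2_fold_change(tpm[, tc[1]], tpm[, tc[2]])$value
  }, numeric(nrow(tpm)))
  if (nrow(tpm) == 1L) out <- matrix(out, nrow = 1, dimnames = list(NULL, names(contrasts)))
  rownames(out) <- rownames(tpm)
  out
}

#' Select differentially expressed miRNAs (>= 2-fold by default)
#'
#' @param fold_table matrix from [fold_change_table()].
#' @param threshold log2 threshold; the default 1.0 is the study's
#'   ">= 2-fold" rule, boundary inclusive.
#' @return character vector of selected miRNA names.
#' @export
select_de <- function(fold_table, threshold = 1.0) {
  hit <- apply(fold_table, 1, function(v) any(abs(v) >= threshold, na.rm = TRUE))
  if (!any(hit) && all(is.na(fold_table)))
    warning("select_de: all fold changes undefined (zero TPM)")
  rownames(fold_table)[hit]
}

#' Venn partition of miRNA detection across library groups
#'
#' Each miRNA detected in at least one group is assigned to exactly one
#' region of the k-set Venn diagram (the subset of groups in which it is
#' detected). A group may be a single library or several libraries
#' (detection in any member counts).
#'
#' @param counts raw count matrix (miRNAs x libraries).
#' @param sets named list: set label -> character vector of library
#'   names belonging to that set (at most 6 sets).
#' @param threshold detection cut-off; a miRNA is detected when its
#'   count exceeds `threshold` (default 0, i.e. count > 0).
#' @return named integer vector over all 2^k - 1 regions; region names
#'   join set labels with "&".
#' @export
venn_partition <- function(counts, sets, threshold = 0) {
  k <- length(sets)
  if (k < 1 || k > 6) stop("venn_partition: between 1 and 6 sets supported")
  counts <- as.matrix(counts)
  det <- vapply(sets, function(libs) {
    rowSums(counts[, libs, drop = FALSE] > threshold) > 0
  }, logical(nrow(counts)))
  if (nrow(counts) == 1L)
    det <- matrix(det, nrow = 1, dimnames = list(NULL, names(sets)))
  labels <- names(sets)
  regions <- character(0)
  for (m in seq_len(2^k - 1)) {
    members <- labels[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
    regions <- c(regions, paste(members, collapse = "&"))
  }
  out <- stats::setNames(integer(length(regions)), regions)
  membership <- apply(det, 1, function(v) paste(labels[v], collapse = "&"))
  tab <- table(membership[membership != ""])
  out[names(tab)] <- as.integer(tab)
  out
}

#' Uncentered Pearson distance
#'
#' `d(x, y) = 1 - sum(x*y) / sqrt(sum(x^2) * sum(y^2))` -- the cosine
#' style correlation without mean-centering. Defined for any vector that
#' is not all zero.
#'
#' @param mat numeric matrix; distances are computed between rows.
#' @return a `dist` object.
#' @export
uncentered_pearson_dist <- function(mat) {
  mat <- as.matrix(mat)
  norms <- sqrt(rowSums(mat^2))
  zero <- which(norms == 0)
  if (length(zero)) {
    nm <- rownames(mat)[zero[1]]
    stop("uncentered_pearson_dist: all-zero profile",
         if (!is.null(nm)) paste0(" '", nm, "'") else paste0(" (row ", zero[1], ")"))
  }
  sim <- (mat %*% t(mat)) / (norms %o% norms)
  stats::as.dist(1 - sim)
}

#' Average-linkage clustering under uncentered Pearson distance
#'
#' Rows of `mat` are clustered by UPGMA (average linkage) on the
#' uncentered Pearson distance. Rows are ordered lexicographically by
#' label beforehand so distance ties resolve deterministically.
#'
#' @param mat numeric matrix with row names; at least 2 rows.
#' @return an [stats::hclust] object; render with [write_newick()].
#' @export
cluster_uncentered_average <- function(mat) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("cluster_uncentered_average: need at least 2 profiles")
  if (is.null(rownames(mat))) rownames(mat) <- paste0("row", seq_len(nrow(mat)))
  mat <- mat[order(rownames(mat)), , drop = FALSE]
  stats::hclust(uncentered_pearson_dist(mat), method = "average")
}
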