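# FPKM normalization of gene-level fragment-count matrices and the
# derived summaries: expressed-gene sets, Venn partitions, log2 matrices
# and classical MDS sample maps.

#' Read a count matrix with gene lengths
#'
#' TSV layout: `gene`, `length`, then one column per sample.
#'
#' @param path Path to the TSV.
#' @return List with `counts` (gene x sample integer matrix) and
#'   `lengths` (named vector, bp).
#' @export
read_counts <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("gene", "length") %in% names(tab)))
  samples <- setdiff(names(tab), c("gene", "length"))
  counts <- as.matrix(tab[, samples, drop = FALSE])
  rownames(counts) <- tab$gene
  storage.mode(counts) <- "integer"
  list(counts = counts, lengths = setNames(tab$length, tab$gene))
}

#' FPKM normalization
#'
#' `FPKM[g,s] = counts[g,s] * 1e9 / (length[g] * total[s])` with
#' `total[s]` the column sum of fragment counts.
#'
#' @param counts Gene x sample matrix of non-negative fragment counts.
#' @param lengths Named vector of gene lengths (bp), covering all genes.
#' @return Gene x sample FPKM matrix.
#' @export
fpkm <- function(counts, lengths) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  lengths <- lengths[rownames(counts)]
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    stop("every gene needs a positive length")
  }
  totals <- colSums(counts)
  zero <- names(totals)[totals == 0]
  if (length(zero)) {
    stop("zero total counts in sample(s): ", paste(zero, collapse = ", "))
  }
  sweep(counts * 1e9 / lengths, 2L, totals, "/")
}

#' Expressed-gene sets, Venn partitions and proportions
#'
#' A gene is expressed in a sample when its FPKM exceeds `threshold`
#' (strictly; the default 0 gives detected/not-detected semantics).
#' Proportions are percentages of `annotated_total`, rounded half-up to
#' integers.
#'
#' @param f FPKM matrix (genes x samples).
#' @param annotated_total Number of annotated genes the percentages refer
#'   to.
#' @param threshold FPKM threshold (default 0).
#' @param subset Optional gene-id vector restricting the report (e.g. the
#'   family members).
#' @return List: `expressed` (named list of gene-id vectors per sample),
#'   `n_expressed`, `proportion_pct` (integer percents), `venn` (named
#'   partition counts, keys like `"s1&s3"`), `common` (genes expressed in
#'   every sample).
#' @export
expressed_sets <- function(f, annotated_total, threshold = 0,
                           subset = NULL) {
  stopifnot(threshold >= 0)
  if (annotated_total <= 0) stop("annotated_total must be positive")
  if (!is.null(subset)) f <- f[rownames(f) %in% subset, , drop = FALSE]
  samples <- colnames(f)
  expressed <- lapply(samples, function(s) rownames(f)[f[, s] > threshold])
  names(expressed) <- samples
  n_expressed <- vapply(expressed, length, integer(1))
  membership <- vapply(expressed, function(g) rownames(f) %in% g,
                       logical(nrow(f)))
  if (nrow(f) == 1L) membership <- matrix(membership, nrow = 1L,
                                          dimnames = list(rownames(f), samples))
  in_any <- rowSums(membership) > 0
  venn <- integer(0)
  k <- length(samples)
  for (m in seq_len(2^k - 1L)) {
    sel <- as.logical(bitwAnd(m, 2^(seq_len(k) - 1L)))
    key <- paste(samples[sel], collapse = "&")
    region <- rowSums(membership[, sel, drop = FALSE]) == sum(sel) &
      rowSums(membership[, !sel, drop = FALSE]) == 0
    venn[key] <- sum(region)
  }
  list(
    expressed = expressed,
    n_expressed = n_expressed,
    proportion_pct = round_half_up(n_expressed / annotated_total * 100),
    venn = venn,
    n_union = sum(in_any),
    common = rownames(f)[rowSums(membership) == k]
  )
}

#' log2(FPKM + 1) matrix
#'
#' @param f FPKM matrix.
#' @return Matrix of the same shape.
#' @export
log_matrix <- function(f) log2(f + 1)

#' Classical (Torgerson) MDS of samples
#'
#' Euclidean distances between the samples' `log2(FPKM + 1)` profiles,
#' restricted to the `top_n` most variable genes, embedded with
#' [stats::cmdscale()]. The sign of each axis is fixed so the first
#' sample's coordinate is non-negative.
#'
#' @param f FPKM matrix (genes x samples).
#' @param k Number of dimensions (`< ncol(f)`).
#' @param top_n Number of most-variable genes used (default 500).
#' @return Sample x k coordinate matrix (centered at the origin).
#' @export
classical_mds <- function(f, k = 2L, top_n = 500L) {
  n <- ncol(f)
  if (n < 2L) stop("need at least two samples")
  if (k >= n) stop("k must be smaller than the number of samples")
  lf <- log_matrix(f)
  v <- apply(lf, 1L, var)
  keep <- order(v, decreasing = TRUE)[seq_len(min(top_n, nrow(lf)))]
  d <- dist(t(lf[keep, , drop = FALSE]))
  # cmdscale warns when null axes are dropped; the padding below handles it
  coords <- suppressWarnings(cmdscale(d, k = k))
  if (is.null(dim(coords)) || ncol(coords) < k) {
    # degenerate (e.g. identical samples): cmdscale drops null axes
    full <- matrix(0, n, k, dimnames = list(colnames(f), NULL))
    if (!is.null(dim(coords)) && ncol(coords) > 0) {
      full[, seq_len(ncol(coords))] <- coords
    }
    coords <- full
  }
  for (j in seq_len(ncol(coords))) {
    if (coords[1L, j] < 0) coords[, j] <- -coords[, j]
  }
  rownames(coords) <- colnames(f)
  coords
}
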