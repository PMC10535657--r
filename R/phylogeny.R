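# Protein distance matrices, UPGMA clustering and Newick serialization.

#' Protein distance matrix from a multiple alignment
#'
#' p-distance = mismatches / compared columns with pairwise deletion of
#' gap columns; the Poisson distance is `-ln(1 - p)`.
#'
#' @param seqs Named character vector of equal-length aligned protein
#'   sequences (gaps as `-`).
#' @param model `"p"` or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
protein_distance <- function(seqs, model = c("p", "poisson")) {
  model <- match.arg(model)
  stopifnot(length(seqs) >= 2L)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1L) stop("aligned sequences must have equal length")
  n <- length(seqs)
  chars <- lapply(seqs, seq_chars)
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- chars[[i]]; b <- chars[[j]]
      use <- a != "-" & b != "-"
      if (!any(use)) {
        stop("no comparable columns between ", names(seqs)[i], " and ",
             names(seqs)[j])
      }
      p <- sum(a[use] != b[use]) / sum(use)
      val <- if (model == "p") p else {
        if (p >= 1) stop("Poisson distance undefined at p >= 1") else -log(1 - p)
      }
      d[i, j] <- d[j, i] <- val
    }
  }
  d
}

#' Protein distance matrix from pairwise global alignments
#'
#' Alignment-free input variant: every pair is globally aligned
#' (Needleman-Wunsch, BLOSUM62) and the p-distance computed over its
#' residue-residue columns. Used to seed reference co-clustering when no
#' multiple alignment is supplied.
#'
#' @param seqs Named character vector of unaligned protein sequences.
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
pairwise_protein_distance <- function(seqs) {
  stopifnot(length(seqs) >= 2L)
  n <- length(seqs)
  submat <- get_submat("BLOSUM62")
  d <- matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(seqs[[i]]), Biostrings::AAString(seqs[[j]]),
        type = "global", substitutionMatrix = submat,
        gapOpening = 10, gapExtension = 0.5)
      a <- seq_chars(as.character(Biostrings::alignedPattern(aln)))
      b <- seq_chars(as.character(Biostrings::alignedSubject(aln)))
      use <- a != "-" & b != "-"
      d[i, j] <- d[j, i] <- sum(a[use] != b[use]) / max(sum(use), 1L)
    }
  }
  d
}

#' UPGMA clustering of a distance matrix
#'
#' Iteratively merges the closest pair of clusters; the new cluster's
#' distances are size-weighted averages and its height is half the merge
#' distance, so the tree is ultrametric. Ties are broken by the
#' lexicographically smallest pair of cluster representative labels, which
#' makes the output invariant to input order.
#'
#' @param d Symmetric distance matrix with labeled rows/columns.
#' @return An [ape::read.tree()] `phylo` object with branch lengths.
#' @export
upgma <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2L)
  if (any(!is.finite(d))) stop("distance matrix must be finite")
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix must be symmetric")
  labels <- rownames(d)
  stopifnot(!is.null(labels), !anyDuplicated(labels))
  active <- seq_along(labels)
  newick <- quote_newick(labels)
  height <- rep(0, length(labels))
  size <- rep(1L, length(labels))
  rep_label <- labels  # smallest member label, for tie-breaking
  D <- d
  while (length(active) > 1L) {
    best <- NULL; best_val <- Inf; best_key <- NULL
    for (ii in seq_along(active)[-length(active)]) {
      for (jj in (ii + 1L):length(active)) {
        i <- active[ii]; j <- active[jj]
        val <- D[i, j]
        key <- paste(sort(c(rep_label[i], rep_label[j])), collapse = "\r")
        if (val < best_val - 1e-15 ||
            (abs(val - best_val) <= 1e-15 && !is.null(best_key) && key < best_key)) {
          best_val <- val; best <- c(i, j); best_key <- key
        }
      }
    }
    i <- best[1L]; j <- best[2L]
    if (rep_label[j] < rep_label[i]) { tmp <- i; i <- j; j <- tmp }
    h <- best_val / 2
    nid <- length(height) + 1L
    newick[nid] <- sprintf("(%s:%s,%s:%s)",
                           newick[i], format(h - height[i], digits = 15),
                           newick[j], format(h - height[j], digits = 15))
    height[nid] <- h
    size[nid] <- size[i] + size[j]
    rep_label[nid] <- min(rep_label[i], rep_label[j])
    # size-weighted average linkage to every other active cluster
    D <- rbind(cbind(D, 0), 0)
    for (k in setdiff(active, c(i, j))) {
      D[nid, k] <- D[k, nid] <-
        (size[i] * D[i, k] + size[j] * D[j, k]) / (size[i] + size[j])
    }
    active <- c(setdiff(active, c(i, j)), nid)
  }
  tree <- ape::read.tree(text = paste0(newick[active], ";"))
  tree
}

quote_newick <- function(labels) {
  needs <- grepl("[ ()\\[\\]:;,']", labels)
  out <- labels
  out[needs] <- paste0("'", gsub("'", "''", labels[needs]), "'")
  out
}

#' Serialize a tree as Newick
#'
#' @param tree An ape `phylo` object.
#' @param path Optional output path; when `NULL` the string is returned.
#' @return Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(path)) {
    writeLines(s, path)
    return(invisible(s))
  }
  s
}

#' Read a Newick tree
#'
#' @param x Newick string or path to a Newick file.
#' @return An ape `phylo` object.
#' @export
read_newick <- function(x) {
  if (file.exists(x)) ape::read.tree(x) else ape::read.tree(text = x)
}
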