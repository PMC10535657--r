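# Promoter cis-regulatory element scanning against an extensible IUPAC
# motif table, with roll-up into five functional categories.

CIS_CATEGORIES <- c("light", "hormone", "development", "environment",
                    "promoter/binding", "unknown")

#' Load a cis-element motif table
#'
#' The table is a TSV with columns `name`, `pattern` (IUPAC nucleotide
#' consensus, length >= 4) and `category` (one of light, hormone,
#' development, environment, promoter/binding, unknown). A curated table of
#' literature consensus motifs is bundled with the package.
#'
#' @param path Path to a motif TSV; default the bundled table.
#' @return Data frame of motif definitions.
#' @export
load_motifs <- function(path = system.file("extdata", "cis_motifs.tsv",
                                           package = "wrkyscan")) {
  m <- read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  stopifnot(all(c("name", "pattern", "category") %in% names(m)))
  m$pattern <- toupper(m$pattern)
  for (i in seq_len(nrow(m))) {
    bad <- setdiff(seq_chars(m$pattern[i]), names(IUPAC_NT))
    if (length(bad)) {
      stop("motif ", m$name[i], ": malformed IUPAC symbol(s): ",
           paste(bad, collapse = ", "))
    }
    if (nchar(m$pattern[i]) < 4L) {
      stop("motif ", m$name[i], ": pattern shorter than 4 nt")
    }
  }
  bad_cat <- setdiff(unique(m$category), CIS_CATEGORIES)
  if (length(bad_cat)) {
    stop("unknown motif category: ", paste(bad_cat, collapse = ", "))
  }
  m
}

# All matches of one IUPAC pattern on one strand of one promoter;
# ambiguities in the pattern are interpreted, subject letters are literal.
match_iupac <- function(pattern, subject) {
  if (nchar(subject) < nchar(pattern)) return(integer(0))
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(pattern), Biostrings::DNAString(subject),
    fixed = "subject"
  )
  BiocGenerics::start(hits)
}

#' Scan promoters for cis-element motifs
#'
#' Every position on both strands where the IUPAC consensus matches is
#' reported (overlaps allowed, no merging). Minus-strand hits are reported
#' at the start of the reverse-complement match in promoter coordinates.
#'
#' @param promoters Named character vector of promoter sequences.
#' @param motifs Motif table from [load_motifs()].
#' @param both_strands Scan the reverse strand too (default `TRUE`).
#' @return Data frame `promoter_id`, `motif_name`, `position` (1-based),
#'   `strand`, ordered by (promoter, position, strand, motif).
#' @export
scan_motifs <- function(promoters, motifs, both_strands = TRUE) {
  rows <- list()
  for (pid in names(promoters)) {
    subj <- toupper(promoters[[pid]])
    if (nchar(subj) == 0L) next
    for (i in seq_len(nrow(motifs))) {
      pat <- motifs$pattern[i]
      fwd <- match_iupac(pat, subj)
      if (length(fwd)) {
        rows[[length(rows) + 1L]] <- data.frame(
          promoter_id = pid, motif_name = motifs$name[i],
          position = fwd, strand = "+", stringsAsFactors = FALSE)
      }
      if (both_strands) {
        rev_hits <- match_iupac(revcomp(pat), subj)
        if (length(rev_hits)) {
          rows[[length(rows) + 1L]] <- data.frame(
            promoter_id = pid, motif_name = motifs$name[i],
            position = rev_hits, strand = "-", stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(promoter_id = character(0), motif_name = character(0),
                      position = integer(0), strand = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$promoter_id, out$position, out$strand, out$motif_name), ]
  rownames(out) <- NULL
  out
}

#' Summarize motif hits into category counts and percentages
#'
#' @param hits Output of [scan_motifs()].
#' @param motifs Motif table from [load_motifs()].
#' @param n_promoters Number of promoters scanned (for the W-box gene
#'   tally); defaults to the promoters present in `hits`.
#' @return List with `motif_counts`, `category_counts`,
#'   `category_percent` (over total hits; all zero with `no_hits = TRUE`
#'   when there are none), `n_genes_with_wbox`, `n_hits`.
#' @export
summarize_categories <- function(hits, motifs, n_promoters = NULL) {
  cat_of <- setNames(motifs$category, motifs$name)
  motif_counts <- table(factor(hits$motif_name, levels = motifs$name))
  cat_counts <- vapply(CIS_CATEGORIES, function(cc) {
    sum(motif_counts[names(cat_of)[cat_of == cc]])
  }, numeric(1))
  n_hits <- nrow(hits)
  pct <- if (n_hits > 0) cat_counts / n_hits * 100 else cat_counts * 0
  wbox_genes <- unique(hits$promoter_id[hits$motif_name == "W-box"])
  list(
    motif_counts = as.integer(motif_counts) |> setNames(motifs$name),
    category_counts = cat_counts,
    category_percent = pct,
    no_hits = n_hits == 0L,
    n_hits = n_hits,
    n_genes_with_wbox = length(wbox_genes)
  )
}

#' Write motif hits as BED-like TSV
#'
#' Columns: promoter id, 0-based start, 0-based-exclusive end, motif name,
#' `.`, strand.
#'
#' @param hits Output of [scan_motifs()].
#' @param motifs Motif table (for pattern lengths).
#' @param path Output path.
#' @export
write_hits_bed <- function(hits, motifs, path) {
  len_of <- setNames(nchar(motifs$pattern), motifs$name)
  bed <- data.frame(
    chrom = hits$promoter_id,
    start = hits$position - 1L,
    end = hits$position - 1L + len_of[hits$motif_name],
    name = hits$motif_name,
    score = ".",
    strand = hits$strand
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
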