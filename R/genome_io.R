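# Genome/annotation I/O and strand-aware subsequence extraction.
#
# Coordinates follow the GFF3 convention throughout: 1-based, inclusive.
# Sequences are plain named character vectors (uppercase); Biostrings does
# the FASTA parsing and rtracklayer the GFF3 parsing.

#' Read a (multi-)FASTA file of nucleotide sequences
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one uppercase sequence per record.
#'   Record ids are the first whitespace-delimited token of each header.
#' @details Duplicate record ids and empty records are errors.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  dup <- ids[duplicated(ids)]
  if (length(dup)) {
    stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  }
  seqs <- toupper(as.character(ss))
  if (any(nchar(seqs) == 0L)) {
    stop("empty FASTA record(s): ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  }
  names(seqs) <- ids
  seqs
}

#' Write named sequences as wrapped FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param width Line wrap width.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(!is.null(names(seqs)) || length(seqs) == 0L)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, max(nchar(s), 1L), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Construct a gene model
#'
#' A located, stranded gene with its CDS segments on one contig.
#'
#' @param gene_id Gene identifier.
#' @param contig Contig/chromosome id.
#' @param start,end 1-based inclusive gene span.
#' @param strand `"+"` or `"-"`.
#' @param cds Two-column matrix of 1-based inclusive (start, end) CDS
#'   segments, in genomic coordinate order.
#' @return Object of class `gene_model`.
#' @export
gene_model <- function(gene_id, contig, start, end, strand, cds) {
  stopifnot(length(gene_id) == 1L, length(contig) == 1L)
  start <- as.integer(start); end <- as.integer(end)
  if (!strand %in% c("+", "-")) stop("unknown strand symbol: ", strand)
  if (start > end) stop(gene_id, ": start > end")
  cds <- matrix(as.integer(cds), ncol = 2L,
                dimnames = list(NULL, c("start", "end")))
  if (nrow(cds) == 0L) stop(gene_id, ": gene model needs >= 1 CDS segment")
  cds <- cds[order(cds[, 1L]), , drop = FALSE]
  if (any(cds[, 1L] > cds[, 2L])) stop(gene_id, ": CDS segment start > end")
  if (any(cds[, 1L] < start) || any(cds[, 2L] > end)) {
    stop(gene_id, ": CDS segment outside gene span")
  }
  if (nrow(cds) > 1L && any(cds[-1L, 1L] <= cds[-nrow(cds), 2L])) {
    stop(gene_id, ": overlapping CDS segments")
  }
  structure(
    list(gene_id = gene_id, contig = contig, start = start, end = end,
         strand = strand, cds = cds),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s %s:%d-%d(%s), %d CDS segment(s)\n",
              x$gene_id, x$contig, x$start, x$end, x$strand, nrow(x$cds)))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Parses gene/mRNA/CDS features and groups CDS segments under their parent
#' gene. Coordinates are preserved exactly (1-based inclusive).
#'
#' @param path Path to a GFF3 file.
#' @param contig_lengths Optional named integer vector (or a genome as
#'   returned by [read_fasta()]); when supplied, CDS features outside the
#'   declared contig bounds are an error.
#' @return Named list of [gene_model()] objects.
#' @export
read_gff3 <- function(path, contig_lengths = NULL) {
  stopifnot(file.exists(path))
  gr <- rtracklayer::import(path, format = "gff3")
  if (!is.null(contig_lengths) && is.character(contig_lengths)) {
    contig_lengths <- setNames(nchar(contig_lengths), names(contig_lengths))
  }
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- as.character(md$ID)
  parent <- vapply(md$Parent, function(p) if (length(p)) p[[1]] else NA_character_,
                   character(1))

  # map any feature id up to its ancestral gene id
  gene_idx <- which(type == "gene")
  gene_of <- setNames(ids[gene_idx], ids[gene_idx])
  mrna_idx <- which(type %in% c("mRNA", "transcript"))
  gene_of[ids[mrna_idx]] <- parent[mrna_idx]

  out <- list()
  for (gi in gene_idx) {
    gid <- ids[gi]
    contig <- as.character(GenomicRanges::seqnames(gr))[gi]
    strand <- as.character(BiocGenerics::strand(gr))[gi]
    if (!strand %in% c("+", "-")) stop(gid, ": unknown strand symbol: ", strand)
    cds_idx <- which(type == "CDS" &
                       !is.na(parent) &
                       (parent == gid | gene_of[parent] %in% gid))
    if (!length(cds_idx)) next
    cds <- cbind(BiocGenerics::start(gr)[cds_idx], BiocGenerics::end(gr)[cds_idx])
    if (!is.null(contig_lengths)) {
      if (!contig %in% names(contig_lengths)) {
        stop(gid, ": contig ", contig, " not in declared contigs")
      }
      if (any(cds < 1L) || any(cds[, 2L] > contig_lengths[[contig]])) {
        stop(gid, ": CDS outside bounds of contig ", contig,
             " (length ", contig_lengths[[contig]], ")")
      }
    }
    out[[gid]] <- gene_model(
      gene_id = gid, contig = contig,
      start = BiocGenerics::start(gr)[gi], end = BiocGenerics::end(gr)[gi],
      strand = strand, cds = cds
    )
  }
  out
}

#' Write gene models as GFF3
#'
#' @param genes List of [gene_model()] objects.
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (g in genes) {
    writeLines(sprintf("%s\twrkyscan\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                       g$contig, g$start, g$end, g$strand, g$gene_id), con)
    mrna <- paste0(g$gene_id, ".t1")
    writeLines(sprintf("%s\twrkyscan\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
                       g$contig, g$start, g$end, g$strand, mrna, g$gene_id), con)
    for (i in seq_len(nrow(g$cds))) {
      writeLines(sprintf("%s\twrkyscan\tCDS\t%d\t%d\t.\t%s\t0\tID=%s.cds;Parent=%s",
                         g$contig, g$cds[i, 1L], g$cds[i, 2L], g$strand,
                         mrna, mrna), con)
    }
  }
  invisible(path)
}

#' Extract the spliced CDS of a gene from the genome
#'
#' Segments are concatenated in genomic order; for minus-strand genes the
#' concatenation is reverse-complemented, yielding the coding strand in
#' transcription order.
#'
#' @param genome Named character vector of contig sequences.
#' @param gene A [gene_model()].
#' @return CDS nucleotide string.
#' @export
extract_cds <- function(genome, gene) {
  if (!gene$contig %in% names(genome)) {
    stop(gene$gene_id, ": contig ", gene$contig, " missing from genome")
  }
  contig <- genome[[gene$contig]]
  if (any(gene$cds[, 2L] > nchar(contig))) {
    stop(gene$gene_id, ": CDS outside bounds of contig ", gene$contig)
  }
  pieces <- substring(contig, gene$cds[, 1L], gene$cds[, 2L])
  s <- paste(pieces, collapse = "")
  if (gene$strand == "-") s <- revcomp(s)
  s
}

#' Translate a CDS with the standard genetic code
#'
#' A single terminal stop codon is removed; an internal stop is an error.
#' Codons containing ambiguity codes that do not resolve to one amino acid
#' translate to `"X"`.
#'
#' @param cds Nucleotide string, length divisible by 3.
#' @return Protein string.
#' @export
translate_cds <- function(cds) {
  cds <- toupper(cds)
  n <- nchar(cds)
  if (n == 0L) stop("empty CDS")
  if (n %% 3L != 0L) stop("CDS length ", n, " not divisible by 3")
  starts <- seq(1L, n, by = 3L)
  codons <- substring(cds, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # ambiguous codon
  n_codon <- length(aa)
  if (aa[n_codon] == "*") {
    aa <- aa[-n_codon]
    n_codon <- n_codon - 1L
  }
  internal_stop <- which(aa == "*")
  if (length(internal_stop)) {
    stop("internal stop codon at codon position ", internal_stop[1L])
  }
  paste(aa, collapse = "")
}

#' Extract the promoter region upstream of a gene's start codon
#'
#' For plus-strand genes, the `upstream_length` bases immediately 5' of the
#' first CDS base; for minus-strand genes, the bases immediately 3' (in
#' genome coordinates) of the last CDS base, reverse-complemented. The
#' window is truncated (never padded) at contig edges and the truncation is
#' flagged via the `"truncated"` attribute.
#'
#' @param genome Named character vector of contig sequences.
#' @param gene A [gene_model()].
#' @param upstream_length Window size in bp (default 2000).
#' @return Promoter string with attribute `truncated` (logical).
#' @export
extract_promoter <- function(genome, gene, upstream_length = 2000L) {
  stopifnot(upstream_length > 0L)
  if (!gene$contig %in% names(genome)) {
    stop(gene$gene_id, ": contig ", gene$contig, " missing from genome")
  }
  contig <- genome[[gene$contig]]
  clen <- nchar(contig)
  if (gene$strand == "+") {
    anchor <- gene$cds[1L, 1L]          # first CDS base
    from <- anchor - upstream_length
    to <- anchor - 1L
    truncated <- from < 1L
    from <- max(from, 1L)
    s <- if (to < from) "" else substring(contig, from, to)
  } else {
    anchor <- gene$cds[nrow(gene$cds), 2L]  # last CDS base in genome coords
    from <- anchor + 1L
    to <- anchor + upstream_length
    truncated <- to > clen
    to <- min(to, clen)
    s <- if (to < from) "" else revcomp(substring(contig, from, to))
  }
  if (nchar(s) == 0L) {
    warning(gene$gene_id, ": start codon at contig edge, empty promoter")
  }
  attr(s, "truncated") <- truncated
  s
}

#' Extract promoters for a set of genes and write them as FASTA
#'
#' Headers follow `<gene_id>|promoter|<length>|truncated=<bool>`.
#'
#' @param genome Named character vector of contig sequences.
#' @param genes List of [gene_model()] objects.
#' @param path Optional output FASTA path.
#' @param upstream_length Window size in bp.
#' @return Named character vector of promoters (names are gene ids);
#'   truncation flags in attribute `"truncated"`.
#' @export
extract_promoters <- function(genome, genes, path = NULL,
                              upstream_length = 2000L) {
  proms <- character(0); trunc <- logical(0)
  for (g in genes) {
    p <- extract_promoter(genome, g, upstream_length)
    proms[g$gene_id] <- as.character(p)
    trunc[g$gene_id] <- attr(p, "truncated")
  }
  if (!is.null(path)) {
    hdr <- sprintf("%s|promoter|%d|truncated=%s",
                   names(proms), nchar(proms), tolower(as.character(trunc)))
    write_fasta(setNames(proms, hdr), path)
  }
  attr(proms, "truncated") <- trunc
  proms
}
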