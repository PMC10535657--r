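# Pairwise protein similarity by Smith-Waterman local alignment and
# tandem/segmental duplication classification.
#
# Percent similarity over a *local* alignment is meaningless when the
# alignment is only a handful of columns (any two family members share
# the exact heptapeptide), so duplication calls additionally require a
# minimum alignment length (default 30 aa, about half a WRKY domain).

#' Duplication-detection configuration
#'
#' Defaults mirror EMBOSS Water (BLOSUM62, gap open 10, gap extend 0.5)
#' and the usual gene-family survey criteria: tandem = same chromosome
#' within 100 kb at >= 70 % similarity; pairs above 98 % similarity are
#' flagged as recent duplicates.
#'
#' @param tandem_window Max gap between gene spans for a tandem call (bp).
#' @param similarity_threshold Minimum percent similarity for any call.
#' @param recent_threshold Percent similarity above which a pair is
#'   flagged recent.
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param matrix Substitution matrix name (any matrix shipped with
#'   Biostrings, e.g. `"BLOSUM62"`).
#' @param min_alignment_length Minimum local-alignment columns for a
#'   duplication call.
#' @return Config list.
#' @export
duplication_config <- function(tandem_window = 100000L,
                               similarity_threshold = 70,
                               recent_threshold = 98,
                               gap_open = 10, gap_extend = 0.5,
                               matrix = "BLOSUM62",
                               min_alignment_length = 30L) {
  stopifnot(similarity_threshold > 0,
            similarity_threshold < recent_threshold,
            recent_threshold <= 100)
  list(tandem_window = tandem_window,
       similarity_threshold = similarity_threshold,
       recent_threshold = recent_threshold,
       gap_open = gap_open, gap_extend = gap_extend, matrix = matrix,
       min_alignment_length = min_alignment_length)
}

get_submat <- function(name) {
  e <- new.env()
  utils::data(list = name, package = "Biostrings", envir = e)
  get(name, envir = e)
}

#' Smith-Waterman local alignment of two proteins
#'
#' Optimal local alignment under affine gap penalties. Identity is the
#' percentage of identical pairs over alignment columns (gap columns
#' included); similarity the percentage of positively scoring residue
#' pairs.
#'
#' @param a,b Protein strings.
#' @param cfg A [duplication_config()].
#' @return List: `score`, `aligned_length`, `identity_pct`,
#'   `similarity_pct`, `aligned_a`, `aligned_b`, `start_a`, `end_a`,
#'   `start_b`, `end_b`. A pair with no positively scoring residue pair
#'   yields the empty alignment (score 0).
#' @export
smith_waterman <- function(a, b, cfg = duplication_config()) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  submat <- get_submat(cfg$matrix)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(toupper(a)), Biostrings::AAString(toupper(b)),
    type = "local", substitutionMatrix = submat,
    gapOpening = cfg$gap_open, gapExtension = cfg$gap_extend
  )
  score <- Biostrings::score(aln)
  if (score <= 0) {
    return(list(score = 0, aligned_length = 0L, identity_pct = 0,
                similarity_pct = 0, aligned_a = "", aligned_b = "",
                start_a = NA_integer_, end_a = NA_integer_,
                start_b = NA_integer_, end_b = NA_integer_))
  }
  pa <- as.character(Biostrings::alignedPattern(aln))
  pb <- as.character(Biostrings::alignedSubject(aln))
  ca <- seq_chars(pa); cb <- seq_chars(pb)
  cols <- length(ca)
  res <- ca != "-" & cb != "-"
  ident <- sum(ca == cb & res)
  pair_scores <- submat[cbind(match(ca[res], rownames(submat)),
                              match(cb[res], colnames(submat)))]
  positive <- sum(pair_scores > 0)
  list(
    score = score,
    aligned_length = cols,
    identity_pct = ident / cols * 100,
    similarity_pct = positive / cols * 100,
    aligned_a = pa, aligned_b = pb,
    start_a = BiocGenerics::start(aln@pattern@range),
    end_a = BiocGenerics::end(aln@pattern@range),
    start_b = BiocGenerics::start(aln@subject@range),
    end_b = BiocGenerics::end(aln@subject@range)
  )
}

#' Classify a gene pair as a tandem or segmental duplication
#'
#' A pair below the similarity threshold is not a duplication (`NULL`).
#' Otherwise: same contig with the gap between gene spans within
#' `tandem_window` (inclusive) -> tandem; anything else -> segmental.
#' Pairs above `recent_threshold` similarity are flagged recent.
#'
#' @param gene_a,gene_b [gene_model()] objects.
#' @param aln Result of [smith_waterman()] on the pair's proteins.
#' @param cfg A [duplication_config()].
#' @return One-row data frame (`gene_a`, `gene_b`, `type`,
#'   `similarity_pct`, `genomic_distance`, `recent`) or `NULL`.
#' @export
classify_duplication <- function(gene_a, gene_b, aln,
                                 cfg = duplication_config()) {
  if (aln$similarity_pct < cfg$similarity_threshold) return(NULL)
  if (aln$aligned_length < (cfg$min_alignment_length %||% 0L)) return(NULL)
  same_contig <- gene_a$contig == gene_b$contig
  dist <- NA_integer_
  if (same_contig) {
    # gap between gene spans; overlapping spans count as distance 0
    dist <- max(0L, max(gene_a$start, gene_b$start) -
                  min(gene_a$end, gene_b$end))
  }
  type <- if (same_contig && dist <= cfg$tandem_window) "tandem" else "segmental"
  data.frame(
    gene_a = gene_a$gene_id, gene_b = gene_b$gene_id, type = type,
    similarity_pct = aln$similarity_pct, genomic_distance = dist,
    recent = aln$similarity_pct > cfg$recent_threshold,
    stringsAsFactors = FALSE
  )
}

#' Find duplicated gene pairs in a gene set
#'
#' All-vs-all Smith-Waterman on the proteins, then classification of every
#' pair meeting the similarity threshold.
#'
#' @param genes Named list of [gene_model()] objects.
#' @param proteins Named character vector of protein sequences (names
#'   matching gene ids).
#' @param cfg A [duplication_config()].
#' @return Data frame of duplication events (possibly 0 rows).
#' @export
find_duplications <- function(genes, proteins, cfg = duplication_config()) {
  ids <- intersect(names(genes), names(proteins))
  out <- list()
  if (length(ids) >= 2L) {
    pairs <- combn(ids, 2L)
    for (k in seq_len(ncol(pairs))) {
      ia <- pairs[1L, k]; ib <- pairs[2L, k]
      aln <- smith_waterman(proteins[[ia]], proteins[[ib]], cfg)
      ev <- classify_duplication(genes[[ia]], genes[[ib]], aln, cfg)
      if (!is.null(ev)) out[[length(out) + 1L]] <- ev
    }
  }
  if (!length(out)) {
    return(data.frame(gene_a = character(0), gene_b = character(0),
                      type = character(0), similarity_pct = numeric(0),
                      genomic_distance = integer(0), recent = logical(0),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Summarize duplication ages per type
#'
#' Undefined (`NaN`/`NA`) divergence times are excluded everywhere; zero
#' times are additionally excluded from the mean (a zero-time pair carries
#' no dating information, only the statement that the copies are
#' identical), but enter the range.
#'
#' @param events Data frame with columns `type` and `time_mya`.
#' @return Data frame per type: `n`, `mean_mya`, `min_mya`, `max_mya`
#'   (`NaN` mean when no defined nonzero time exists).
#' @export
summarize_ages <- function(events) {
  types <- unique(events$type)
  rows <- lapply(types, function(tt) {
    t_all <- events$time_mya[events$type == tt]
    t_def <- t_all[is.finite(t_all)]
    t_mean <- t_def[t_def > 0]
    data.frame(
      type = tt,
      n = length(t_mean),
      mean_mya = if (length(t_mean)) mean(t_mean) else NaN,
      min_mya = if (length(t_def)) min(t_def) else NaN,
      max_mya = if (length(t_def)) max(t_def) else NaN,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
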