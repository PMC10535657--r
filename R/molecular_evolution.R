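# Nei-Gojobori (1986) Ka/Ks estimation on codon alignments, selection
# classification and divergence-time dating.
#
# Pure NG86: synonymous site fractions from the standard code with equal
# mutation weights, multi-hit codons averaged over all orderings of the
# changes with equal pathway weights (pathways through stop codons
# excluded), proportions corrected with the Jukes-Cantor formula.

NT4 <- c("A", "C", "G", "T")

codon_aa <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  if (is.na(aa)) NA_character_ else unname(aa)
}

# Synonymous site count of one codon: at each position, the fraction of
# the three single-base changes that preserve the amino acid (classical
# NG86 convention: changes to stop codons count as nonsynonymous
# opportunities). Each position contributes exactly one site, so
# S + N = 3 per codon.
codon_syn_sites <- function(codon) {
  chars <- seq_chars(codon)
  aa0 <- codon_aa(codon)
  s <- 0
  for (j in 1:3) {
    syn <- 0L
    for (b in setdiff(NT4, chars[j])) {
      alt <- chars; alt[j] <- b
      aa1 <- codon_aa(paste(alt, collapse = ""))
      if (aa1 != "*" && aa1 == aa0) syn <- syn + 1L
    }
    s <- s + syn / 3
  }
  s
}

# All permutations of a small integer vector (naive recursion; k <= 3).
perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
  }
  out
}

# Synonymous/nonsynonymous difference counts between two codons, averaged
# with equal weight over all mutational pathways; pathways visiting a stop
# codon are excluded (with a fall-back to all pathways when every ordering
# is blocked).
codon_diffs <- function(ca, cb) {
  a <- seq_chars(ca); b <- seq_chars(cb)
  pos <- which(a != b)
  k <- length(pos)
  if (k == 0L) return(c(sd = 0, nd = 0))
  paths <- perms(pos)
  tally <- function(skip_stops) {
    sd <- 0; nd <- 0; n_used <- 0L
    for (p in paths) {
      cur <- a
      steps <- numeric(0); ok <- TRUE
      s_sd <- 0; s_nd <- 0
      for (j in p) {
        prev_aa <- codon_aa(paste(cur, collapse = ""))
        cur[j] <- b[j]
        new_aa <- codon_aa(paste(cur, collapse = ""))
        if (skip_stops && new_aa == "*") { ok <- FALSE; break }
        if (new_aa == prev_aa) s_sd <- s_sd + 1 else s_nd <- s_nd + 1
      }
      if (ok) { sd <- sd + s_sd; nd <- nd + s_nd; n_used <- n_used + 1L }
    }
    if (n_used == 0L) return(NULL)
    c(sd = sd / n_used, nd = nd / n_used)
  }
  tally(TRUE) %||% tally(FALSE)
}

#' Build a codon alignment from two CDS and their protein alignment
#'
#' Maps every aligned residue pair of a protein alignment back to its
#' codon pair; gap columns are dropped, and a terminal stop codon on
#' either CDS is ignored.
#'
#' @param cds_a,cds_b Coding sequences (with or without terminal stop).
#' @param aln Protein alignment from [smith_waterman()] of the two
#'   translations.
#' @return List of class `codon_alignment`: `codons_a`, `codons_b`
#'   (parallel character vectors), `n_codons`.
#' @export
build_codon_alignment <- function(cds_a, cds_b, aln) {
  prot_a <- translate_cds(cds_a)
  prot_b <- translate_cds(cds_b)
  if (aln$aligned_length == 0L) {
    return(structure(list(codons_a = character(0), codons_b = character(0),
                          n_codons = 0L), class = "codon_alignment"))
  }
  ca <- seq_chars(aln$aligned_a); cb <- seq_chars(aln$aligned_b)
  ia <- aln$start_a - 1L; ib <- aln$start_b - 1L
  codons_a <- character(0); codons_b <- character(0)
  for (col in seq_along(ca)) {
    if (ca[col] != "-") ia <- ia + 1L
    if (cb[col] != "-") ib <- ib + 1L
    if (ca[col] == "-" || cb[col] == "-") next
    cod_a <- substring(cds_a, 3L * (ia - 1L) + 1L, 3L * ia)
    cod_b <- substring(cds_b, 3L * (ib - 1L) + 1L, 3L * ib)
    if (is.na(codon_aa(cod_a)) || codon_aa(cod_a) != substring(prot_a, ia, ia)) {
      stop("CDS/protein mismatch in sequence a at residue ", ia)
    }
    if (is.na(codon_aa(cod_b)) || codon_aa(cod_b) != substring(prot_b, ib, ib)) {
      stop("CDS/protein mismatch in sequence b at residue ", ib)
    }
    codons_a <- c(codons_a, cod_a)
    codons_b <- c(codons_b, cod_b)
  }
  structure(list(codons_a = codons_a, codons_b = codons_b,
                 n_codons = length(codons_a)), class = "codon_alignment")
}

# Jukes-Cantor multiple-hit correction; NaN where undefined (p >= 3/4).
jc_correct <- function(p) {
  arg <- 1 - 4 / 3 * p
  ifelse(is.finite(arg) & arg > 0, -3 / 4 * log(arg), NaN)
}

#' NG86 Ka/Ks estimation on a codon alignment
#'
#' @param aln A `codon_alignment` from [build_codon_alignment()] (or a
#'   list with `codons_a`/`codons_b`).
#' @return List: `counts` (`N`, `S`, `Nd`, `Sd`, `pn`, `ps`) and `ka`,
#'   `ks`, `ratio`, `selection`. Undefined intermediates propagate as
#'   `NaN` (e.g. saturation, identical sequences give `ks = 0` and ratio
#'   `NaN`).
#' @param neutral_tolerance Half-width of the neutral band on the ratio.
#' @export
ng86 <- function(aln, neutral_tolerance = 1e-9) {
  stopifnot(length(aln$codons_a) == length(aln$codons_b))
  n_codons <- length(aln$codons_a)
  if (n_codons < 1L) stop("empty codon alignment")
  S_a <- sum(vapply(aln$codons_a, codon_syn_sites, numeric(1)))
  S_b <- sum(vapply(aln$codons_b, codon_syn_sites, numeric(1)))
  S <- (S_a + S_b) / 2
  N <- 3 * n_codons - S
  diffs <- mapply(function(x, y) codon_diffs(x, y),
                  aln$codons_a, aln$codons_b)
  Sd <- sum(diffs["sd", ])
  Nd <- sum(diffs["nd", ])
  ps <- if (S > 0) Sd / S else NaN
  pn <- if (N > 0) Nd / N else NaN
  ks <- jc_correct(ps)
  ka <- jc_correct(pn)
  ratio <- if (is.finite(ka) && is.finite(ks) && ks > 0) ka / ks else NaN
  list(
    counts = list(N = N, S = S, Nd = Nd, Sd = Sd, pn = pn, ps = ps),
    ka = ka, ks = ks, ratio = ratio,
    selection = selection_class(ratio, neutral_tolerance)
  )
}

#' Selection class from a Ka/Ks ratio
#'
#' Ratio above 1 -> positive, below 1 -> negative (purifying), equal to 1
#' within `neutral_tolerance` -> neutral, `NaN` -> undefined.
#'
#' @param ratio Ka/Ks value.
#' @param neutral_tolerance Half-width of the neutral band.
#' @return One of `"positive"`, `"negative"`, `"neutral"`, `"undefined"`.
#' @export
selection_class <- function(ratio, neutral_tolerance = 1e-9) {
  if (!is.finite(ratio)) return("undefined")
  if (abs(ratio - 1) <= neutral_tolerance) return("neutral")
  if (ratio > 1) "positive" else "negative"
}

#' Molecular-evolution configuration
#'
#' The default dates divergence from Ks at a neutral substitution rate of
#' 6.1e-9 per site per year. The `"table2-compat"` preset instead dates
#' from Ka at 6.56e-9 per site per year, the internally consistent
#' calibration of published bilberry WRKY divergence times (which are
#' proportional to Ka, not Ks).
#'
#' @param rate_r Substitution rate per site per year.
#' @param time_numerator `"ks"` or `"ka"`.
#' @param neutral_tolerance Neutral band half-width for selection calls.
#' @param preset Optional `"table2-compat"`.
#' @return Config list.
#' @export
evolution_config <- function(rate_r = 6.1e-9,
                             time_numerator = c("ks", "ka"),
                             neutral_tolerance = 1e-9,
                             preset = NULL) {
  if (!is.null(preset)) {
    stopifnot(preset == "table2-compat")
    return(list(rate_r = 6.56e-9, time_numerator = "ka",
                neutral_tolerance = neutral_tolerance))
  }
  stopifnot(rate_r > 0)
  list(rate_r = rate_r, time_numerator = match.arg(time_numerator),
       neutral_tolerance = neutral_tolerance)
}

#' Divergence time from a substitution distance
#'
#' `T = k / (2 * rate_r) * 1e-6` million years ago.
#'
#' @param k Substitutions per site (Ks or Ka).
#' @param cfg An [evolution_config()].
#' @return Time in Mya (`NaN` for undefined `k`).
#' @export
divergence_time <- function(k, cfg = evolution_config()) {
  if (!is.finite(k)) return(NaN)
  stopifnot(k >= 0)
  k / (2 * cfg$rate_r) * 1e-6
}

#' Ka/Ks and divergence time for one CDS pair
#'
#' Aligns the translated proteins (Smith-Waterman), back-translates to a
#' codon alignment, runs NG86 and dates the divergence.
#'
#' @param cds_a,cds_b Coding sequences.
#' @param cfg An [evolution_config()].
#' @param aln_cfg A [duplication_config()] controlling the protein
#'   alignment.
#' @return One-row data frame: `ka`, `ks`, `ratio`, `selection`,
#'   `time_mya`, `n_codons`.
#' @export
kaks_pair <- function(cds_a, cds_b, cfg = evolution_config(),
                      aln_cfg = duplication_config()) {
  aln <- smith_waterman(translate_cds(cds_a), translate_cds(cds_b), aln_cfg)
  caln <- build_codon_alignment(cds_a, cds_b, aln)
  if (caln$n_codons == 0L) {
    return(data.frame(ka = NaN, ks = NaN, ratio = NaN,
                      selection = "undefined", time_mya = NaN, n_codons = 0L,
                      stringsAsFactors = FALSE))
  }
  res <- ng86(caln, cfg$neutral_tolerance)
  k <- if (cfg$time_numerator == "ks") res$ks else res$ka
  data.frame(ka = res$ka, ks = res$ks, ratio = res$ratio,
             selection = res$selection,
             time_mya = divergence_time(k, cfg),
             n_codons = caln$n_codons, stringsAsFactors = FALSE)
}
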