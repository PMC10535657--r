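# ProtParam-style physicochemical profiling: molecular weight, isoelectric
# point, GRAVY, instability index, and the CDS/protein length relation.

# Average (not monoisotopic) residue masses, Da.
AA_AVG_MASS <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS <- 18.01524

# Kyte-Doolittle hydropathy.
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

# pKa sets for the pI calculation. "bjellqvist" approximates the ExPASy
# ProtParam convention (with residue-specific terminal corrections);
# "emboss" is the EMBOSS iep table.
PKA_SETS <- list(
  bjellqvist = list(
    positive = c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98),
    negative = c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0),
    nterm_by_res = c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82,
                     V = 7.44, E = 7.7),
    cterm_by_res = c(D = 4.55, E = 4.75)
  ),
  emboss = list(
    positive = c(Nterm = 8.6, K = 10.8, R = 12.5, H = 6.5),
    negative = c(Cterm = 3.6, D = 3.9, E = 4.1, C = 8.5, Y = 10.1),
    nterm_by_res = c(),
    cterm_by_res = c()
  )
)

check_aa <- function(chars, context = "sequence") {
  bad <- setdiff(unique(chars), names(AA_AVG_MASS))
  if (length(bad)) {
    stop(context, ": unknown residue(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Protein molecular weight (average masses)
#'
#' Sum of average residue masses plus one water.
#'
#' @param seq Protein string (standard 20 amino acids).
#' @return Mass in Daltons.
#' @export
molecular_weight <- function(seq) {
  if (nchar(seq) == 0L) stop("empty protein sequence")
  chars <- seq_chars(toupper(seq))
  check_aa(chars)
  sum(AA_AVG_MASS[chars]) + WATER_MASS
}

# Net charge of a protein at a given pH (Henderson-Hasselbalch over the
# termini and D,E,C,Y,H,K,R side chains).
protein_charge <- function(seq, pH, pka_set = "bjellqvist") {
  pk <- PKA_SETS[[pka_set]]
  chars <- seq_chars(toupper(seq))
  counts <- table(chars)
  pos_pk <- pk$positive
  neg_pk <- pk$negative
  first <- chars[1L]; last <- chars[length(chars)]
  if (first %in% names(pk$nterm_by_res)) pos_pk[["Nterm"]] <- pk$nterm_by_res[[first]]
  if (last %in% names(pk$cterm_by_res)) neg_pk[["Cterm"]] <- pk$cterm_by_res[[last]]
  charge <- 1 / (1 + 10^(pH - pos_pk[["Nterm"]])) -
    1 / (1 + 10^(neg_pk[["Cterm"]] - pH))
  for (res in c("K", "R", "H")) {
    n <- if (res %in% names(counts)) counts[[res]] else 0
    charge <- charge + n / (1 + 10^(pH - pos_pk[[res]]))
  }
  for (res in c("D", "E", "C", "Y")) {
    n <- if (res %in% names(counts)) counts[[res]] else 0
    charge <- charge - n / (1 + 10^(neg_pk[[res]] - pH))
  }
  charge
}

#' Isoelectric point
#'
#' pH at which the net protein charge crosses zero, found by bisection on
#' \[0, 14\] to a tolerance of 0.001.
#'
#' @param seq Protein string.
#' @param pka_set `"bjellqvist"` (ProtParam-style, default) or `"emboss"`.
#' @return pI in pH units.
#' @export
isoelectric_point <- function(seq, pka_set = c("bjellqvist", "emboss")) {
  if (nchar(seq) == 0L) stop("empty protein sequence")
  pka_set <- match.arg(pka_set)
  check_aa(seq_chars(toupper(seq)))
  lo <- 0; hi <- 14
  while (hi - lo > 0.001) {
    mid <- (lo + hi) / 2
    if (protein_charge(seq, mid, pka_set) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' GRAVY: grand average of hydropathy
#'
#' Arithmetic mean of Kyte-Doolittle values over all residues.
#'
#' @param seq Protein string.
#' @return Dimensionless mean in \[-4.5, 4.5\].
#' @export
gravy <- function(seq) {
  if (nchar(seq) == 0L) stop("empty protein sequence")
  chars <- seq_chars(toupper(seq))
  check_aa(chars)
  mean(KYTE_DOOLITTLE[chars])
}

#' Instability index
#'
#' `II = (10/L) * sum` of the published dipeptide instability weights over
#' the `L - 1` dipeptides; a value above 40 conventionally labels the
#' protein unstable in vitro.
#'
#' @param seq Protein string (length >= 2 for a defined value; shorter
#'   sequences return 0 / stable with a warning).
#' @param threshold Stability threshold (default 40).
#' @return List with `value` and `stability` (`"stable"`/`"unstable"`).
#' @export
instability_index <- function(seq, threshold = 40) {
  chars <- seq_chars(toupper(seq))
  check_aa(chars)
  L <- length(chars)
  if (L < 2L) {
    warning("sequence shorter than 2 residues: instability index undefined, reported as 0")
    return(list(value = 0, stability = "stable"))
  }
  w <- sum(DIWV[cbind(chars[-L], chars[-1L])])
  value <- 10 / L * w
  list(value = value,
       stability = if (value > threshold) "unstable" else "stable")
}

#' Check the CDS/protein coding-length relation
#'
#' A CDS that includes its stop codon satisfies
#' `cds_length_nt == 3 * (length_aa + 1)`.
#'
#' @param cds_length_nt CDS length in nucleotides.
#' @param length_aa Protein length in amino acids.
#' @return `TRUE` when the relation holds.
#' @export
check_cds_consistency <- function(cds_length_nt, length_aa) {
  stopifnot(cds_length_nt > 0, length_aa > 0)
  cds_length_nt == 3 * (length_aa + 1)
}

#' Physicochemical property table for a protein set
#'
#' @param proteins Named character vector of protein sequences.
#' @param cds Optional named character vector of matching CDS sequences;
#'   when given, a `cds_consistent` column is added.
#' @param pka_set Passed to [isoelectric_point()].
#' @return Data frame with one row per protein: `protein_id`, `length_aa`,
#'   `cds_length_nt`, `mw`, `pi`, `instability`, `stability`, `gravy`.
#' @export
protein_properties <- function(proteins, cds = NULL,
                               pka_set = "bjellqvist") {
  rows <- lapply(names(proteins), function(id) {
    s <- proteins[[id]]
    ii <- instability_index(s)
    cl <- if (!is.null(cds) && id %in% names(cds)) nchar(cds[[id]]) else NA_integer_
    data.frame(
      protein_id = id,
      length_aa = nchar(s),
      cds_length_nt = cl,
      mw = molecular_weight(s),
      pi = isoelectric_point(s, pka_set),
      instability = ii$value,
      stability = ii$stability,
      gravy = gravy(s),
      cds_consistent = if (is.na(cl)) NA else check_cds_consistency(cl, nchar(s)),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
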