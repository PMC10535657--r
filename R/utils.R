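# Shared low-level helpers: sequence string utilities, IUPAC handling,
# deterministic seed fan-out, rounding conventions.

IUPAC_NT <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

COMPLEMENT_MAP <- c(
  A = "T", C = "G", G = "C", T = "A", N = "N",
  R = "Y", Y = "R", S = "S", W = "W", K = "M", M = "K",
  B = "V", D = "H", H = "D", V = "B"
)

#' Reverse complement of a nucleotide string
#'
#' Handles the full IUPAC ambiguity alphabet. `revcomp(revcomp(x)) == x`.
#'
#' @param x A single nucleotide string.
#' @return The reverse complement, uppercase.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  x <- toupper(x)
  chars <- strsplit(x, "", fixed = TRUE)[[1]]
  bad <- setdiff(unique(chars), names(COMPLEMENT_MAP))
  if (length(bad)) {
    stop("non-IUPAC nucleotide character(s): ", paste(bad, collapse = ", "))
  }
  paste(rev(unname(COMPLEMENT_MAP[chars])), collapse = "")
}

# Split a sequence string into single characters.
seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1]]

# Round half away from zero (0.5 -> 1), matching how integer percentages
# are conventionally printed in genome-survey tables; base round() is
# round-half-even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Deterministic per-component substreams from one master seed, so that
# adding one simulated component never perturbs another's draws.
# Offsets keep the derived seed inside the 32-bit integer range.
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  streams <- c(
    genome = 11L, protein = 23L, cds = 37L, promoter = 41L,
    duplication = 53L, expression = 67L, evolve = 79L, misc = 97L
  )
  off <- streams[[stream]]
  as.integer((as.numeric(seed) * 1009 + off * 9973) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Validate a nucleotide string against the IUPAC alphabet.
check_nt <- function(x, id = "sequence") {
  chars <- unique(seq_chars(toupper(x)))
  bad <- setdiff(chars, names(IUPAC_NT))
  if (length(bad)) {
    stop(id, ": non-IUPAC nucleotide character(s): ", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}
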