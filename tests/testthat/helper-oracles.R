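# Independent oracles, deliberately naive and separate from the package
# code paths they check.

# --- Smith-Waterman: Gotoh affine local DP, scores only. Gap of length
# L costs open + ext * L (the EMBOSS/Biostrings convention).
sw_oracle_score <- function(a, b, submat, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)     # ending in a match/mismatch
  X <- matrix(-Inf, n + 1, m + 1)  # ending in a gap in b (up)
  Y <- matrix(-Inf, n + 1, m + 1)  # ending in a gap in a (left)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[A[i - 1], B[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
      best <- max(best, M[i, j])
    }
  }
  best
}

# --- NG86 exhaustive-pathway oracle. Permutations are enumerated by
# filtering all k^k index tuples; sites come from a precomputed
# 64-codon table.
ng86_oracle <- function(codons_a, codons_b) {
  gc <- Biostrings::GENETIC_CODE
  all_codons <- names(gc)
  nt <- c("A", "C", "G", "T")
  syn_sites <- vapply(all_codons, function(cod) {
    ch <- strsplit(cod, "")[[1]]
    tot <- 0
    for (p in 1:3) for (b in setdiff(nt, ch[p])) {
      alt <- ch; alt[p] <- b
      alt_cod <- paste(alt, collapse = "")
      if (gc[[alt_cod]] != "*" && gc[[alt_cod]] == gc[[cod]]) tot <- tot + 1 / 3
    }
    tot
  }, numeric(1))
  all_perms <- function(k) {
    tup <- as.matrix(expand.grid(rep(list(seq_len(k)), k)))
    tup[apply(tup, 1, function(r) length(unique(r)) == k), , drop = FALSE]
  }
  S <- (sum(syn_sites[codons_a]) + sum(syn_sites[codons_b])) / 2
  N <- 3 * length(codons_a) - S
  Sd <- 0; Nd <- 0
  for (ci in seq_along(codons_a)) {
    x <- strsplit(codons_a[ci], "")[[1]]
    y <- strsplit(codons_b[ci], "")[[1]]
    pos <- which(x != y)
    if (!length(pos)) next
    pp <- all_perms(length(pos))
    path_s <- c(); path_n <- c()
    for (r in seq_len(nrow(pp))) {
      cur <- x; s <- 0; n <- 0; ok <- TRUE
      for (step in pos[pp[r, ]]) {
        aa_before <- gc[[paste(cur, collapse = "")]]
        cur[step] <- y[step]
        aa_after <- gc[[paste(cur, collapse = "")]]
        if (aa_after == "*") { ok <- FALSE; break }
        if (aa_after == aa_before) s <- s + 1 else n <- n + 1
      }
      if (ok) { path_s <- c(path_s, s); path_n <- c(path_n, n) }
    }
    Sd <- Sd + mean(path_s)
    Nd <- Nd + mean(path_n)
  }
  jc <- function(p) if (1 - 4 / 3 * p <= 0) NaN else -3 / 4 * log(1 - 4 / 3 * p)
  list(N = N, S = S, Nd = Nd, Sd = Sd, ka = jc(Nd / N), ks = jc(Sd / S))
}

# --- UPGMA oracle: stats::hclust average linkage; compare via the
# cophenetic (merge-height) distances.
upgma_cophenetic_oracle <- function(d) {
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  as.matrix(stats::cophenetic(hc))
}

# --- pI oracle: brute-force pH grid scan of the charge equation,
# written out independently.
pi_grid_oracle <- function(seq) {
  ch <- strsplit(seq, "")[[1]]
  cnt <- function(r) sum(ch == r)
  pos <- c(Nterm = 7.5, K = 10.0, R = 12.0, H = 5.98)
  neg <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0)
  ntfix <- c(A = 7.59, M = 7.0, S = 6.93, P = 8.36, T = 6.82, V = 7.44, E = 7.7)
  ctfix <- c(D = 4.55, E = 4.75)
  if (ch[1] %in% names(ntfix)) pos["Nterm"] <- ntfix[[ch[1]]]
  if (ch[length(ch)] %in% names(ctfix)) neg["Cterm"] <- ctfix[[ch[length(ch)]]]
  charge_at <- function(pH) {
    q <- 1 / (1 + 10^(pH - pos["Nterm"])) - 1 / (1 + 10^(neg["Cterm"] - pH))
    q <- q + cnt("K") / (1 + 10^(pH - pos["K"])) +
      cnt("R") / (1 + 10^(pH - pos["R"])) +
      cnt("H") / (1 + 10^(pH - pos["H"]))
    q - cnt("D") / (1 + 10^(neg["D"] - pH)) -
      cnt("E") / (1 + 10^(neg["E"] - pH)) -
      cnt("C") / (1 + 10^(neg["C"] - pH)) -
      cnt("Y") / (1 + 10^(neg["Y"] - pH))
  }
  grid <- seq(0, 14, by = 5e-4)
  grid[which.min(abs(vapply(grid, charge_at, numeric(1))))]
}

# Random protein / CDS generators for property tests.
rand_protein <- function(n, alphabet = rownames(wrkyscan:::DIWV)) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
rand_cds <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  paste(c(sample(sense, n_codons, replace = TRUE), "TAA"), collapse = "")
}

blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  get("BLOSUM62", envir = e)
})
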