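# Fully specified synthetic fixtures: a toy genome carrying a WRKY-like
# gene family with planted groups, duplicate pairs evolved at controlled
# omega, promoters with planted cis elements, and negative-binomial count
# matrices -- each with a machine-readable truth table.
#
# One master seed fans out to per-component substreams (see derive_seed)
# so adding genes never perturbs, say, the expression draws.

# Residues used for untagged filler: no W (would spawn spurious
# heptapeptide cores), no C/H (would spawn spurious zinc fingers).
FILLER_AA <- c("A", "D", "E", "F", "G", "I", "K", "L", "M", "N", "P", "Q",
               "R", "S", "T", "V", "Y")

rand_aa <- function(n) paste(sample(FILLER_AA, n, replace = TRUE), collapse = "")
rand_nt <- function(n) paste(sample(NT4, n, replace = TRUE), collapse = "")

# Reverse-lookup of the standard code, stops excluded.
CODONS_OF <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

# Random back-translation (uniform over synonymous codons).
reverse_translate <- function(protein) {
  chars <- seq_chars(protein)
  paste(vapply(chars, function(a) {
    opts <- CODONS_OF[[a]]
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

# One WRKY-like domain of the requested zinc-finger type.
make_domain <- function(zf = c("C2H2", "C2HC", "none"), hept = "WRKYGQK") {
  zf <- match.arg(zf)
  switch(zf,
    C2H2 = paste0(hept, rand_aa(5), "C", rand_aa(4), "C", rand_aa(22),
                  "H", rand_aa(1), "H"),
    C2HC = paste0(hept, rand_aa(5), "C", rand_aa(7), "C", rand_aa(23),
                  "H", rand_aa(1), "C"),
    none = paste0(hept, rand_aa(10))
  )
}

# A protein conforming to one family group's rule.
make_group_protein <- function(group, hept = "WRKYGQK") {
  body <- switch(group,
    I   = paste0(make_domain("C2H2", hept), rand_aa(20), make_domain("C2H2", hept)),
    II  = make_domain("C2H2", hept),
    III = make_domain("C2HC", hept),
    IV  = make_domain("none", hept),
    stop("unknown group: ", group)
  )
  paste0("M", rand_aa(19), body, rand_aa(20))
}

# Instantiate an IUPAC pattern as a concrete sequence.
instantiate_iupac <- function(pattern) {
  paste(vapply(seq_chars(pattern), function(s) {
    opts <- seq_chars(IUPAC_NT[[s]])
    opts[sample.int(length(opts), 1L)]
  }, character(1)), collapse = "")
}

# A promoter whose full motif-hit set equals exactly the planted plan.
# Background is repaired (point mutations) until it is motif-free, the
# planted instances are written in, and the final sequence re-scanned to
# assert exactness.
make_promoter <- function(length, plan, motifs, max_rounds = 200L) {
  bg <- rand_nt(length)
  len_of <- setNames(nchar(motifs$pattern), motifs$name)
  if (nrow(plan)) {
    span_start <- plan$offset
    span_end <- plan$offset + len_of[plan$motif] - 1L
    if (any(span_end > length)) stop("planted motif exceeds promoter length")
    ord <- order(span_start)
    if (any(span_start[ord][-1L] <= span_end[ord][-nrow(plan)] )) {
      stop("planted motif windows overlap")
    }
  }
  planted_mask <- rep(FALSE, length)
  write_planted <- function(s) {
    for (i in seq_len(nrow(plan))) {
      inst <- instantiate_iupac(
        motifs$pattern[motifs$name == plan$motif[i]][1L])
      if (plan$strand[i] == "-") inst <- revcomp(inst)
      substr(s, plan$offset[i], plan$offset[i] + nchar(inst) - 1L) <- inst
      planted_mask[plan$offset[i]:(plan$offset[i] + nchar(inst) - 1L)] <<- TRUE
    }
    s
  }
  s <- write_planted(bg)
  for (round in seq_len(max_rounds)) {
    hits <- scan_motifs(setNames(c(s), "p"), motifs)
    extra <- rep(TRUE, nrow(hits))
    for (i in seq_len(nrow(plan))) {
      extra <- extra & !(hits$motif_name == plan$motif[i] &
                           hits$position == plan$offset[i] &
                           hits$strand == plan$strand[i])
    }
    if (!any(extra)) {
      if (nrow(hits) != nrow(plan)) stop("lost a planted motif during repair")
      return(s)
    }
    # mutate one background base inside each spurious hit
    for (i in which(extra)) {
      span <- hits$position[i]:(hits$position[i] + len_of[hits$motif_name[i]] - 1L)
      free <- span[!planted_mask[span]]
      if (!length(free)) stop("spurious motif inside planted windows; ",
                              "choose non-interacting motifs for the plan")
      j <- free[sample.int(length(free), 1L)]
      old <- substring(s, j, j)
      substr(s, j, j) <- sample(setdiff(NT4, old), 1L)
    }
  }
  stop("could not repair promoter background in ", max_rounds, " rounds")
}

#' Configuration for the synthetic family generator
#'
#' Defaults state a small but complete world: two genes per group,
#' three contigs, 2 kb promoters, one tandem and one segmental duplicate
#' evolved at moderate divergence under purifying selection, a handful of
#' planted promoter motifs, and a three-sample expression design.
#'
#' @param n_per_group Named counts for groups I, II, III, IV.
#' @param n_contigs Number of contigs genes are spread over.
#' @param promoter_length Promoter window (bp).
#' @param intergenic Spacer between gene blocks (bp).
#' @param max_contig_length Error if a contig would exceed this.
#' @param duplication_plan Data frame `source` (gene index), `type`
#'   (`"tandem"`/`"segmental"`), `omega`, `target_ks`.
#' @param motif_plan Data frame `gene` (index), `motif`, `offset`,
#'   `strand`; offsets are 1-based on the promoter.
#' @param expression List: `samples`, `expressed_prob`, `mu`, `size`,
#'   `common_n` (genes forced on in every sample).
#' @param seed Master seed.
#' @return Config list.
#' @export
family_sim_config <- function(
    n_per_group = c(I = 2L, II = 3L, III = 2L, IV = 2L),
    n_contigs = 3L,
    promoter_length = 2000L,
    intergenic = 500L,
    max_contig_length = Inf,
    duplication_plan = data.frame(
      source = c(2L, 3L),
      type = c("tandem", "segmental"),
      omega = c(0.2, 0.2),
      target_ks = c(0.15, 0.15)
    ),
    motif_plan = data.frame(
      gene = c(1L, 1L, 2L, 3L),
      motif = c("W-box", "LTR", "CAAT-box", "MBS"),
      offset = c(101L, 501L, 901L, 1301L),
      strand = c("+", "-", "+", "+")
    ),
    expression = list(samples = c("s1", "s2", "s3"),
                      expressed_prob = 0.8, mu = 200, size = 2,
                      common_n = 2L),
    seed = 1L) {
  stopifnot(all(n_per_group >= 0L), n_contigs >= 1L, promoter_length > 0L)
  list(n_per_group = n_per_group, n_contigs = n_contigs,
       promoter_length = promoter_length, intergenic = intergenic,
       max_contig_length = max_contig_length,
       duplication_plan = duplication_plan, motif_plan = motif_plan,
       expression = expression, seed = seed)
}

#' Simulate a WRKY-like gene family with full ground truth
#'
#' Generates proteins whose domains obey their planted group's rule,
#' back-translates them, evolves planned duplicate copies at controlled
#' omega, plants promoter motifs into motif-free background, lays
#' everything out on contigs (tandem copies adjacent to their source,
#' segmental copies on another contig), and assembles the genome.
#' Deterministic under the config seed.
#'
#' @param cfg A [family_sim_config()].
#' @param motifs Motif table used for promoter planting/verification.
#' @return List: `genome`, `genes` (named list of [gene_model()]),
#'   `proteins`, `cds`, `promoters` (planted, transcription orientation)
#'   and `truth` (`genes`, `duplications`, `motifs` data frames).
#' @export
simulate_family <- function(cfg = family_sim_config(),
                            motifs = load_motifs()) {
  groups <- rep(names(cfg$n_per_group), cfg$n_per_group)
  n_base <- length(groups)

  # --- proteins & CDS ------------------------------------------------
  set.seed(derive_seed(cfg$seed, "protein"))
  ids <- sprintf("syn%03d", seq_len(n_base))
  proteins <- setNames(vapply(groups, make_group_protein, character(1)), ids)
  set.seed(derive_seed(cfg$seed, "cds"))
  cds <- setNames(vapply(proteins, function(p) {
    paste0(reverse_translate(p), "TAA")
  }, character(1)), ids)

  truth_genes <- data.frame(gene_id = ids, group = groups,
                            stringsAsFactors = FALSE)

  # --- duplicates ----------------------------------------------------
  dup <- cfg$duplication_plan
  truth_dups <- NULL
  if (!is.null(dup) && nrow(dup)) {
    set.seed(derive_seed(cfg$seed, "evolve"))
    for (i in seq_len(nrow(dup))) {
      src <- ids[dup$source[i]]
      new_id <- paste0(src, "d")
      # domain-signature residues (the heptapeptide core and every C/H,
      # which filler never contains) stay under absolute constraint so
      # the duplicate keeps its planted group
      chars <- seq_chars(proteins[[src]])
      frozen <- sort(unique(c(
        which(chars %in% c("C", "H", "W")),
        unlist(lapply(gregexpr("WRKY", proteins[[src]], fixed = TRUE)[[1]],
                      function(p) if (p > 0) p:(p + 3L) else integer(0)))
      )))
      new_cds <- evolve_pair(cds[[src]], omega = dup$omega[i],
                             target_ks = dup$target_ks[i],
                             frozen_aa = frozen)
      cds[new_id] <- new_cds
      proteins[new_id] <- translate_cds(new_cds)
      truth_genes <- rbind(truth_genes, data.frame(
        gene_id = new_id, group = truth_genes$group[truth_genes$gene_id == src],
        stringsAsFactors = FALSE))
      truth_dups <- rbind(truth_dups, data.frame(
        gene_a = src, gene_b = new_id, type = dup$type[i],
        omega = dup$omega[i], target_ks = dup$target_ks[i],
        stringsAsFactors = FALSE))
    }
  }
  all_ids <- names(proteins)

  # --- promoters -----------------------------------------------------
  set.seed(derive_seed(cfg$seed, "promoter"))
  mp <- cfg$motif_plan
  promoters <- character(0)
  truth_motifs <- NULL
  for (k in seq_along(all_ids)) {
    plan_k <- if (!is.null(mp) && nrow(mp)) {
      mm <- mp[mp$gene == k, , drop = FALSE]
      data.frame(motif = mm$motif, offset = mm$offset, strand = mm$strand,
                 stringsAsFactors = FALSE)
    } else data.frame(motif = character(0), offset = integer(0),
                      strand = character(0))
    promoters[all_ids[k]] <- make_promoter(cfg$promoter_length, plan_k, motifs)
    if (nrow(plan_k)) {
      truth_motifs <- rbind(truth_motifs, data.frame(
        promoter_id = all_ids[k], motif_name = plan_k$motif,
        position = plan_k$offset, strand = plan_k$strand,
        stringsAsFactors = FALSE))
    }
  }

  # --- layout & genome ----------------------------------------------
  set.seed(derive_seed(cfg$seed, "genome"))
  contig_of <- setNames(rep(NA_integer_, length(all_ids)), all_ids)
  base_contig <- (seq_len(n_base) - 1L) %% cfg$n_contigs + 1L
  contig_of[ids] <- base_contig
  if (!is.null(truth_dups)) {
    for (i in seq_len(nrow(truth_dups))) {
      src_contig <- contig_of[[truth_dups$gene_a[i]]]
      contig_of[[truth_dups$gene_b[i]]] <-
        if (truth_dups$type[i] == "tandem") src_contig
        else (src_contig %% cfg$n_contigs) + 1L
    }
    if (cfg$n_contigs < 2L && any(truth_dups$type == "segmental")) {
      stop("segmental duplicates need at least 2 contigs")
    }
  }

  # order genes on each contig: sources first, tandem copies right after
  order_on <- function(cids) {
    base <- intersect(ids, cids)
    out <- character(0)
    for (b in base) {
      out <- c(out, b, intersect(paste0(b, "d"), cids))
    }
    c(out, setdiff(cids, out))
  }

  genome <- character(0)
  genes <- list()
  strands <- setNames(rep(c("+", "-"), length.out = length(all_ids)), all_ids)
  for (ci in seq_len(cfg$n_contigs)) {
    cname <- sprintf("ctg%02d", ci)
    cids <- order_on(names(contig_of)[contig_of == ci])
    seq_parts <- character(0)
    pos <- 0L
    for (gid in cids) {
      seq_parts <- c(seq_parts, rand_nt(cfg$intergenic))
      pos <- pos + cfg$intergenic
      g_cds <- cds[[gid]]
      # one intron for every second gene to exercise multi-segment CDS
      n_seg <- if (match(gid, all_ids) %% 2L == 0L) 2L else 1L
      if (n_seg == 2L) {
        cut <- 3L * (nchar(g_cds) %/% 6L)
        s1 <- substring(g_cds, 1L, cut)
        s2 <- substring(g_cds, cut + 1L, nchar(g_cds))
        intron <- rand_nt(100L)
        gbody <- paste0(s1, intron, s2)
        segs_plus <- rbind(c(1L, cut), c(cut + 101L, nchar(gbody)))
      } else {
        gbody <- g_cds
        segs_plus <- rbind(c(1L, nchar(gbody)))
      }
      strand <- strands[[gid]]
      prom <- promoters[[gid]]
      L <- nchar(gbody)
      if (strand == "+") {
        seq_parts <- c(seq_parts, prom, gbody)
        gstart <- pos + nchar(prom) + 1L
        segs <- segs_plus + gstart - 1L
        pos <- pos + nchar(prom) + L
      } else {
        block <- revcomp(gbody)
        seq_parts <- c(seq_parts, block, revcomp(prom))
        gstart <- pos + 1L
        segs <- cbind(gstart + L - segs_plus[, 2L], gstart + L - segs_plus[, 1L])
        segs <- segs[order(segs[, 1L]), , drop = FALSE]
        pos <- pos + L + nchar(prom)
      }
      genes[[gid]] <- gene_model(gid, cname, min(segs), max(segs),
                                 strand, segs)
      truth_genes$contig[truth_genes$gene_id == gid] <- cname
      truth_genes$strand[truth_genes$gene_id == gid] <- strand
    }
    seq_parts <- c(seq_parts, rand_nt(cfg$intergenic))
    contig_seq <- paste(seq_parts, collapse = "")
    if (nchar(contig_seq) > cfg$max_contig_length) {
      stop("layout too small: contig ", cname, " needs ",
           nchar(contig_seq), " bp > max_contig_length")
    }
    genome[cname] <- contig_seq
  }
  genes <- genes[all_ids]

  list(
    genome = genome, genes = genes, proteins = proteins, cds = cds,
    promoters = promoters,
    truth = list(genes = truth_genes, duplications = truth_dups,
                 motifs = truth_motifs, config = cfg)
  )
}

#' Evolve a duplicate CDS at a controlled Ka/Ks
#'
#' Codon-wise substitution simulation: random single-base proposals,
#' synonymous changes accepted at rate 1, nonsynonymous at rate `omega`,
#' changes creating a stop codon rejected. The process stops once the
#' accepted synonymous events per synonymous site reach `target_ks`.
#'
#' @param cds Coding sequence (terminal stop codon preserved untouched).
#' @param omega Target Ka/Ks (> 0).
#' @param target_ks Target synonymous divergence (events per synonymous
#'   site; >= 0).
#' @param frozen_aa Optional residue indices where nonsynonymous changes
#'   are rejected outright (absolute purifying constraint) -- used to keep
#'   planted domain signatures intact in duplicates.
#' @param max_iter Proposal budget; exceeded -> error (stop-codon
#'   deadlock).
#' @return Mutated CDS with attributes `omega` and `n_syn`/`n_nonsyn`
#'   (accepted event counts).
#' @export
evolve_pair <- function(cds, omega, target_ks, frozen_aa = integer(0),
                        max_iter = NULL) {
  stopifnot(omega > 0, target_ks >= 0)
  protein <- translate_cds(cds)  # validates the CDS
  if (target_ks == 0) {
    out <- cds
    attr(out, "omega") <- omega
    attr(out, "n_syn") <- 0L; attr(out, "n_nonsyn") <- 0L
    return(out)
  }
  n_nt <- nchar(cds)
  has_stop <- codon_aa(substring(cds, n_nt - 2L, n_nt)) == "*"
  coding_len <- if (has_stop) n_nt - 3L else n_nt
  codons <- substring(cds, seq(1L, coding_len, 3L),
                      seq(3L, coding_len, 3L))
  S <- sum(vapply(codons, codon_syn_sites, numeric(1)))
  need <- target_ks * S
  if (is.null(max_iter)) max_iter <- max(10000L, ceiling(need) * 1000L)
  n_syn <- 0L; n_nonsyn <- 0L
  iter <- 0L
  while (n_syn < need) {
    iter <- iter + 1L
    if (iter > max_iter) {
      stop("target_ks unreachable within proposal budget (stop-codon deadlock?)")
    }
    ci <- sample.int(length(codons), 1L)
    pos <- sample.int(3L, 1L)
    cod <- seq_chars(codons[ci])
    alt <- sample(setdiff(NT4, cod[pos]), 1L)
    new <- cod; new[pos] <- alt
    new_codon <- paste(new, collapse = "")
    if (codon_aa(new_codon) == "*") next
    if (codon_aa(new_codon) == codon_aa(codons[ci])) {
      codons[ci] <- new_codon
      n_syn <- n_syn + 1L
    } else if (ci %in% frozen_aa) {
      next
    } else if (runif(1) < omega) {
      codons[ci] <- new_codon
      n_nonsyn <- n_nonsyn + 1L
    }
  }
  out <- paste0(paste(codons, collapse = ""),
                if (has_stop) substring(cds, n_nt - 2L, n_nt) else "")
  attr(out, "omega") <- omega
  attr(out, "n_syn") <- n_syn; attr(out, "n_nonsyn") <- n_nonsyn
  out
}

#' Simulate a fragment-count matrix from a truth table
#'
#' Expressed gene/sample cells draw zero-truncated negative-binomial
#' counts (so a planted expressed gene is never invisible); silent cells
#' are exactly zero. The first `common_n` genes are forced on in every
#' sample, the rest are expressed per sample with `expressed_prob`.
#'
#' @param sim Output of [simulate_family()] (for gene ids and CDS
#'   lengths).
#' @param design Expression design list (see [family_sim_config()]).
#' @param seed Seed; defaults to the family config's expression stream.
#' @return List: `counts` (gene x sample), `lengths`, `expressed`
#'   (logical truth matrix).
#' @export
simulate_counts <- function(sim, design = sim$truth$config$expression,
                            seed = derive_seed(sim$truth$config$seed,
                                               "expression")) {
  stopifnot(length(design$samples) >= 1L)
  set.seed(seed)
  ids <- names(sim$cds)
  lengths <- setNames(nchar(sim$cds), ids)
  k <- length(design$samples)
  expressed <- matrix(FALSE, length(ids), k,
                      dimnames = list(ids, design$samples))
  common_n <- min(design$common_n %||% 0L, length(ids))
  for (s in seq_len(k)) {
    expressed[, s] <- runif(length(ids)) < design$expressed_prob
  }
  if (common_n > 0L) expressed[seq_len(common_n), ] <- TRUE
  counts <- matrix(0L, length(ids), k,
                   dimnames = list(ids, design$samples))
  n_on <- sum(expressed)
  if (n_on > 0L) {
    draws <- rnbinom(n_on, mu = design$mu, size = design$size)
    while (any(draws == 0L)) {
      draws[draws == 0L] <- rnbinom(sum(draws == 0L), mu = design$mu,
                                    size = design$size)
    }
    counts[expressed] <- draws
  }
  list(counts = counts, lengths = lengths, expressed = expressed)
}

#' Write a simulated family to disk in standard formats
#'
#' Emits genome FASTA, GFF3, protein and CDS FASTA, promoter FASTA, and
#' `truth.json`.
#'
#' @param sim Output of [simulate_family()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_family <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fasta"))
  write_gff3(sim$genes, file.path(dir, "genes.gff3"))
  write_fasta(sim$proteins, file.path(dir, "proteins.fasta"))
  write_fasta(vapply(sim$cds, as.character, character(1)),
              file.path(dir, "cds.fasta"))
  write_fasta(sim$promoters, file.path(dir, "promoters.fasta"))
  jsonlite::write_json(sim$truth[c("genes", "duplications", "motifs")],
                       file.path(dir, "truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, null = "null", digits = NA)
  invisible(dir)
}
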