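# Rule-based WRKY domain detection and family-group assignment.
#
# The family is defined by the WRKYGQK heptapeptide (with known variants)
# followed by a zinc finger: C2H2 in groups I/II, C2HC in group III; group
# IV members carry the heptapeptide but no complete finger. Group I
# proteins carry two complete domains.

# Canonical heptapeptide plus the variants reported across plant families.
HEPT_VARIANTS <- c("WRKYGQK", "WRKYGEK", "WRKYGRK", "WRKYGKK", "WRKYLQK")

#' Default zinc-finger spacing configuration
#'
#' Canonical WRKY-literature spacings: `C-x(4,5)-C-x(22,23)-H-x-H` for the
#' C2H2 finger and `C-x(7)-C-x(23)-H-x-C` for the C2HC finger, searched
#' within `window` residues downstream of the heptapeptide.
#'
#' @param c2h2_gap1,c2h2_gap2 Allowed `(min,max)` spacer lengths of the
#'   C2H2 pattern.
#' @param c2hc_gap1,c2hc_gap2 Allowed `(min,max)` spacer lengths of the
#'   C2HC pattern.
#' @param window Search window (aa) downstream of the heptapeptide.
#' @return List used by [detect_zinc_finger()].
#' @export
zf_config <- function(c2h2_gap1 = c(4L, 5L), c2h2_gap2 = c(22L, 23L),
                      c2hc_gap1 = c(7L, 7L), c2hc_gap2 = c(23L, 23L),
                      window = 60L) {
  list(c2h2_gap1 = c2h2_gap1, c2h2_gap2 = c2h2_gap2,
       c2hc_gap1 = c2hc_gap1, c2hc_gap2 = c2hc_gap2, window = window)
}

#' Scan a protein for WRKY heptapeptide cores
#'
#' Reports every non-overlapping `WRKY` core together with up to three
#' following residues. The variant string is the full 7-mer when it is a
#' recognized heptapeptide variant, the 5-mer `WRKYG` when only the fifth
#' residue is conserved, and otherwise the available (<= 7) residues.
#'
#' @param protein Amino-acid string.
#' @param protein_id Id recorded in the hits.
#' @return Data frame with columns `protein_id`, `hept_start` (1-based),
#'   `hept_variant`, `zf_type` (`NA` until [detect_zinc_finger()]),
#'   `zf_start`, `zf_end`.
#' @export
scan_heptapeptide <- function(protein, protein_id = "query") {
  stopifnot(nchar(protein) > 0L)
  protein <- toupper(protein)
  m <- gregexpr("WRKY", protein, fixed = TRUE)[[1]]
  empty <- data.frame(protein_id = character(0), hept_start = integer(0),
                      hept_variant = character(0), zf_type = character(0),
                      zf_start = integer(0), zf_end = integer(0),
                      stringsAsFactors = FALSE)
  if (m[1L] == -1L) return(empty)
  pos <- as.integer(m)
  variants <- vapply(pos, function(p) {
    full <- substring(protein, p, min(p + 6L, nchar(protein)))
    if (full %in% HEPT_VARIANTS) return(full)
    if (substring(full, 1L, 5L) == "WRKYG") return("WRKYG")
    full
  }, character(1))
  data.frame(protein_id = protein_id, hept_start = pos,
             hept_variant = variants, zf_type = NA_character_,
             zf_start = NA_integer_, zf_end = NA_integer_,
             stringsAsFactors = FALSE)
}

#' Detect the zinc finger downstream of a heptapeptide hit
#'
#' Searches within `cfg$window` residues downstream of the heptapeptide end
#' for the C2H2 pattern, then (if absent) the C2HC pattern.
#'
#' @param protein Amino-acid string the hit came from.
#' @param hit One row of the [scan_heptapeptide()] output.
#' @param cfg A [zf_config()].
#' @return The hit row with `zf_type` (`"C2H2"`, `"C2HC"` or `"none"`) and
#'   `zf_start`/`zf_end` (1-based positions on the protein) filled in.
#' @export
detect_zinc_finger <- function(protein, hit, cfg = zf_config()) {
  protein <- toupper(protein)
  hept_end <- hit$hept_start + nchar(hit$hept_variant) - 1L
  from <- hept_end + 1L
  to <- min(hept_end + cfg$window, nchar(protein))
  region <- if (from > to) "" else substring(protein, from, to)

  pat_c2h2 <- sprintf("C.{%d,%d}C.{%d,%d}H.H",
                      cfg$c2h2_gap1[1L], cfg$c2h2_gap1[2L],
                      cfg$c2h2_gap2[1L], cfg$c2h2_gap2[2L])
  pat_c2hc <- sprintf("C.{%d,%d}C.{%d,%d}H.C",
                      cfg$c2hc_gap1[1L], cfg$c2hc_gap1[2L],
                      cfg$c2hc_gap2[1L], cfg$c2hc_gap2[2L])

  hit$zf_type <- "none"
  for (cand in list(c("C2H2", pat_c2h2), c("C2HC", pat_c2hc))) {
    m <- regexpr(cand[2L], region)
    if (m != -1L) {
      hit$zf_type <- cand[1L]
      hit$zf_start <- from + as.integer(m) - 1L
      hit$zf_end <- hit$zf_start + attr(m, "match.length") - 1L
      break
    }
  }
  hit
}

#' Scan a protein for complete WRKY domains
#'
#' Convenience wrapper: heptapeptide scan followed by zinc-finger detection
#' for every hit.
#'
#' @inheritParams detect_zinc_finger
#' @inheritParams scan_heptapeptide
#' @return Data frame of completed domain hits.
#' @export
scan_domains <- function(protein, protein_id = "query", cfg = zf_config()) {
  hits <- scan_heptapeptide(protein, protein_id)
  if (nrow(hits) == 0L) return(hits)
  do.call(rbind, lapply(seq_len(nrow(hits)), function(i) {
    detect_zinc_finger(protein, hits[i, , drop = FALSE], cfg)
  }))
}

#' Assign a WRKY family group from a protein's domain hits
#'
#' Rules: two (or more) complete domains, all C2H2 -> group I; one complete
#' C2H2 domain -> group II; one complete C2HC domain -> group III; at least
#' one heptapeptide but no complete finger -> group IV; no hits -> "none".
#' When several complete domains disagree, the C-terminal-most complete
#' domain decides between II and III (conservative precedence).
#'
#' @param hits Data frame from [scan_domains()] (one protein).
#' @return List with `protein_id`, `n_domains` (complete domains), `group`
#'   and `evidence` (the hits).
#' @export
assign_group <- function(hits) {
  if (nrow(hits) == 0L) {
    return(list(protein_id = NA_character_, n_domains = 0L,
                group = "none", evidence = hits))
  }
  hits <- hits[order(hits$hept_start), , drop = FALSE]
  complete <- hits[!is.na(hits$zf_type) & hits$zf_type != "none", , drop = FALSE]
  n_dom <- nrow(complete)
  group <-
    if (n_dom >= 2L && all(complete$zf_type == "C2H2")) "I"
    else if (n_dom >= 1L) {
      last <- complete$zf_type[n_dom]
      if (last == "C2H2") "II" else "III"
    }
    else "IV"
  list(protein_id = hits$protein_id[1L], n_domains = n_dom,
       group = group, evidence = hits)
}

#' Classify a set of proteins into WRKY family groups
#'
#' @param proteins Named character vector of amino-acid sequences.
#' @param cfg A [zf_config()].
#' @return Data frame with columns `protein_id`, `n_domains`,
#'   `hept_variants` (comma-joined), `zf_types` (comma-joined), `group`.
#' @export
classify_proteins <- function(proteins, cfg = zf_config()) {
  rows <- lapply(names(proteins), function(id) {
    hits <- scan_domains(proteins[[id]], id, cfg)
    fa <- assign_group(hits)
    data.frame(
      protein_id = id,
      n_domains = fa$n_domains,
      hept_variants = paste(hits$hept_variant, collapse = ","),
      zf_types = paste(hits$zf_type, collapse = ","),
      group = if (nrow(hits)) fa$group else "none",
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Assign group-II subgroups by reference co-clustering
#'
#' Each query is placed on a UPGMA tree together with labeled reference
#' domain sequences; its label is the majority subgroup among the
#' references in the smallest clade that contains the query and at least
#' one reference. Distances are alignment-based p-distances from pairwise
#' global alignment.
#'
#' @param queries Named character vector of group-II protein (or domain)
#'   sequences.
#' @param references Named character vector of reference domain sequences;
#'   names must carry the subgroup as a `|`-suffix, e.g. `ref1|IIb`, with
#'   at least two references per subgroup IIa-IIe.
#' @return Named character vector of subgroup labels for the queries.
#' @export
assign_subgroup <- function(queries, references) {
  sub_of <- sub("^.*\\|", "", names(references))
  need <- c("IIa", "IIb", "IIc", "IId", "IIe")
  missing <- setdiff(need, unique(sub_of))
  if (length(missing)) {
    stop("reference set missing subgroup(s): ", paste(missing, collapse = ", "))
  }
  if (length(queries) == 0L) return(setNames(character(0), character(0)))
  # queries sorted by name so labels are stable under input order
  queries <- queries[order(names(queries))]
  all_seqs <- c(queries, references)
  d <- pairwise_protein_distance(all_seqs)
  tree <- upgma(d)
  is_ref <- names(all_seqs) %in% names(references)
  labels <- vapply(names(queries), function(q) {
    node <- which(tree$tip.label == q)
    repeat {
      edge <- which(tree$edge[, 2L] == node)
      if (!length(edge)) break
      node <- tree$edge[edge, 1L]
      tips <- tree$tip.label[clade_tips(tree, node)]
      refs <- intersect(tips, names(references))
      if (length(refs)) {
        subs <- sub("^.*\\|", "", refs)
        tab <- sort(table(subs), decreasing = TRUE)
        return(names(tab)[1L])
      }
    }
    NA_character_
  }, character(1))
  labels
}

# Tip indices of the clade rooted at `node` in an ape phylo tree.
clade_tips <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, clade_tips, tree = tree))
}
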