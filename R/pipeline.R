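# End-to-end orchestration: classify -> properties -> promoters ->
# duplications -> Ka/Ks -> ages -> tree -> expression, with a run
# manifest for reproducibility.

#' Pipeline configuration
#'
#' @param genome,gff3,proteins,cds Paths to the inputs. `genome` + `gff3`
#'   are enough: proteins/CDS are derived when not supplied.
#' @param counts Optional counts TSV (see [read_counts()]); when missing
#'   the expression stage is skipped with a warning.
#' @param motif_table Motif TSV; default the bundled table.
#' @param out_dir Output directory.
#' @param upstream_length Promoter window (bp).
#' @param annotated_total Denominator for expression proportions; default
#'   the number of genes in the annotation.
#' @param fpkm_threshold Expressed-gene FPKM threshold.
#' @param dup_cfg A [duplication_config()].
#' @param evo_cfg An [evolution_config()].
#' @param seed Recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return Config list.
#' @export
pipeline_config <- function(genome, gff3, proteins = NULL, cds = NULL,
                            counts = NULL,
                            motif_table = system.file(
                              "extdata", "cis_motifs.tsv", package = "wrkyscan"),
                            out_dir = "wrkyscan_out",
                            upstream_length = 2000L,
                            annotated_total = NULL,
                            fpkm_threshold = 0,
                            dup_cfg = duplication_config(),
                            evo_cfg = evolution_config(),
                            seed = 1L) {
  list(genome = genome, gff3 = gff3, proteins = proteins, cds = cds,
       counts = counts, motif_table = motif_table, out_dir = out_dir,
       upstream_length = upstream_length, annotated_total = annotated_total,
       fpkm_threshold = fpkm_threshold, dup_cfg = dup_cfg,
       evo_cfg = evo_cfg, seed = seed)
}

#' Run the full gene-family characterization pipeline
#'
#' Stages: family classification, physicochemical properties (family
#' table), promoter extraction + cis-element scan, duplication detection,
#' Ka/Ks + divergence dating of duplicate pairs, age summary, UPGMA tree,
#' and (when counts are provided) expression summaries. Outputs are
#' written under `cfg$out_dir`; re-running on identical inputs reproduces
#' identical files.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisible list of the in-memory stage results.
#' @export
run_pipeline <- function(cfg) {
  for (p in c("genome", "gff3")) {
    if (is.null(cfg[[p]]) || !file.exists(cfg[[p]])) {
      stop("missing mandatory input: --", p)
    }
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  msg <- function(...) message("[wrkyscan] ", ...)

  genome <- read_fasta(cfg$genome)
  genes <- read_gff3(cfg$gff3, genome)
  msg(length(genes), " gene model(s) on ", length(genome), " contig(s)")

  cds <- if (!is.null(cfg$cds)) read_fasta(cfg$cds) else
    vapply(genes, function(g) extract_cds(genome, g), character(1))
  proteins <- if (!is.null(cfg$proteins)) read_fasta(cfg$proteins) else
    vapply(cds, translate_cds, character(1))

  fam <- classify_proteins(proteins)
  props <- protein_properties(proteins, cds)
  coords <- do.call(rbind, lapply(genes, function(g) data.frame(
    protein_id = g$gene_id, contig = g$contig, start = g$start,
    end = g$end, strand = g$strand, stringsAsFactors = FALSE)))
  family_table <- merge(merge(coords, fam, by = "protein_id"),
                        props, by = "protein_id")
  family_table <- family_table[order(family_table$protein_id),
                               c("protein_id", "group", "contig", "start",
                                 "end", "strand", "cds_length_nt",
                                 "length_aa", "mw", "pi", "instability",
                                 "gravy")]
  write.table(family_table, file.path(cfg$out_dir, "family_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  msg("family table written (", nrow(family_table), " rows)")

  proms <- extract_promoters(genome, genes,
                             file.path(cfg$out_dir, "promoters.fasta"),
                             cfg$upstream_length)
  motifs <- load_motifs(cfg$motif_table)
  hits <- scan_motifs(proms, motifs)
  write_hits_bed(hits, motifs, file.path(cfg$out_dir, "cis_hits.bed"))
  cis_report <- summarize_categories(hits, motifs, length(proms))
  jsonlite::write_json(cis_report, file.path(cfg$out_dir, "cis_report.json"),
                       auto_unbox = TRUE, digits = NA)
  msg(nrow(hits), " cis-element hit(s)")

  dups <- find_duplications(genes, proteins, cfg$dup_cfg)
  if (nrow(dups)) {
    kk <- do.call(rbind, lapply(seq_len(nrow(dups)), function(i) {
      kaks_pair(cds[[dups$gene_a[i]]], cds[[dups$gene_b[i]]],
                cfg$evo_cfg, cfg$dup_cfg)
    }))
    dup_table <- cbind(dups, kk)
  } else {
    dup_table <- cbind(dups, data.frame(ka = numeric(0), ks = numeric(0),
                                        ratio = numeric(0),
                                        selection = character(0),
                                        time_mya = numeric(0),
                                        n_codons = integer(0)))
  }
  write.table(dup_table, file.path(cfg$out_dir, "duplication_table.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  ages <- summarize_ages(dup_table)
  jsonlite::write_json(ages, file.path(cfg$out_dir, "age_summary.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  msg(nrow(dup_table), " duplication event(s)")

  tree <- NULL
  if (length(proteins) >= 2L) {
    d <- pairwise_protein_distance(proteins)
    tree <- upgma(d)
    write_newick(tree, file.path(cfg$out_dir, "family_upgma.nwk"))
  }

  expr <- NULL
  if (!is.null(cfg$counts) && file.exists(cfg$counts)) {
    cm <- read_counts(cfg$counts)
    f <- fpkm(cm$counts, cm$lengths)
    write.table(data.frame(gene = rownames(f), f, check.names = FALSE),
                file.path(cfg$out_dir, "fpkm.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    annotated <- cfg$annotated_total %||% nrow(f)
    expr <- expressed_sets(f, annotated, cfg$fpkm_threshold)
    jsonlite::write_json(
      expr[c("n_expressed", "proportion_pct", "venn", "n_union", "common")],
      file.path(cfg$out_dir, "expression_report.json"),
      auto_unbox = TRUE, digits = NA)
    lm <- log_matrix(f)
    write.table(data.frame(gene = rownames(lm), lm, check.names = FALSE),
                file.path(cfg$out_dir, "log2_matrix.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (ncol(f) >= 3L) {
      mds <- classical_mds(f, k = 2L)
      write.table(data.frame(sample = rownames(mds), mds),
                  file.path(cfg$out_dir, "mds.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    msg("expression report written (", ncol(f), " samples)")
  } else if (!is.null(cfg$counts)) {
    warning("counts file not found; expression stage skipped")
  } else {
    msg("no counts input; expression stage skipped")
  }

  manifest <- list(
    package = "wrkyscan",
    version = as.character(utils::packageVersion("wrkyscan")),
    seed = cfg$seed,
    inputs = lapply(
      Filter(Negate(is.null),
             cfg[c("genome", "gff3", "proteins", "cds", "counts")]),
      function(p) if (file.exists(p)) unname(md5sum(p)) else NA),
    parameters = cfg[c("upstream_length", "fpkm_threshold")],
    dup_cfg = cfg$dup_cfg, evo_cfg = cfg$evo_cfg
  )
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(family_table = family_table, cis = cis_report,
                 duplications = dup_table, ages = ages, tree = tree,
                 expression = expr))
}
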