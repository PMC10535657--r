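# Loaders for the bundled published bilberry WRKY tables, used as desk
# inputs for consistency checks (coding-length relation, Ka/Ks ratio
# arithmetic, dating calibration, duplication-age summaries).

#' Published bilberry VmWRKY gene table
#'
#' Genomic coordinates, family group, CDS/protein lengths and
#' physicochemical properties of the 69 characterized bilberry WRKY
#' genes, as published.
#'
#' @return Data frame.
#' @export
load_published_gene_table <- function() {
  read.delim(system.file("extdata", "vmwrky_gene_table.tsv",
                         package = "wrkyscan"),
             stringsAsFactors = FALSE, comment.char = "#")
}

#' Published bilberry VmWRKY duplication table
#'
#' Ka, Ks, Ka/Ks, duplication type and divergence time of the published
#' duplicated gene pairs. `NaN` marks undefined estimates; the `note`
#' column flags the one row computed with a different program (`**`),
#' excluded from internal consistency checks.
#'
#' @return Data frame.
#' @export
load_published_duplication_table <- function() {
  tab <- read.delim(system.file("extdata", "vmwrky_duplication_table.tsv",
                                package = "wrkyscan"),
                    stringsAsFactors = FALSE, comment.char = "#",
                    fill = TRUE)
  tab$note[is.na(tab$note)] <- ""
  tab
}
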