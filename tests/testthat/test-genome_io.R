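test_that("read_fasta parses records, folds case and joins wrapped lines", {
  f <- tempfile(fileext = ".fa")
  writeLines(c(">c1", "ACGT"), f)
  expect_identical(read_fasta(f), c(c1 = "ACGT"))
  writeLines(c(">c1 some description", "ac", "GT"), f)
  expect_identical(read_fasta(f), c(c1 = "ACGT"))
  writeLines(c(">c1", "ACGT", ">c1", "TTTT"), f)
  expect_error(read_fasta(f), "duplicate.*c1")
  writeLines(c(">c1", "ACGT", ">c2"), f)
  expect_error(read_fasta(f), "empty|c2")
})

test_that("FASTA write/read round-trips random fixtures", {
  set.seed(42)
  for (rep in 1:5) {
    seqs <- setNames(
      vapply(1:4, function(i) paste(sample(c("A", "C", "G", "T"),
                                           sample(1:200, 1), TRUE),
                                    collapse = ""), character(1)),
      paste0("ctg", 1:4))
    f <- write_tmp_fasta(seqs)
    expect_identical(read_fasta(f), seqs)
  }
})

test_that("read_gff3 groups CDS under genes and checks bounds", {
  f <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "c1\tx\tgene\t101\t200\t.\t+\t.\tID=g1",
    "c1\tx\tmRNA\t101\t200\t.\t+\t.\tID=g1.t1;Parent=g1",
    "c1\tx\tCDS\t101\t200\t.\t+\t0\tID=g1.c;Parent=g1.t1",
    "c1\tx\tgene\t10\t50\t.\t-\t.\tID=g2",
    "c1\tx\tmRNA\t10\t50\t.\t-\t.\tID=g2.t1;Parent=g2",
    "c1\tx\tCDS\t10\t20\t.\t-\t0\tID=g2.c1;Parent=g2.t1",
    "c1\tx\tCDS\t40\t50\t.\t-\t0\tID=g2.c2;Parent=g2.t1"), f)
  genes <- read_gff3(f)
  expect_named(genes, c("g1", "g2"))
  expect_equal(genes$g1$start, 101)
  expect_equal(genes$g1$end, 200)
  expect_equal(genes$g1$strand, "+")
  expect_equal(unname(genes$g2$cds), cbind(c(10L, 40L), c(20L, 50L)),
               ignore_attr = TRUE)
  # CDS outside the declared contig bounds
  writeLines(c(
    "##gff-version 3",
    "c1\tx\tgene\t100\t500\t.\t+\t.\tID=g1",
    "c1\tx\tmRNA\t100\t500\t.\t+\t.\tID=g1.t1;Parent=g1",
    "c1\tx\tCDS\t100\t500\t.\t+\t0\tID=g1.c;Parent=g1.t1"), f)
  expect_error(read_gff3(f, c(c1 = 300L)), "outside bounds")
})

test_that("GFF3 write/read round-trip preserves coordinates bit-exactly", {
  sim <- default_sim()
  f <- tempfile(fileext = ".gff3")
  write_gff3(sim$genes, f)
  back <- read_gff3(f, sim$genome)
  expect_setequal(names(back), names(sim$genes))
  for (id in names(sim$genes)) {
    expect_equal(back[[id]][c("start", "end", "strand", "contig")],
                 sim$genes[[id]][c("start", "end", "strand", "contig")])
    expect_equal(unname(back[[id]]$cds), unname(sim$genes[[id]]$cds))
  }
})

test_that("gene_model enforces its invariants", {
  expect_error(gene_model("g", "c", 10, 5, "+", cbind(10, 5)), "start > end")
  expect_error(gene_model("g", "c", 1, 100, "*", cbind(1, 10)), "strand")
  expect_error(gene_model("g", "c", 1, 100, "+", cbind(c(1, 5), c(10, 20))),
               "overlapping")
  expect_error(gene_model("g", "c", 5, 100, "+", cbind(1, 10)),
               "outside gene span")
})

test_that("extract_cds concatenates segments in transcription order", {
  g <- c(c1 = "AAATTTGGG")
  expect_identical(extract_cds(g, gene_model("g", "c1", 4, 6, "+", cbind(4, 6))),
                   "TTT")
  expect_identical(extract_cds(g, gene_model("g", "c1", 4, 6, "-", cbind(4, 6))),
                   "AAA")
  g2 <- c(c1 = "ATGCCCTAA")
  gm <- gene_model("g", "c1", 1, 9, "+", cbind(c(1, 7), c(3, 9)))
  expect_identical(extract_cds(g2, gm), "ATGTAA")
  expect_error(extract_cds(c(cX = "AAA"), gm), "missing")
})

test_that("translate_cds follows the standard code with stop handling", {
  expect_identical(translate_cds("ATGGGATAA"), "MG")
  expect_error(translate_cds("ATGTAATAA"), "internal stop.*2")
  expect_error(translate_cds("ATGGG"), "not divisible")
  expect_identical(translate_cds("ATGANATAA"), "MX")
  # coding relation: a 675-aa protein with terminal stop has a 2028-nt CDS
  sim <- default_sim()
  id <- names(sim$cds)[1]
  expect_equal(nchar(sim$cds[[id]]), 3 * (nchar(sim$proteins[[id]]) + 1))
})

test_that("revcomp is a self-inverse over the IUPAC alphabet", {
  set.seed(3)
  for (rep in 1:10) {
    s <- paste(sample(names(wrkyscan:::IUPAC_NT), 50, TRUE), collapse = "")
    expect_identical(revcomp(revcomp(s)), s)
  }
  expect_error(revcomp("ACGZ"), "non-IUPAC")
})

test_that("extract_promoter anchors at the start codon and truncates at edges", {
  set.seed(11)
  bg <- paste(sample(c("A", "C", "G", "T"), 2100, TRUE), collapse = "")
  g <- c(c1 = bg)
  gm <- gene_model("g", "c1", 2001, 2100, "+", cbind(2001, 2100))
  p <- extract_promoter(g, gm, 2000)
  expect_identical(as.character(p), substring(bg, 1, 2000))
  expect_false(attr(p, "truncated"))
  # minus-strand gene ending at 100 on a 150 bp contig
  g2 <- c(c1 = substring(bg, 1, 150))
  gm2 <- gene_model("g", "c1", 50, 100, "-", cbind(50, 100))
  p2 <- extract_promoter(g2, gm2, 2000)
  expect_identical(as.character(p2), revcomp(substring(bg, 101, 150)))
  expect_equal(nchar(p2), 50)
  expect_true(attr(p2, "truncated"))
  # start codon at contig position 1: empty promoter with a warning
  gm3 <- gene_model("g", "c1", 1, 30, "+", cbind(1, 30))
  expect_warning(p3 <- extract_promoter(g2, gm3), "empty promoter")
  expect_identical(as.character(p3), "")
})

test_that("planted synthetic promoters are recovered exactly", {
  sim <- default_sim()
  for (id in names(sim$genes)) {
    p <- extract_promoter(sim$genome, sim$genes[[id]])
    expect_identical(as.character(p), unname(sim$promoters[[id]]))
    expect_identical(extract_cds(sim$genome, sim$genes[[id]]),
                     unname(as.character(sim$cds[[id]])))
  }
})
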