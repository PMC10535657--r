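test_that("smith_waterman on identical and dissimilar sequences", {
  a <- "MKWVTFISLLLLFSSAYS"
  r <- smith_waterman(a, a)
  expect_equal(r$identity_pct, 100)
  expect_equal(r$similarity_pct, 100)
  expect_equal(r$aligned_length, nchar(a))
  # no positively scoring residue pairs -> empty alignment
  r0 <- smith_waterman("DDDD", "KKKK")
  expect_equal(r0$score, 0)
  expect_equal(r0$aligned_length, 0)
  expect_equal(r0$similarity_pct, 0)
})

test_that("smith_waterman score equals the brute-force DP oracle", {
  set.seed(31)
  aas <- rownames(blosum62)[1:20]
  for (rep in 1:100) {
    a <- paste(sample(aas, sample(4:8, 1), TRUE), collapse = "")
    b <- paste(sample(aas, sample(4:8, 1), TRUE), collapse = "")
    got <- smith_waterman(a, b)$score
    want <- sw_oracle_score(a, b, blosum62)
    expect_equal(got, max(want, 0), info = paste(a, b))
  }
})

test_that("smith_waterman is symmetric and monotone under extension", {
  set.seed(32)
  aas <- rownames(blosum62)[1:20]
  for (rep in 1:10) {
    a <- paste(sample(aas, 15, TRUE), collapse = "")
    b <- paste(sample(aas, 12, TRUE), collapse = "")
    expect_equal(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
    ext <- paste0(a, paste(sample(aas, 5, TRUE), collapse = ""))
    expect_gte(smith_waterman(ext, b)$score, smith_waterman(a, b)$score)
  }
})

test_that("classify_duplication applies distance and similarity criteria", {
  gm <- function(id, contig, start, end)
    gene_model(id, contig, start, end, "+", cbind(start, end))
  cfg <- duplication_config()
  aln85 <- list(similarity_pct = 85, aligned_length = 100)
  aln99 <- list(similarity_pct = 99, aligned_length = 100)
  aln65 <- list(similarity_pct = 65, aligned_length = 100)
  a <- gm("a", "c1", 1000, 2000)
  b_near <- gm("b", "c1", 52000, 53000)        # 50 kb apart
  b_far <- gm("b", "c1", 500000, 501000)       # 498 kb apart
  b_other <- gm("b", "c2", 1000, 2000)
  expect_equal(classify_duplication(a, b_near, aln85, cfg)$type, "tandem")
  expect_equal(classify_duplication(a, b_far, aln85, cfg)$type, "segmental")
  ev <- classify_duplication(a, b_other, aln85, cfg)
  expect_equal(ev$type, "segmental")
  expect_true(is.na(ev$genomic_distance))
  expect_null(classify_duplication(a, b_near, aln65, cfg))
  expect_true(classify_duplication(a, b_near, aln99, cfg)$recent)
  expect_false(classify_duplication(a, b_near, aln85, cfg)$recent)
  # the tandem window boundary is inclusive
  b_edge <- gm("b", "c1", 102000, 103000)      # gap exactly 100 kb
  expect_equal(classify_duplication(a, b_edge, aln85, cfg)$type, "tandem")
  # short local alignments never qualify
  expect_null(classify_duplication(a, b_near,
                                   list(similarity_pct = 100,
                                        aligned_length = 7), cfg))
})

test_that("planted duplication labels are recovered on synthetic fixtures", {
  for (seed in c(7L, 19L)) {
    sim <- default_sim(seed)
    dups <- find_duplications(sim$genes, sim$proteins)
    truth <- sim$truth$duplications
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    expect_setequal(key(dups$gene_a, dups$gene_b),
                    key(truth$gene_a, truth$gene_b))
    got <- setNames(dups$type, key(dups$gene_a, dups$gene_b))
    expect_identical(unname(got[key(truth$gene_a, truth$gene_b)]), truth$type)
  }
})

test_that("summarize_ages averages defined nonzero times per type", {
  ev <- data.frame(
    type = c("tandem", "tandem", "segmental", "segmental", "segmental"),
    time_mya = c(0.138938872, 16.41485794, 2, NaN, 0))
  s <- summarize_ages(ev)
  tan <- s[s$type == "tandem", ]
  expect_equal(tan$mean_mya, 8.2769, tolerance = 1e-4)
  expect_equal(tan$min_mya, 0.138938872)
  expect_equal(tan$max_mya, 16.41485794)
  seg <- s[s$type == "segmental", ]
  expect_equal(seg$mean_mya, 2)   # NaN excluded everywhere, 0 from the mean
  expect_equal(seg$min_mya, 0)    # but zero stays in the range
  # single defined time: mean = min = max
  s1 <- summarize_ages(data.frame(type = "tandem", time_mya = 3.5))
  expect_equal(unlist(s1[, c("mean_mya", "min_mya", "max_mya")]),
               c(mean_mya = 3.5, min_mya = 3.5, max_mya = 3.5))
  # no defined times
  s2 <- summarize_ages(data.frame(type = "tandem", time_mya = NaN))
  expect_true(is.nan(s2$mean_mya))
})
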