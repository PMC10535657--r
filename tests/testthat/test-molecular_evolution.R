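split3 <- function(s) substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))

test_that("build_codon_alignment maps residue pairs back to codons", {
  cds <- "ATGAAACCCGGGTTTTACTAA"
  aln <- smith_waterman(translate_cds(cds), translate_cds(cds))
  ca <- build_codon_alignment(cds, cds, aln)
  expect_equal(ca$n_codons, 6)
  expect_identical(ca$codons_a, ca$codons_b)
  expect_identical(ca$codons_a, split3(substring(cds, 1, 18)))
  # a gap column drops its codon: delete one residue from b
  cds_b <- "ATGAAACCCTTTTACTAA"        # GGG codon removed
  aln2 <- smith_waterman(translate_cds(cds), translate_cds(cds_b))
  ca2 <- build_codon_alignment(cds, cds_b, aln2)
  expect_lte(ca2$n_codons, 5)
  expect_false("GGG" %in% ca2$codons_a[ca2$codons_a == ca2$codons_b])
  # CDS/protein mismatch is an error
  expect_error(build_codon_alignment(cds, "ATGAAACCC", aln), "divisible|mismatch")
})

test_that("ng86 handles degenerate and saturated inputs like the field convention", {
  cds <- "ATGAAACCCGGGTTTTAC"
  r <- ng86(list(codons_a = split3(cds), codons_b = split3(cds)))
  expect_equal(r$ka, 0)
  expect_equal(r$ks, 0)
  expect_true(is.nan(r$ratio))
  expect_equal(r$selection, "undefined")
  # single codon pair TTT/TTC: one synonymous difference on 1/3 sites
  r2 <- ng86(list(codons_a = "TTT", codons_b = "TTC"))
  expect_equal(r2$counts$Sd, 1)
  expect_equal(r2$counts$S, 1 / 3)
  expect_true(is.nan(r2$ks))  # ps = 3 > 3/4: saturation, JC undefined
})

test_that("ng86 reproduces independently computed reference values", {
  # frozen from an independent NG86 implementation
  r <- ng86(list(codons_a = split3("ATGAAACCCGGGTTTTAC"),
                 codons_b = split3("ATGAAACCAGGGTTCTAC")))
  expect_equal(r$ka, 0, tolerance = 1e-8)
  expect_equal(r$ks, 1.64791843, tolerance = 1e-6)
  r2 <- ng86(list(codons_a = split3("ATGAAACCCGGGTTTTACGAT"),
                  codons_b = split3("ATGAAGCCAGGGTATTACGAT")))
  expect_equal(r2$ka, 0.05885371, tolerance = 1e-6)
  expect_equal(r2$ks, 1.20707843, tolerance = 1e-6)
})

test_that("ng86 counts match the exhaustive-pathway oracle on small pairs", {
  set.seed(41)
  gc <- Biostrings::GENETIC_CODE
  sense <- names(gc)[gc != "*"]
  for (rep in 1:25) {
    n <- sample(1:6, 1)
    a <- sample(sense, n, replace = TRUE)
    b <- sample(sense, n, replace = TRUE)
    got <- ng86(list(codons_a = a, codons_b = b))
    want <- ng86_oracle(a, b)
    expect_equal(got$counts$N + got$counts$S, 3 * n)  # exact conservation
    expect_equal(got$counts$N, want$N, tolerance = 1e-12)
    expect_equal(got$counts$Sd, want$Sd, tolerance = 1e-12)
    expect_equal(got$counts$Nd, want$Nd, tolerance = 1e-12)
    # symmetry
    rev <- ng86(list(codons_a = b, codons_b = a))
    expect_equal(got$counts, rev$counts, tolerance = 1e-12)
  }
})

test_that("selection_class follows the ratio thresholds", {
  expect_equal(selection_class(0.4954089), "negative")
  expect_equal(selection_class(1.2), "positive")
  expect_equal(selection_class(1), "neutral")
  expect_equal(selection_class(NaN), "undefined")
  expect_equal(selection_class(0.95, neutral_tolerance = 0.1), "neutral")
})

test_that("divergence_time applies T = k/(2r) * 1e-6 and its calibrations", {
  cfg <- evolution_config()
  expect_equal(divergence_time(0, cfg), 0)
  expect_true(is.nan(divergence_time(NaN, cfg)))
  # the published formula on a published Ks does NOT give the printed time
  expect_equal(divergence_time(0.0116, cfg), 0.95082, tolerance = 1e-4)
  # the table2-compat preset (Ka at 6.56e-9) reproduces the printed times
  compat <- evolution_config(preset = "table2-compat")
  expect_equal(divergence_time(0.0018229, compat), 0.138938872,
               tolerance = 1e-3)
  expect_equal(divergence_time(0.9085855, compat), 69.25193994,
               tolerance = 1e-3)
  # linear in k, inverse-linear in rate
  expect_equal(divergence_time(0.2, cfg), 2 * divergence_time(0.1, cfg))
  expect_equal(divergence_time(0.1, evolution_config(rate_r = 1.22e-8)),
               divergence_time(0.1, cfg) / 2)
})

test_that("kaks_pair recovers simulated omega in closed loop (small n)", {
  set.seed(43)
  cds <- rand_cds(150)
  est <- replicate(10, {
    mut <- evolve_pair(cds, omega = 0.2, target_ks = 0.3)
    kaks_pair(cds, as.character(mut))$ratio
  })
  expect_lt(abs(median(est) - 0.2), 0.15)
  expect_true(all(est < 1))
})
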