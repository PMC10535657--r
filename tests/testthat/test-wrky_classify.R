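mk_zf_tail <- function(type = c("C2H2", "C2HC")) {
  type <- match.arg(type)
  f <- function(n) strrep("A", n)
  if (type == "C2H2") paste0(f(5), "C", f(4), "C", f(22), "H", f(1), "H")
  else paste0(f(5), "C", f(7), "C", f(23), "H", f(1), "C")
}

test_that("scan_heptapeptide finds cores and variant strings", {
  h <- scan_heptapeptide("MKWRKYGQKA", "p")
  expect_equal(nrow(h), 1)
  expect_equal(h$hept_start, 3)
  expect_equal(h$hept_variant, "WRKYGQK")

  h2 <- scan_heptapeptide(paste0("AAWRKYGKKAA", strrep("A", 30), "AAWRKYGQK"), "p")
  expect_equal(h2$hept_variant, c("WRKYGKK", "WRKYGQK"))

  expect_equal(nrow(scan_heptapeptide("MKKKR")), 0)

  # non-canonical seventh residue degrades to the conserved 5-mer variant
  expect_equal(scan_heptapeptide("AWRKYGAXA")$hept_variant, "WRKYG")
})

test_that("detect_zinc_finger recognizes C2H2 and C2HC spacings", {
  for (type in c("C2H2", "C2HC")) {
    prot <- paste0("MAA", "WRKYGQK", mk_zf_tail(type), "AAA")
    hit <- detect_zinc_finger(prot, scan_heptapeptide(prot, "p"))
    expect_equal(hit$zf_type, type)
    expect_gt(hit$zf_start, hit$hept_start)
  }
  bare <- paste0("MAA", "WRKYGQK", strrep("A", 40))
  expect_equal(detect_zinc_finger(bare, scan_heptapeptide(bare, "p"))$zf_type,
               "none")
})

test_that("assign_group applies the family rules with documented precedence", {
  two_c2h2 <- paste0("M", "WRKYGQK", mk_zf_tail("C2H2"), strrep("A", 10),
                     "WRKYGQK", mk_zf_tail("C2H2"))
  one_c2hc <- paste0("M", "WRKYGQK", mk_zf_tail("C2HC"))
  one_c2h2 <- paste0("M", "WRKYGQK", mk_zf_tail("C2H2"))
  hept_only <- paste0("M", "WRKYGQK", strrep("A", 50))
  mixed <- paste0("M", "WRKYGQK", mk_zf_tail("C2H2"), strrep("A", 10),
                  "WRKYGQK", mk_zf_tail("C2HC"))
  expect_equal(assign_group(scan_domains(two_c2h2))$group, "I")
  expect_equal(assign_group(scan_domains(one_c2h2))$group, "II")
  expect_equal(assign_group(scan_domains(one_c2hc))$group, "III")
  expect_equal(assign_group(scan_domains(hept_only))$group, "IV")
  expect_equal(assign_group(scan_domains("MKKKRAAA"))$group, "none")
  # mixed fingers: not group I; decided by the C-terminal complete domain
  expect_equal(assign_group(scan_domains(mixed))$group, "III")
  # two heptapeptides, one complete finger: grouped by the complete one
  partial <- paste0("M", "WRKYGQK", strrep("A", 40), "WRKYGQK",
                    mk_zf_tail("C2H2"))
  expect_equal(assign_group(scan_domains(partial))$group, "II")
})

test_that("assign_group is deterministic and order-invariant", {
  prot <- paste0("M", "WRKYGQK", mk_zf_tail("C2H2"), strrep("A", 10),
                 "WRKYGQK", mk_zf_tail("C2H2"))
  hits <- scan_domains(prot)
  expect_identical(assign_group(hits)$group,
                   assign_group(hits[rev(seq_len(nrow(hits))), ])$group)
})

test_that("classification recovers planted groups on synthetic families", {
  sim <- default_sim()
  cl <- classify_proteins(sim$proteins)
  truth <- sim$truth$genes
  expect_identical(cl$group,
                   truth$group[match(cl$protein_id, truth$gene_id)])
  expect_equal(sum(table(cl$group)), length(sim$proteins))
})

test_that("assign_subgroup co-clusters queries with labeled references", {
  refs <- read_fasta(system.file("extdata", "wrky_subgroup_refs_synthetic.fasta",
                                 package = "wrkyscan"))
  # a query identical to a reference joins its subgroup
  q <- setNames(refs[["IIb_ref1|IIb"]], "query1")
  expect_equal(unname(assign_subgroup(q, refs)), "IIb")
  # IIc-derived mutants are recovered as IIc
  set.seed(5)
  mutate <- function(s, n) {
    ch <- strsplit(s, "")[[1]]
    idx <- sample(setdiff(which(!(ch %in% c("C", "H"))), 1:7), n)
    for (i in idx) ch[i] <- sample(setdiff(LETTERS[LETTERS %in% rownames(wrkyscan:::DIWV)], ch[i]), 1)
    paste(ch, collapse = "")
  }
  qs <- setNames(vapply(1:3, function(i) mutate(refs[["IIc_ref1|IIc"]], 3),
                        character(1)), paste0("q", 1:3))
  expect_true(all(assign_subgroup(qs, refs) == "IIc"))
  # empty query list, and a reference set missing a subgroup
  expect_length(assign_subgroup(setNames(character(0), character(0)), refs), 0)
  expect_error(assign_subgroup(q, refs[!grepl("IId", names(refs))]),
               "missing subgroup.*IId")
})
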