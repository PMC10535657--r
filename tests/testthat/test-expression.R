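test_that("fpkm applies the per-kilobase per-million formula", {
  counts <- matrix(c(10L, 999990L), 2, 1,
                   dimnames = list(c("g1", "g2"), "s1"))
  lengths <- c(g1 = 1000, g2 = 1000)
  f <- fpkm(counts, lengths)
  expect_equal(f["g1", "s1"], 10)        # 10 * 1e9 / (1000 * 1e6)
  counts2 <- cbind(counts, s2 = c(0L, 10L))
  f2 <- fpkm(counts2, lengths)
  expect_equal(f2["g1", "s2"], 0)        # zero count <-> zero FPKM
  # scale invariance: doubling a sample's counts leaves FPKM unchanged
  expect_equal(fpkm(counts * 2L, lengths), f)
  # column-sum identity: sum_g FPKM * length = 1e9
  set.seed(61)
  cm <- matrix(rpois(50, 100) + 1L, 10, 5,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:5)))
  ll <- setNames(sample(200:3000, 10), paste0("g", 1:10))
  ff <- fpkm(cm, ll)
  expect_equal(unname(colSums(ff * ll)), rep(1e9, 5))
  # zero column total is an error naming the sample
  cm0 <- cm; cm0[, 2] <- 0L
  expect_error(fpkm(cm0, ll), "s2")
})

test_that("expressed_sets computes proportions, Venn partitions and the common set", {
  # the published light-sample tally: 24,491 expressed of 36,405 -> 67%
  f1 <- matrix(c(rep(1, 24491), rep(0, 36405 - 24491)), ncol = 1,
               dimnames = list(paste0("g", 1:36405), "red"))
  r <- expressed_sets(f1, annotated_total = 36405)
  expect_equal(unname(r$proportion_pct), 67)

  f <- matrix(c(1, 1, 0,
                1, 0, 0,
                1, 1, 1,
                0, 0, 0), 4, 3, byrow = TRUE,
              dimnames = list(paste0("g", 1:4), c("a", "b", "c")))
  r2 <- expressed_sets(f, annotated_total = 4)
  expect_equal(unname(r2$n_expressed), c(3, 2, 1))
  expect_equal(r2$common, "g3")
  expect_equal(unname(r2$venn[c("a", "a&b", "a&b&c")]), c(1, 1, 1))
  expect_equal(sum(r2$venn), r2$n_union)
  # an empty sample contributes nothing
  expect_equal(unname(r2$venn["c"]), 0)
  # raising the threshold never grows a set
  r3 <- expressed_sets(f, annotated_total = 4, threshold = 0.5)
  expect_true(all(r3$n_expressed <= r2$n_expressed))
  expect_error(expressed_sets(f, annotated_total = 0), "positive")
})

test_that("planted expression truth is recovered (closed loop)", {
  sim <- default_sim()
  cm <- simulate_counts(sim)
  f <- fpkm(cm$counts, cm$lengths)
  r <- expressed_sets(f, annotated_total = nrow(f))
  for (s in colnames(cm$counts)) {
    expect_setequal(r$expressed[[s]], rownames(cm$expressed)[cm$expressed[, s]])
  }
  expect_setequal(r$common,
                  rownames(cm$expressed)[rowSums(cm$expressed) ==
                                           ncol(cm$expressed)])
  # silent genes are zero everywhere
  silent <- rownames(cm$counts)[rowSums(cm$expressed) == 0]
  expect_true(all(cm$counts[silent, ] == 0))
})

test_that("log_matrix is log2(FPKM + 1)", {
  f <- matrix(c(0, 1, 3), 3, 1, dimnames = list(c("a", "b", "c"), "s"))
  lm <- log_matrix(f)
  expect_equal(unname(lm[, 1]), c(0, 1, 2))
})

test_that("classical_mds embeds sample profiles", {
  # two samples at log-distance d -> coordinates +/- d/2
  f <- matrix(c(3, 0, 1, 1), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  co <- classical_mds(f, k = 1)
  d <- sqrt(sum((log2(f[, 1] + 1) - log2(f[, 2] + 1))^2))
  expect_equal(unname(co[, 1]), c(d / 2, -d / 2))
  expect_gte(co[1, 1], 0)
  # three samples, k = 2: embedded distances reproduce the inputs
  set.seed(62)
  f3 <- matrix(runif(30, 0, 50), 10, 3,
               dimnames = list(paste0("g", 1:10), paste0("s", 1:3)))
  co3 <- classical_mds(f3, k = 2)
  expect_equal(unname(as.matrix(dist(co3))),
               unname(as.matrix(dist(t(log_matrix(f3))))), tolerance = 1e-9)
  # identical samples collapse to the origin
  f0 <- matrix(rep(c(1, 5, 9), 3), 3, 3,
               dimnames = list(paste0("g", 1:3), paste0("s", 1:3)))
  expect_true(all(abs(classical_mds(f0, k = 2)) < 1e-9))
  expect_error(classical_mds(f3, k = 3), "smaller")
})
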