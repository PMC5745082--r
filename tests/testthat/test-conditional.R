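# Small hand-checkable panel: 1 essential gene, disruption 0.99, weight 1
single_gene_setup <- function(paf = 0.99) {
  dm <- matrix(paf, 1, 1, dimnames = list("S1", "g1"))
  ess <- essentiality_table(
    data.frame(condition = "c1", gene = "g1", fdr_p = 0.1))
  list(dm = dm, ess = ess)
}

test_that("strain divergence is the mean log-survival", {
  expect_identical(strain_divergence(matrix(0, 2, 3)), c(0, 0))
  m <- matrix(0.99, 1, 1, dimnames = list("S1", "g1"))
  expect_equal(unname(strain_divergence(m)), log(0.01), tolerance = 1e-12)
  # appending zero-disruption genes halves |E_s|
  m2 <- cbind(m, g2 = 0)
  expect_equal(strain_divergence(m2), strain_divergence(m) / 2)
  expect_true(all(strain_divergence(matrix(runif(20, 0, 0.99), 4, 5)) <= 0))
  expect_error(strain_divergence(matrix(numeric(0), 1, 0)), "empty")
  expect_error(strain_divergence(matrix(1, 1, 1)), "below 1")
})

test_that("gene weights follow the three modes", {
  expect_equal(gene_weight(0.05, 1, 100), 0.0130103, tolerance = 1e-6)
  expect_identical(gene_weight(0.1, 5, 20, mode = "uniform"), 1)
  # as_rendered and inverted agree only when C_g = N_c
  expect_equal(gene_weight(0.01, 7, 7), gene_weight(0.01, 7, 7, "inverted"))
  expect_false(gene_weight(0.01, 2, 7) == gene_weight(0.01, 2, 7, "inverted"))
  expect_error(gene_weight(0.5, 0, 10), "c_g")
  expect_error(gene_weight(0.5, 11, 10), "c_g")
  expect_warning(w0 <- gene_weight(0, 1, 10), "clipped")
  expect_true(is.finite(w0) && w0 > 0)
})

test_that("single-gene worked example gives S = S_max = 1", {
  s <- single_gene_setup()
  cs <- conditional_score(s$dm, s$ess, weight_mode = "uniform")
  expect_equal(unname(cs$S["S1", "c1"]), 1, tolerance = 1e-12)
  expect_equal(unname(cs$S_max["S1", "c1"]), 1, tolerance = 1e-12)
  expect_equal(unname(max_score(c(g1 = 1), log(0.01), 0.99)), 1,
               tolerance = 1e-12)
  expect_identical(unname(max_score(c(g1 = 1), 0, 0.99)), 0)
  expect_identical(unname(max_score(c(g1 = 1), log(0.01), 0)), 0)
  expect_error(max_score(c(g1 = 1), log(0.01), 1), "below 1")
})

test_that("scores are non-negative, zero outside the set, monotone in P(AF)", {
  set.seed(22)
  dm <- matrix(runif(60, 0, 0.99), 6, 10,
               dimnames = list(paste0("S", 1:6), paste0("g", 1:10)))
  dm[2, ] <- 0                              # reference-like strain
  dm[3, 1:3] <- 0                           # zero inside the set only
  ess <- essentiality_table(
    data.frame(condition = rep("c1", 3), gene = paste0("g", 1:3),
               fdr_p = c(0.01, 0.02, 0.04)))
  cs <- conditional_score(dm, ess)
  expect_true(all(cs$S >= 0))
  expect_identical(unname(cs$S["S2", "c1"]), 0)   # E_s = 0 strain
  expect_identical(unname(cs$S["S3", "c1"]), 0)   # no set disruption
  expect_true(all(cs$S <= cs$S_max + 1e-12))
  # raising one set gene's disruption with the divergence term held fixed
  # never lowers S (each summand is increasing in P(AF))
  w <- cs$weights[["c1"]]
  e <- cs$E_s[["S4"]]
  for (step in c(0.05, 0.1, 0.2)) {
    p2 <- pmin(dm["S4", names(w)] + c(step, 0, 0), 0.99)
    s_stepped <- sum(w * log1p(-p2)) / e
    expect_gte(s_stepped, cs$S["S4", "c1"] - 1e-12)
  }
})

test_that("weights scale S and S_max linearly without changing restorability", {
  set.seed(23)
  dm <- matrix(runif(40, 0, 0.99), 4, 10,
               dimnames = list(paste0("S", 1:4), paste0("g", 1:10)))
  genes <- paste0("g", 1:4)
  f <- c(0.01, 0.03, 0.002, 0.04)
  ess1 <- essentiality_table(data.frame(condition = "c1", gene = genes,
                                        fdr_p = f))
  ess2 <- essentiality_table(data.frame(condition = "c1", gene = genes,
                                        fdr_p = f^3))  # triples -log10 F
  cs1 <- conditional_score(dm, ess1)
  cs2 <- conditional_score(dm, ess2)
  expect_equal(cs2$S, 3 * cs1$S, tolerance = 1e-12)
  expect_equal(cs2$S_max, 3 * cs1$S_max, tolerance = 1e-12)
  ca1 <- complement_all(cs1, dm); ca2 <- complement_all(cs2, dm)
  expect_identical(ca1$restorable, ca2$restorable)
})

test_that("missing essential genes are skipped with a warning", {
  s <- single_gene_setup()
  ess <- essentiality_table(
    data.frame(condition = c("c1", "c1"), gene = c("g1", "ghost"),
               fdr_p = c(0.1, 0.1)))
  expect_warning(cs <- conditional_score(s$dm, ess, "uniform"), "missing")
  expect_identical(cs$skipped, "ghost")
  expect_equal(unname(cs$S["S1", "c1"]), 1, tolerance = 1e-12)
})

test_that("complementation deltas are the per-gene summands and add to S", {
  set.seed(24)
  dm <- matrix(runif(50, 0, 0.99), 5, 10,
               dimnames = list(paste0("S", 1:5), paste0("g", 1:10)))
  ess <- essentiality_table(
    data.frame(condition = rep(c("c1", "c2"), each = 3),
               gene = c("g1", "g2", "g3", "g2", "g4", "g5"),
               fdr_p = runif(6, 0.001, 0.04)))
  cs <- conditional_score(dm, ess)
  ca <- complement_all(cs, dm)
  # full additivity, exactly
  for (cd in c("c1", "c2")) {
    sums <- tapply(ca$delta[ca$condition == cd], ca$strain[ca$condition == cd],
                   sum)
    expect_equal(sums[rownames(dm)], cs$S[, cd], tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # delta equals the gene's own term; zero-disruption gene not restorable
  dm["S1", "g2"] <- 0
  cs0 <- conditional_score(dm, ess)
  d0 <- complement_delta(cs0, dm, "S1", "c1", "g2")
  expect_identical(d0$delta, 0)
  expect_false(d0$restorable)
  # single-gene panel: delta = S_max, restorable
  s <- single_gene_setup()
  cs1 <- conditional_score(s$dm, s$ess, "uniform")
  d1 <- complement_delta(cs1, s$dm, "S1", "c1", "g1")
  expect_equal(d1$delta, 1, tolerance = 1e-12)
  expect_true(d1$restorable)
  expect_error(complement_delta(cs1, s$dm, "S1", "c1", "g9"), "essential set")
  expect_error(complement_delta(cs1, s$dm, "S1", "nope", "g1"), "condition")
})

test_that("restoration counts recover the planted causal gene", {
  panel <- gen_strain_panel(50, 100, 4, params = noiseless_params(),
                            seed = 25)
  dm <- disruption_matrix(panel$variants, panel$presence, panel$distances)
  cs <- conditional_score(dm, panel$essentiality)
  ca <- complement_all(cs, dm)
  counts <- restoration_counts(ca)
  tr <- panel$truth
  # each planted (strain, condition, causal gene) triple is counted
  expected <- integer(0)
  for (cd in tr$conditions) {
    set <- tr$essential_sets[[cd]]
    lost <- tr$lost[, set, drop = FALSE]
    tab <- colSums(lost)
    expected <- c(expected, tab)
  }
  expected <- tapply(expected, names(expected), sum)
  for (g in names(expected)[expected > 0])
    expect_identical(counts[[g]], as.integer(expected[[g]]))
  # counts invariant to row order of the deltas
  expect_identical(counts, restoration_counts(ca[sample(nrow(ca)), ]))
  # no disruption anywhere: all counts zero
  dm0 <- dm; dm0[] <- 0
  suppressWarnings(cs0 <- conditional_score(dm0, panel$essentiality))
  expect_true(all(restoration_counts(complement_all(cs0, dm0)) == 0))
})
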