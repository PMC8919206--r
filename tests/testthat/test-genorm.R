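test_that("relative quantities follow Q = A^(minCq - Cq)", {
  m <- rbind(g1 = c(20, 21, 22), g2 = c(25, 25, 25))
  colnames(m) <- paste0("S", 1:3)
  q <- relative_quantities(m, 2)
  expect_equal(unname(q["g1", ]), c(1, 0.5, 0.25))
  expect_equal(unname(q["g2", ]), c(1, 1, 1))

  m2 <- rbind(g1 = c(20, 21)); colnames(m2) <- c("S1", "S2")
  q2 <- relative_quantities(rbind(m2, g2 = c(30, 30)), 1.948)
  expect_equal(unname(q2["g1", ]), c(1, 1 / 1.948))

  expect_error(relative_quantities(m, 1), "exceed 1")
  expect_error(relative_quantities(m, c(2, 2, 2)), "one amplification factor")
})

test_that("pair variation matches hand-computed toy values", {
  q <- relative_quantities(toy_cq(), 2)
  expect_equal(genorm_pair_variation(q, "A", "B"), 0.0816497, tolerance = 1e-6)
  expect_equal(genorm_pair_variation(q, "A", "C"), 0.6454972, tolerance = 1e-6)
  expect_equal(genorm_pair_variation(q, "B", "C"), 0.5686241, tolerance = 1e-6)
  # constant Cq offset between genes => constant ratio => zero variation
  m <- rbind(g1 = c(20, 22, 21, 24), g2 = c(23, 25, 24, 27))
  colnames(m) <- paste0("S", 1:4)
  expect_equal(genorm_pair_variation(relative_quantities(m), "g1", "g2"), 0)
  # permutation invariance in sample order
  perm <- sample(ncol(q))
  expect_equal(genorm_pair_variation(q[, perm], "A", "C"),
               genorm_pair_variation(q, "A", "C"))
  expect_error(genorm_pair_variation(q, "A", "A"), "differ")
})

test_that("iterative exclusion reproduces the toy ranking with a tied top pair", {
  q <- relative_quantities(toy_cq(), 2)
  r <- genorm_rank(q)
  rk <- r$ranking
  expect_equal(rk$m_value[rk$gene == "C"], 0.6070607, tolerance = 1e-6)
  expect_equal(rk$m_value[rk$gene == "A"], rk$m_value[rk$gene == "B"])
  expect_equal(rk$m_value[rk$gene == "A"], 0.0816497, tolerance = 1e-6)
  expect_identical(rk$rank[match(c("A", "B", "C"), rk$gene)], c(1L, 1L, 3L))
  expect_identical(r$stability_order, c("A", "B", "C"))
  expect_error(genorm_rank(q[1:2, ]), ">= 3 genes")
})

test_that("the two last-surviving genes always tie (property over random inputs)", {
  for (seed in 1:20) {
    q <- relative_quantities(random_cq(sample(3:8, 1), sample(4:10, 1), seed))
    rk <- genorm_rank(q)$ranking
    top <- rk[rk$rank == 1L, ]
    expect_identical(nrow(top), 2L)
    expect_equal(top$m_value[1], top$m_value[2])
  }
})

test_that("geNorm agrees with the naive brute-force implementation", {
  for (seed in 21:30) {
    cq <- random_cq(6, 8, seed)
    bf <- bf_genorm(cq)
    rk <- genorm_rank(relative_quantities(cq))$ranking
    expect_equal(stats::setNames(rk$m_value, rk$gene), bf$m, tolerance = 1e-10)
  }
})

test_that("M values are invariant to loading shifts and per-gene offsets", {
  cq <- random_cq(5, 10, seed = 77)
  q <- relative_quantities(cq)
  base <- genorm_rank(q)$ranking$m_value
  set.seed(1)
  loading <- rnorm(ncol(cq))
  shifted <- sweep(cq, 2L, loading, "+")
  expect_equal(genorm_rank(relative_quantities(shifted))$ranking$m_value,
               base, tolerance = 1e-12)
  gene_off <- rnorm(nrow(cq))
  offset <- sweep(cq, 1L, gene_off, "+")
  expect_equal(genorm_rank(relative_quantities(offset))$ranking$m_value,
               base, tolerance = 1e-12)
})

test_that("normalization factors are geometric means of the chosen genes", {
  q <- relative_quantities(toy_cq(), 2)
  expect_equal(normalization_factor(q, "A"), q["A", ])
  expect_equal(normalization_factor(q, c("A", "B")),
               sqrt(q["A", ] * q["B", ]), tolerance = 1e-12)
  # reciprocal pattern: geometric mean constant
  qq <- rbind(g1 = c(0.2, 0.5, 1), g2 = c(1, 0.4, 0.2))
  colnames(qq) <- paste0("S", 1:3)
  nf <- normalization_factor(qq, c("g1", "g2"))
  expect_equal(unname(nf), sqrt(c(0.2, 0.2, 0.2)), tolerance = 1e-12)
  expect_error(normalization_factor(q, character(0)), "at least one")
})

test_that("V profile matches brute force and collapses for proportional genes", {
  exp <- simulate_cq_experiment(n_genes = 6, n_samples = 12, seed = 101)
  m <- average_technical_replicates(exp$replicates)
  q <- relative_quantities(m)
  r <- genorm_rank(q)
  pv <- pairwise_variation_profile(q, r)
  expect_equal(pv$profile$v, bf_v_profile(q, r$stability_order),
               tolerance = 1e-12)
  expect_identical(pv$profile$n, 2:5)

  # genes that are exact scalar multiples in q (constant Cq offsets)
  base <- c(20, 22, 21, 23, 24)
  cq <- rbind(g1 = base, g2 = base + 1, g3 = base + 2, g4 = base - 1)
  colnames(cq) <- paste0("S", 1:5)
  pv0 <- pairwise_variation_profile(relative_quantities(cq))
  expect_equal(pv0$profile$v, rep(0, 2))
  expect_identical(pv0$recommended_n, 2L)
})

test_that("recommended n is the first V below threshold", {
  cq <- constructed_v4_matrix()
  q <- relative_quantities(cq, 2)
  pv <- pairwise_variation_profile(q)
  expect_false(pv$profile$below_threshold[pv$profile$n == 2])
  expect_false(pv$profile$below_threshold[pv$profile$n == 3])
  expect_true(pv$profile$below_threshold[pv$profile$n == 4])
  expect_identical(pv$recommended_n, 4L)
  # above-threshold everywhere: no recommendation
  pv_hi <- pairwise_variation_profile(q, threshold = 1e-6)
  expect_true(is.na(pv_hi$recommended_n))
})
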