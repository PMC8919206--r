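test_that("sample centering removes column means", {
  m <- toy_cq()
  z <- center_by_sample(m)
  expect_equal(unname(colSums(z)), rep(0, 4), tolerance = 1e-12)
  expect_equal(unname(z["A", ]), c(-1, -1.366667, -0.8, -1.166667),
               tolerance = 1e-6)
  same <- rbind(g1 = c(20, 21), g2 = c(20, 21), g3 = c(20, 21))
  colnames(same) <- c("S1", "S2")
  expect_equal(unname(center_by_sample(same)), matrix(0, 3, 2))
})

test_that("ungrouped stability matches the hand-evaluated toy case", {
  r <- normfinder_ungrouped(toy_cq())$ranking
  expect_equal(r$sigma2[match(c("A", "B", "C"), r$gene)],
               c(0.05, 0, 0.3666667), tolerance = 1e-6)
  expect_equal(r$stability[match(c("A", "B", "C"), r$gene)],
               c(0.2236068, 0, 0.6055301), tolerance = 1e-6)
  expect_identical(r$rank[match(c("B", "A", "C"), r$gene)], c(1L, 2L, 3L))
  expect_error(normfinder_ungrouped(toy_cq()[1:2, ]), ">= 3 genes")
})

test_that("pure loading data yields zero stability for every gene", {
  b <- c(20, 25, 18, 30)
  L <- c(0, 1.5, -0.7, 0.3, 2, -1)
  m <- outer(b, L, "+")
  dimnames(m) <- list(paste0("g", 1:4), paste0("S", 1:6))
  r <- normfinder_ungrouped(m)$ranking
  expect_equal(r$stability, rep(0, 4), tolerance = 1e-12)
})

test_that("ungrouped estimator agrees with brute force and is invariant", {
  for (seed in 31:40) {
    cq <- random_cq(5, 8, seed)
    expect_equal(normfinder_ungrouped(cq)$ranking$stability,
                 unname(bf_normfinder_ungrouped(cq)), tolerance = 1e-10)
  }
  cq <- random_cq(6, 10, seed = 50)
  base <- normfinder_ungrouped(cq)$ranking$stability
  set.seed(2)
  shifted <- sweep(cq, 2L, rnorm(ncol(cq)), "+")  # loading
  offset <- sweep(cq, 1L, rnorm(nrow(cq)), "+")   # primer offsets
  expect_equal(normfinder_ungrouped(shifted)$ranking$stability, base,
               tolerance = 1e-12)
  expect_equal(normfinder_ungrouped(offset)$ranking$stability, base,
               tolerance = 1e-12)
  # permutation invariance in gene and sample order
  gp <- sample(nrow(cq)); sp <- sample(ncol(cq))
  perm <- normfinder_ungrouped(cq[gp, sp])$ranking
  expect_equal(perm$stability[match(rownames(cq), perm$gene)], base,
               tolerance = 1e-12)
})

test_that("ungrouped estimator recovers configured noise SDs in simulation", {
  sigma <- seq(0.05, 1.2, length.out = 12)
  est <- matrix(0, 100, 12)
  for (s in 1:100) {
    exp <- simulate_cq_experiment(n_samples = 200, n_reps = 1, tech_sd = 0,
                                  loading_sd = 1, gene_noise_sd = sigma,
                                  seed = s)
    m <- average_technical_replicates(exp$replicates)
    est[s, ] <- normfinder_ungrouped(m)$ranking$stability
  }
  mean_est <- colMeans(est)
  big <- sigma >= 0.2
  expect_true(all(abs(mean_est[big] - sigma[big]) / sigma[big] < 0.10))
})

test_that("grouped analysis validates its group structure", {
  cq <- random_cq(4, 8, seed = 60)
  expect_error(normfinder_grouped(cq, rep("a", 8)), ">= 2 groups")
  expect_error(normfinder_grouped(cq, c(rep("a", 6), "b", "b")),
               "fewer than 3 samples: b")
  ann <- data.frame(sample = colnames(cq), group = rep(c("a", "b"), each = 4))
  r <- normfinder_grouped(cq, ann)
  expect_identical(dim(r$d), c(4L, 2L))
  expect_equal(r$n_per_group, c(a = 4, b = 4))
})

test_that("gamma2 clamps to zero when group scatter is below sampling noise", {
  # no true group effects and modest n: observed d variance < mean noise
  set.seed(123)
  cq <- sweep(matrix(rnorm(5 * 12, 0, 1), 5), 1L, c(20, 22, 24, 26, 28), "+")
  dimnames(cq) <- list(paste0("g", 1:5), paste0("S", 1:12))
  r <- normfinder_grouped(cq, rep(c("a", "b"), each = 6))
  if (r$gamma2 == 0) {
    expect_equal(unname(r$d_shrunk), matrix(0, 5, 2), tolerance = 1e-12)
  } else {
    expect_true(all(abs(r$d_shrunk) < abs(r$d) + 1e-12))
  }
})

test_that("a group-shifted gene scores worse than its unshifted twin", {
  worse <- 0L
  for (s in 1:100) {
    set.seed(s)
    n_g <- 20
    # two identical-noise twins g1/g2 plus three fillers; +1 cycle for g1
    # in group b only
    cq <- sweep(matrix(rnorm(5 * 2 * n_g, 0, 0.3), 5), 1L,
                c(20, 20, 24, 26, 28), "+")
    dimnames(cq) <- list(paste0("g", 1:5), paste0("S", 1:(2 * n_g)))
    grp <- rep(c("a", "b"), each = n_g)
    cq["g1", grp == "b"] <- cq["g1", grp == "b"] + 1
    r <- normfinder_grouped(cq, grp)$ranking
    if (r$stability[r$gene == "g1"] > r$stability[r$gene == "g2"]) {
      worse <- worse + 1L
    }
  }
  expect_gte(worse, 95L)
})
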