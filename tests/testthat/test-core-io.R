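test_that("wide tables round-trip bit-identically through write and read", {
  m <- random_cq(3, 4, seed = 11)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_cq_table(m, p)
  back <- read_cq_table(p, "wide")
  expect_identical(dim(back), dim(m))
  expect_identical(dimnames(back), dimnames(m))
  expect_identical(as.vector(back), as.vector(m))

  pc <- withr::local_tempfile(fileext = ".csv")
  write_cq_table(m, pc)
  expect_identical(read_cq_table(pc, "wide"), back)
})

test_that("long tables preserve record counts and round-trip values", {
  exp <- simulate_cq_experiment(n_genes = 4, n_samples = 5, n_reps = 2,
                                seed = 3)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_cq_table(exp$replicates, p)
  back <- read_cq_table(p, "long")
  expect_equal(nrow(back), 2 * 4 * 5)
  expect_identical(back$cq, exp$replicates$cq)
  expect_identical(back$sample, exp$replicates$sample)
})

test_that("missing cells survive a round trip as NA, not zero", {
  m <- random_cq(3, 4, seed = 5)
  m["g2", "S3"] <- NA
  p <- withr::local_tempfile(fileext = ".tsv")
  write_cq_table(m, p)
  back <- read_cq_table(p, "wide", allow_missing = TRUE)
  expect_true(is.na(back["g2", "S3"]))
  expect_identical(back[!is.na(back)], m[!is.na(m)])
  expect_error(read_cq_table(p, "wide", allow_missing = FALSE), "missing")
})

test_that("malformed cells and duplicate rows are rejected with names", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tS1\tS2", "g1\t20.1\ttwenty", "g2\t21\t22"), p)
  expect_error(read_cq_table(p, "wide"), "twenty.*g1.*S2")
  writeLines(c("gene\tS1\tS2", "g1\t20\t21", "g1\t20\t21"), p)
  expect_error(read_cq_table(p, "wide"), "duplicate gene")
  writeLines(c("gene\tS1", "g1\t20"), p)
  expect_error(read_cq_table(p, "long"), "missing: sample")
})

test_that("replicate averaging equals the arithmetic mean cell by cell", {
  reps <- data.frame(sample = rep("S1", 3), gene = rep("g1", 3),
                     replicate = 1:3, cq = c(20, 21, 22))
  expect_equal(average_technical_replicates(reps)["g1", "S1"], 21)
  reps$cq <- c(20, 20, 20)
  expect_equal(average_technical_replicates(reps)["g1", "S1"], 20)

  exp <- simulate_cq_experiment(seed = 7)  # 12 x 36 x 3 default design
  m <- average_technical_replicates(exp$replicates)
  expect_equal(dim(m), c(12L, 36L))
  r <- exp$replicates
  for (cell in list(c("gene01", "S01"), c("gene07", "S19"), c("gene12", "S36"))) {
    vals <- r$cq[r$gene == cell[1] & r$sample == cell[2]]
    expect_equal(m[cell[1], cell[2]], sum(vals) / length(vals))
  }
  full <- tapply(r$cq, list(factor(r$gene, rownames(m)),
                            factor(r$sample, colnames(m))), mean)
  expect_equal(unname(m), unname(as.matrix(full)))
})

test_that("averaging is replicate-order invariant and idempotent on 1-rep data", {
  exp <- simulate_cq_experiment(n_genes = 3, n_samples = 4, n_reps = 3, seed = 9)
  r <- exp$replicates
  set.seed(1)
  shuffled <- r[sample(nrow(r)), ]
  # first-seen order differs after shuffling; compare on aligned dimnames
  m1 <- average_technical_replicates(r)
  m2 <- average_technical_replicates(shuffled)
  expect_equal(m2[rownames(m1), colnames(m1)], m1)
  one <- r[r$replicate == 1L, ]
  m3 <- average_technical_replicates(one)
  again <- data.frame(sample = rep(colnames(m3), each = nrow(m3)),
                      gene = rep(rownames(m3), ncol(m3)),
                      replicate = 1L, cq = as.vector(m3))
  expect_equal(average_technical_replicates(again)[rownames(m3), colnames(m3)],
               m3)
})

test_that("validation reports range, missingness and dimension violations", {
  exp <- simulate_cq_experiment(seed = 2)
  m <- average_technical_replicates(exp$replicates)
  expect_identical(nrow(validate_cq_matrix(m)), 0L)

  m["gene03", "S05"] <- 50
  v <- validate_cq_matrix(m)
  expect_identical(v$type, "range")
  expect_identical(v$gene, "gene03")
  expect_identical(v$sample, "S05")

  one <- m[1, 1:10, drop = FALSE]
  v2 <- validate_cq_matrix(one, min_genes = 2)
  expect_true("dimension" %in% v2$type)

  m2 <- average_technical_replicates(exp$replicates)
  m2["gene01", "S01"] <- NA
  expect_true("missing" %in% validate_cq_matrix(m2)$type)
})

test_that("incomplete samples are dropped with a message", {
  m <- random_cq(4, 6, seed = 13)
  m["g1", "S2"] <- NA
  expect_message(out <- drop_incomplete_samples(m), "S2")
  expect_identical(colnames(out), setdiff(colnames(m), "S2"))
  expect_false(anyNA(out))
})
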