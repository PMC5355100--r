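test_that("quantile normalization matches the sorted-mean definition", {
  # hand-computed: columns (1,3) and (2,4) both become (1.5, 3.5)
  m <- cbind(a = c(1, 3), b = c(2, 4))
  expect_equal(unname(quantileNormalize(m)),
               cbind(c(1.5, 3.5), c(1.5, 3.5)))
  # rank order preserved when one column is reversed
  m2 <- cbind(a = c(3, 1), b = c(2, 4))
  q2 <- quantileNormalize(m2)
  expect_equal(order(q2[, 1]), order(m2[, 1]))
  expect_equal(order(q2[, 2]), order(m2[, 2]))
  # identical columns are a fixed point; single column unchanged
  m3 <- cbind(x = c(5, 1, 7), y = c(5, 1, 7))
  expect_equal(quantileNormalize(m3), m3)
  m4 <- cbind(x = c(9, 2, 5))
  expect_equal(quantileNormalize(m4), m4)
  expect_error(quantileNormalize(matrix(numeric(), 0, 0)), "empty")
})

test_that("quantile normalization is idempotent and equalizes distributions", {
  set.seed(101)
  m <- matrix(rlnorm(600, 7, 1), 100, 6)
  q1 <- quantileNormalize(m)
  expect_equal(quantileNormalize(q1), q1, tolerance = 1e-12)
  for (j in 2:6)
    expect_equal(sort(q1[, j]), sort(q1[, 1]))
})

test_that("paired log2 fold change is the mean of per-pair log ratios", {
  # T = (4, 8), N = (1, 2), pseudocount 0 -> mean(log2 4, log2 4) = 2
  x <- toyPairedSet(matrix(c(4, 8), 1), matrix(c(1, 2), 1))
  expect_equal(unname(pairedLog2FC(x, pseudocount = 0)), 2)
  # doubling every tumor value gives exactly 1; equality gives 0
  x2 <- toyPairedSet(matrix(c(10, 30, 24), 1), matrix(c(5, 15, 12), 1))
  expect_equal(unname(pairedLog2FC(x2, pseudocount = 0)), 1)
  x3 <- toyPairedSet(matrix(c(7, 9), 1), matrix(c(7, 9), 1))
  expect_equal(unname(pairedLog2FC(x3)), 0)
})

test_that("per-probe t-tests agree with the closed-form Student oracle", {
  set.seed(7)
  for (rep in 1:25) {
    n <- sample(2:6, 1)
    tumor <- matrix(rlnorm(n, 8, 0.7), 1)
    normal <- matrix(rlnorm(n, 8, 0.7), 1)
    x <- toyPairedSet(tumor, normal)
    expect_equal(unname(probeTTest(x, mode = "two_sample")),
                 tTwoSampleOracle(log2(tumor + 1), log2(normal + 1)),
                 tolerance = 1e-10)
    expect_equal(unname(probeTTest(x, mode = "paired")),
                 tPairedOracle(log2(tumor[1, ] + 1),
                               log2(normal[1, ] + 1)),
                 tolerance = 1e-10)
  }
})

test_that("degenerate zero-variance probes get p = 1 with a warning", {
  x <- toyPairedSet(matrix(c(8, 8, 8), 1), matrix(c(4, 4, 4), 1))
  expect_warning(p <- probeTTest(x, mode = "paired"), "zero variance")
  expect_equal(unname(p), 1)
  # identical groups: t = 0, p = 1 (not degenerate, no warning)
  x2 <- toyPairedSet(matrix(c(3, 9, 5), 1), matrix(c(9, 3, 5), 1))
  expect_silent(p2 <- probeTTest(x2, mode = "two_sample"))
  expect_equal(unname(p2), 1)
})

test_that("Benjamini-Hochberg matches the step-up enumeration oracle", {
  # hand-enumerated cases
  expect_equal(benjaminiHochberg(rep(0.01, 5)), rep(0.01, 5))
  expect_equal(benjaminiHochberg(c(0.01, 0.02, 0.03, 0.04, 0.05)),
               rep(0.05, 5))
  expect_equal(benjaminiHochberg(0.3), 0.3)
  expect_error(benjaminiHochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  # random vectors against the brute-force oracle
  set.seed(11)
  for (rep in 1:200) {
    p <- runif(sample(1:50, 1))^sample(1:3, 1)
    expect_equal(benjaminiHochberg(p), bhOracle(p), tolerance = 1e-12)
  }
})

test_that("BH preserves p-value ordering (monotonicity)", {
  set.seed(13)
  for (rep in 1:50) {
    p <- runif(30)
    f <- benjaminiHochberg(p)
    o <- order(p)
    expect_true(all(diff(f[o]) >= -1e-15))
  }
})

test_that("volcano filtering applies strict double thresholds", {
  de <- data.frame(log2fc = c(1.5, -2, 3), fdr = c(0.01, 0.04, 0.2),
                   row.names = c("a", "b", "c"))
  v <- volcanoFilter(de)
  expect_identical(v$up, "a")
  expect_identical(v$down, "b")
  # fold change exactly 2.0 is excluded by the strict inequality
  de2 <- data.frame(log2fc = 1, fdr = 0.01, row.names = "edge")
  expect_length(volcanoFilter(de2)$up, 0)
  # empty table gives empty lists
  v0 <- volcanoFilter(data.frame(log2fc = numeric(), fdr = numeric()))
  expect_length(v0$up, 0)
  expect_length(v0$down, 0)
})

test_that("planted differential probes are recovered on simulated data", {
  cfg <- SimConfig(nPairs = 10, nLnc = 500, nMrna = 500, fracDE = 0.1,
                   log2fcRange = c(2, 2), noiseSd = 0.3, seed = 2024)
  s <- simulateExpression(cfg)
  de <- runDifferentialExpression(s$expr)
  truth <- s$truth$isDE
  recall <- sum(de$passesFilter & truth) / sum(truth)
  fpr <- sum(de$passesFilter & !truth) / sum(!truth)
  expect_gte(recall, 0.9)
  expect_lte(fpr, 0.05)
})

test_that("unpaired columns are rejected with the pair named", {
  m <- matrix(1:4, 1, dimnames = list("p", c("a_T", "a_N", "b_T", "c_N")))
  expect_error(
    PairedExpressionSet(m, pairId = c("a", "a", "b", "c"),
                        group = c("tumor", "normal", "tumor", "normal")),
    "exactly once")
})
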