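test_that("Mann-Whitney AUC equals exhaustive pair counting", {
  expect_equal(aucMannWhitney(c(3, 5), c(1, 4)), 0.75)
  expect_equal(aucMannWhitney(c(10, 11), c(1, 2)), 1)   # separation
  expect_equal(aucMannWhitney(rep(2, 4), rep(2, 6)), 0.5)  # all ties
  expect_error(aucMannWhitney(numeric(), 1), "non-empty")
  set.seed(41)
  for (rep in 1:60) {
    nPos <- sample(1:20, 1); nNeg <- sample(1:20, 1)
    pos <- sample(1:8, nPos, replace = TRUE) + 0.5 * rbinom(nPos, 1, 0.5)
    neg <- sample(1:8, nNeg, replace = TRUE) + 0.5 * rbinom(nNeg, 1, 0.5)
    expect_equal(aucMannWhitney(pos, neg), aucOracle(pos, neg),
                 tolerance = 1e-12)
  }
})

test_that("AUC is invariant under monotone transforms and complements", {
  set.seed(42)
  for (rep in 1:30) {
    pos <- rnorm(12, 1); neg <- rnorm(15)
    a <- aucMannWhitney(pos, neg)
    expect_equal(aucMannWhitney(exp(pos), exp(neg)), a, tolerance = 1e-12)
    expect_equal(aucMannWhitney(2 * pos + 7, 2 * neg + 7), a,
                 tolerance = 1e-12)
    expect_equal(a + aucMannWhitney(neg, pos), 1, tolerance = 1e-12)
  }
})

test_that("Hanley-McNeil SE matches the plug-in formula and its limits", {
  n <- 10
  # at A = 0.5, Q1 = Q2 = 1/3, so both correction terms are (1/3 - 1/4);
  # this also equals the exact null SD of U/(nm), sqrt((2n+1)/(12 n^2))
  expect_equal(aucSeHanley(0.5, n, n),
               sqrt((0.25 + 2 * (n - 1) * (1 / 3 - 0.25)) / n^2))
  expect_equal(aucSeHanley(0.5, n, n), sqrt((2 * n + 1) / (12 * n^2)))
  expect_equal(aucSeHanley(1, 12, 9), 0)
  # SE shrinks monotonically with n at fixed AUC
  ses <- vapply(c(5, 10, 50, 200), function(k) aucSeHanley(0.8, k, k),
                numeric(1))
  expect_true(all(diff(ses) < 0))
})

test_that("the Youden threshold maximizes sensitivity + specificity - 1", {
  y <- youdenThreshold(c(3, 5), c(1, 4))
  expect_equal(y$j, 0.5)
  expect_equal(y$threshold, 5)  # tie broken toward higher specificity
  expect_equal(y$specificity, 1)
  # perfect separation
  y2 <- youdenThreshold(c(9, 10), c(1, 2))
  expect_equal(y2$sensitivity, 1)
  expect_equal(y2$specificity, 1)
  y3 <- youdenThreshold(4, 2)
  expect_equal(y3$threshold, 4)
  expect_equal(unname(c(y3$sensitivity, y3$specificity)), c(1, 1))
  # exhaustive check of the maximization on random score sets
  set.seed(43)
  for (rep in 1:25) {
    pos <- sample(1:6, 8, replace = TRUE)
    neg <- sample(1:6, 8, replace = TRUE)
    y <- youdenThreshold(pos, neg)
    cand <- sort(unique(c(pos, neg)))
    jAll <- vapply(cand, function(t)
      mean(pos >= t) + mean(neg < t) - 1, numeric(1))
    expect_equal(y$j, max(jAll), tolerance = 1e-12)
  }
})

test_that("binormal AUC matches the closed form and empirical sampling", {
  expect_equal(binormalAuc(3, 1, 3, 2), 0.5)
  expect_equal(binormalAuc(2.16, 2.44, 6.91, 5.40),
               pnorm(4.75 / sqrt(2.44^2 + 5.40^2)))
  expect_equal(binormalAuc(1, 0, 2, 0), 1)  # degenerate limit
  expect_error(binormalAuc(1, 0, 1, 0), "undefined")
  # empirical AUC of large normal samples converges to the closed form
  set.seed(44)
  n <- 100000
  pos <- rnorm(n, 1.2, 1.5); neg <- rnorm(n, 0, 1)
  expect_lte(abs(aucMannWhitney(pos, neg) -
                   binormalAuc(0, 1, 1.2, 1.5)), 0.01)
})

test_that("rocSummary bundles AUC, SE and operating point coherently", {
  rs <- rocSummary(c(2, 3, 9), c(1, 2, 4))
  expect_equal(auc(rs), aucMannWhitney(c(2, 3, 9), c(1, 2, 4)))
  expect_equal(aucSE(rs), aucSeHanley(auc(rs), 3, 3))
  op <- operatingPoint(rs)
  expect_true(all(op[c("sensitivity", "specificity")] >= 0 &
                    op[c("sensitivity", "specificity")] <= 1))
})

test_that("the logistic panel fit behaves like ridge-IRLS should", {
  set.seed(45)
  n <- 200
  x <- cbind(a = rnorm(n), b = rnorm(n))
  eta <- -0.3 + 1.2 * x[, "a"] - 0.8 * x[, "b"]
  y <- rbinom(n, 1, plogis(eta))
  fit <- fitPanel(x, y)
  # cross-check against glm on well-conditioned data
  ref <- glm(y ~ x, family = binomial())
  expect_equal(unname(coef(fit)), unname(coef(ref)), tolerance = 1e-4)
  # a perfectly separating marker still yields panel AUC 1
  xs <- cbind(sep = c(rnorm(20, -4), rnorm(20, 4)))
  ys <- rep(0:1, each = 20)
  fs <- fitPanel(xs, ys)
  sc <- panelScore(fs, xs)
  expect_equal(aucMannWhitney(sc[ys == 1], sc[ys == 0]), 1)
  # duplicated marker columns preserve the score ranking (ridge symmetry)
  xd <- cbind(m1 = x[, "a"], m2 = x[, "a"])
  fd <- fitPanel(xd, y)
  f1 <- fitPanel(x[, "a", drop = FALSE], y)
  expect_equal(order(panelScore(fd, xd)),
               order(panelScore(f1, x[, "a", drop = FALSE])))
  # constant markers are dropped with a warning
  xc <- cbind(x, flat = 1)
  expect_warning(fc <- fitPanel(xc, y), "constant")
  expect_setequal(panelMarkers(fc), c("a", "b"))
})

test_that("panel coefficients recover planted log-odds weights", {
  set.seed(46)
  n <- 2000
  beta <- c(`(Intercept)` = 0.25, m1 = 1.0, m2 = -0.7, m3 = 0.5)
  x <- matrix(rnorm(n * 3), n, dimnames = list(NULL, names(beta)[-1]))
  y <- rbinom(n, 1, plogis(beta[1] + x %*% beta[-1]))
  fit <- fitPanel(x, y)
  relErr <- abs(coef(fit)[-1] - beta[-1]) / abs(beta[-1])
  expect_true(all(relErr <= 0.15))
})

test_that("cohort evaluation freezes the panel on training data", {
  set.seed(47)
  mk <- function(n) {
    g <- rep(c("tumor", "normal"), each = n)
    m <- cbind(mA = rnorm(2 * n) + 1.6 * (g == "tumor"),
               mB = rnorm(2 * n) + 1.0 * (g == "tumor"))
    list(markers = m, group = g)
  }
  train <- mk(40); valid <- mk(40)
  ev <- evaluateCohorts(train, validation = valid)
  tab <- ev$table
  expect_setequal(unique(tab$cohort), c("training", "validation"))
  expect_setequal(unique(tab$marker), c("mA", "mB", "panel"))
  # validation == training gives identical summaries
  ev2 <- evaluateCohorts(train, validation = train)
  t2 <- ev2$table
  trRows <- t2[t2$cohort == "training", -1]
  vaRows <- t2[t2$cohort == "validation", -1]
  rownames(trRows) <- rownames(vaRows) <- NULL
  expect_equal(trRows, vaRows)
  # train/validation AUC of same-generator cohorts agree within 3 SE
  pa <- tab[tab$marker == "panel", ]
  seBinom <- max(pa$se)
  expect_lte(abs(diff(pa$auc)), 3 * seBinom + 1e-9)
  # label shuffling drives the panel to chance level
  shuf <- train
  set.seed(48)
  shuf$group <- sample(shuf$group)
  evS <- evaluateCohorts(shuf)
  pS <- evS$table[evS$table$marker == "panel", ]
  expect_lte(abs(pS$auc - 0.5), 3 * pS$se)
  # marker mismatch is an error
  badValid <- list(markers = valid$markers[, 1, drop = FALSE],
                   group = valid$group)
  expect_error(evaluateCohorts(train, validation = badValid), "lacks")
})
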