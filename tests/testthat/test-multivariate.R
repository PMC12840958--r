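test_that("z-scoring standardises columns and flags constant ones", {
  x <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(2, 8, 5))
  z <- zscoreMatrix(x)
  expect_equal(unname(z[, "a"]), (c(1, 2, 3) - 2) / sd(c(1, 2, 3)))
  expect_equal(unname(z[, "b"]), c(0, 0, 0))
  expect_equal(unname(attr(z, "constant")), c(FALSE, TRUE, FALSE))
  m <- randMatrix(9, 5, seed = 3)
  zm <- zscoreMatrix(m)
  expect_true(all(abs(colMeans(zm)) < 1e-12))
  expect_equal(unname(apply(zm, 2, sd)), rep(1, 5))
})

test_that("PCA agrees with a covariance-eigendecomposition oracle", {
  x <- zscoreMatrix(randMatrix(6, 4, seed = 21))
  res <- pcaFit(x, nComponents = 3)
  ev <- eigen(cov(x), symmetric = TRUE)
  # eigenvalues of the covariance vs singular values
  lam <- res$explainedVariance * sum(ev$values)
  expect_equal(lam[1:4], ev$values, tolerance = 1e-8)
  # scores match the projections on the eigenvectors up to sign
  proj <- sweep(x, 2, colMeans(x)) %*% ev$vectors
  for (a in 1:3)
    expect_lt(min(sum((res$scores[, a] - proj[, a])^2),
                  sum((res$scores[, a] + proj[, a])^2)), 1e-16)
  expect_equal(sum(res$explainedVariance), 1.0)
  # orthonormal loadings, deterministic sign convention
  expect_equal(crossprod(res$loadings), diag(3), ignore_attr = TRUE)
  for (a in 1:3)
    expect_gt(res$loadings[which.max(abs(res$loadings[, a])), a], 0)
})

test_that("PCA handles rank-1 input and rejects too many components", {
  u <- c(1, 2, 3, 4)
  x <- outer(u, c(2, -1, 0.5))
  res <- pcaFit(x, nComponents = 1)
  expect_equal(res$explainedVariance[1], 1.0)
  expect_error(pcaFit(x, nComponents = 4), "nComponents")
})

test_that("Ward clustering reproduces hand-evaluated and brute-force merges", {
  # one distant outlier: the close pair merges first
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0))
  res <- hcaWard(pts)
  expect_equal(sort(res$merge[1, ]), c(-2, -1))
  expect_equal(res$height[1], 1)          # sqrt(2 * ESS increase 0.5)

  # identical items merge at height 0
  res0 <- hcaWard(rbind(c(1, 1), c(1, 1)))
  expect_equal(res0$height, 0)

  # random 5-point instances match the exhaustive Ward oracle
  for (s in 1:10) {
    x <- randMatrix(5, 2, seed = 100 + s)
    mine <- hcaWard(x)
    oracle <- wardOracle(x)
    expect_equal(mine$height, oracle$heights, tolerance = 1e-10)
    expect_equal(hcaPartitions(mine, 5), oracle$partitions)
  }
})

test_that("Ward merge heights are non-decreasing and agree with hclust", {
  x <- randMatrix(20, 4, seed = 5)
  res <- hcaWard(x)
  expect_equal(nrow(res$merge), 19)
  expect_true(all(diff(res$height) >= -1e-12))
  hc <- stats::hclust(dist(x), method = "ward.D2")
  expect_equal(res$height, hc$height, tolerance = 1e-10)
})

test_that("k-means attains the obvious optima and its trace never increases", {
  # k = n: zero within-cluster scatter
  x <- randMatrix(6, 2, seed = 9)
  km <- kmeansLloyd(x, k = 6, seed = 1, nRestarts = 10)
  expect_equal(km$wcss, 0)

  # two well-separated clouds are recovered exactly
  set.seed(4)
  clouds <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
                  matrix(rnorm(20, 50, 0.1), 10, 2))
  km2 <- kmeansLloyd(clouds, k = 2, seed = 2)
  expect_equal(length(unique(km2$labels[1:10])), 1)
  expect_equal(length(unique(km2$labels[11:20])), 1)
  expect_false(km2$labels[1] == km2$labels[11])
  expect_true(all(diff(km2$wcssTrace) <= 1e-9))

  # duplicated rows always co-cluster
  dup <- rbind(clouds, clouds[1, ], clouds[1, ])
  km3 <- kmeansLloyd(dup, k = 2, seed = 3)
  expect_equal(km3$labels[21], km3$labels[1])
  expect_equal(km3$labels[22], km3$labels[1])

  # wcss matches its definition
  d2own <- rowSums((clouds - km2$centers[km2$labels, ])^2)
  expect_equal(km2$wcss, sum(d2own))
  expect_error(kmeansLloyd(clouds, k = 21, seed = 1), "exceed")
})

test_that("OPLS-DA with no orthogonal component reduces exactly to PLS1", {
  X <- zscoreMatrix(randMatrix(10, 6, seed = 31))
  y <- rep(c("a", "b"), each = 5)
  fit <- oplsDA(X, y, nOrtho = 0)
  # direct PLS1: t = X X'y / ||X'y||
  yc <- rep(c(-1, 1), each = 5)
  w <- crossprod(X, yc); w <- w / sqrt(sum(w^2))
  expect_equal(fit@scores, drop(X %*% w), tolerance = 1e-12)
  expect_equal(fit@nOrtho, 0L)

  # independent reference: mixOmics PLS scores, up to scale and sign
  ref <- mixOmics::pls(X, yc, ncomp = 1, scale = FALSE, mode = "regression")
  tref <- ref$variates$X[, 1]
  a <- fit@scores / sqrt(sum(fit@scores^2))
  b <- tref / sqrt(sum(tref^2))
  expect_lt(min(sum((a - b)^2), sum((a + b)^2)), 1e-20)
})

test_that("OPLS-DA separates a planted class direction from orthogonal nuisance", {
  set.seed(77)
  n <- 12
  y <- rep(c("lo", "hi"), each = n / 2)
  yc <- rep(c(-1, 1), each = n / 2)
  nuis <- rnorm(n); nuis <- nuis - mean(nuis)
  nuis <- nuis - yc * sum(nuis * yc) / sum(yc^2)   # orthogonal to y
  X <- outer(yc, c(1, 1, 0, 0)) + outer(nuis, c(0, 0, 1.5, 1.5)) +
    matrix(rnorm(n * 4, sd = 0.05), n, 4)
  fit <- oplsDA(zscoreMatrix(X), y, nOrtho = 1)
  # predictive scores orthogonal to orthogonal scores
  expect_lt(abs(sum(fit@scores * fit@orthoScores[, 1])) /
              sqrt(sum(fit@scores^2) * sum(fit@orthoScores[, 1]^2)), 1e-8)
  # class means of t have opposite signs, positive for the +1-coded class
  expect_gt(mean(fit@scores[y == fit@classes[2]]), 0)
  expect_lt(mean(fit@scores[y == fit@classes[1]]), 0)
  expect_gt(fit@R2Y, 0.9)

  # appending a pure-noise variable barely moves R2Y
  X2 <- cbind(X, rnorm(n, sd = 1))
  fit2 <- oplsDA(zscoreMatrix(X2), y, nOrtho = 1)
  expect_lt(abs(fit2@R2Y - fit@R2Y), 0.05)
})

test_that("VIP scores satisfy the normalisation identity and rank informative variables", {
  # identical copies share the symmetry: all VIP = 1
  set.seed(12)
  v <- rnorm(8)
  X <- cbind(v, v, v, v)
  y <- rep(c("a", "b"), 4)
  fit <- oplsDA(zscoreMatrix(X), y, nOrtho = 0)
  expect_equal(unname(fit@vip), rep(1, 4), tolerance = 1e-12)

  # sum VIP^2 = number of variables for arbitrary fits
  for (s in 1:5) {
    Xr <- zscoreMatrix(randMatrix(8, 5, seed = 300 + s))
    fr <- oplsDA(Xr, rep(c("a", "b"), each = 4), nOrtho = 1)
    expect_lt(abs(sum(fr@vip^2) - 5), 1e-8)
    expect_lt(abs(sum(vipScores(fr, orthogonal = TRUE)^2) - 5), 1e-6)
  }

  # one informative variable among noise wins the VIP ranking
  hits <- 0
  for (s in 1:100) {
    set.seed(400 + s)
    yc <- rep(c(-1, 1), each = 3)
    Xi <- cbind(yc + rnorm(6, sd = 0.2),
                matrix(rnorm(6 * 7), 6, 7))
    fi <- oplsDA(zscoreMatrix(Xi), rep(c("a", "b"), each = 3), nOrtho = 0)
    if (which.max(fi@vip) == 1) hits <- hits + 1
  }
  expect_gte(hits, 95)
})

test_that("permutation validation calibrates against planted and null effects", {
  # a planted multivariate class effect: 3 informative variables among 10
  planted <- function(n2, s) {
    set.seed(s)
    yc <- rep(c(-1, 1), each = n2)
    X <- cbind(outer(yc, rep(1.5, 3)), matrix(0, 2 * n2, 7)) +
      matrix(rnorm(2 * n2 * 10), 2 * n2, 10)
    list(X = zscoreMatrix(X), y = rep(c("a", "b"), each = n2))
  }

  # 6 vs 6: conventional significance in essentially every seed
  low6 <- 0
  for (s in 1:10) {
    d <- planted(6, 1000 + s)
    if (permutationTest(d$X, d$y, nOrtho = 1, nPerm = 99,
                        seed = 50 + s) <= 0.05) low6 <- low6 + 1
  }
  expect_gte(low6, 9)

  # 3 vs 3: only 20 distinct splits exist and a uniform label
  # permutation redraws the observed split ~10% of the time, so with the
  # (1 + #{perm >= obs})/(1 + nPerm) convention the p-value floors near
  # 0.1 -- small but bounded away from 0; Q2 is the sharper statistic
  low3 <- 0
  for (s in 1:10) {
    d <- planted(3, 2000 + s)
    if (permutationTest(d$X, d$y, nOrtho = 1, nPerm = 99, seed = 60 + s,
                        statistic = "Q2") <= 0.3) low3 <- low3 + 1
  }
  expect_gte(low3, 9)

  # Q2 separates a held-out-predictable model from pure noise
  d <- planted(6, 7)
  expect_gt(q2LOO(d$X, d$y, 1), 0.3)
  set.seed(9)
  Xn <- zscoreMatrix(matrix(rnorm(120), 12, 10))
  expect_lt(q2LOO(Xn, rep(c("a", "b"), each = 6), 1), 0.1)

  # pure-noise X: p has no excess of small values
  ps <- vapply(1:40, function(s) {
    X <- zscoreMatrix(randMatrix(8, 6, seed = 700 + s))
    as.numeric(permutationTest(X, rep(c("a", "b"), each = 4), nOrtho = 0,
                               nPerm = 99, seed = 800 + s))
  }, numeric(1))
  expect_gt(mean(ps), 0.3)
  expect_lt(mean(ps), 0.7)
})
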