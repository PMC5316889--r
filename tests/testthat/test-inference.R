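test_that("within-subject z-scoring is exact and rejects constants", {
  expect_equal(zscore_within(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(1)
  v <- rnorm(50)
  s <- rep(1:2, 25)
  z <- zscore_within(v, s)
  for (k in 1:2) {
    expect_equal(mean(z[s == k]), 0, tolerance = 1e-12)
    expect_equal(sd(z[s == k]), 1, tolerance = 1e-12)
  }
  expect_error(zscore_within(c(2, 2, 2)), "zero variance")
})

test_that("multilevel GLM recovers an exact first-level relationship", {
  set.seed(2)
  X <- lapply(1:4, function(i) cbind(x = rnorm(30)))
  Y <- lapply(X, function(x) as.numeric(2 * x))
  fit <- multilevel_glm(Y, X, n_boot = 500, seed = 3)
  expect_equal(fit$group$estimate, 2, tolerance = 1e-10)
  expect_equal(fit$R2_full, 1, tolerance = 1e-10)
  expect_lte(fit$group$p_two, 2 / 501 + 1e-12)
  expect_error(multilevel_glm(Y[1:2], X[1:2], n_boot = 10), "3 subjects")
})

test_that("Empirical Bayes pooling degenerates to the plain mean", {
  p <- painsig:::eb_pool(c(1, 2, 3), c(2, 2, 2))
  expect_equal(p$estimate, 2, tolerance = 1e-12)
  expect_equal(p$weights / sum(p$weights), rep(1 / 3, 3), tolerance = 1e-12)
  # zero sampling variance everywhere: equal weights, no division by zero
  p0 <- painsig:::eb_pool(c(1, 1, 1), c(0, 0, 0))
  expect_equal(p0$estimate, 1)
})

test_that("a pure-noise predictor contributes no unique variance", {
  set.seed(4)
  X <- lapply(1:10, function(i) cbind(x1 = rnorm(60), x2 = rnorm(60)))
  Y <- lapply(X, function(x) as.numeric(x[, 1] + rnorm(60, 0, 0.5)))
  fit <- multilevel_glm(Y, X, n_boot = 200, seed = 5)
  expect_lt(fit$unique_R2[["x2"]], 0.05)
  expect_gt(fit$unique_R2[["x1"]], 0.5)
  expect_gte(min(fit$unique_R2), -1e-10)  # unique R2 is nonnegative
})

test_that("variance partition: saturated predictor and collinear pair", {
  set.seed(5)
  X <- lapply(1:5, function(i) cbind(x = rnorm(40)))
  Y <- lapply(X, function(x) as.numeric(3 * x))
  vp <- variance_partition(Y, X, n_perm = 300, seed = 6)
  expect_equal(vp$unique_R2[["x"]], 1, tolerance = 1e-10)
  expect_lte(vp$p[["x"]], 2 / 301 + 1e-12)
  # identical predictors share all their variance
  X2 <- lapply(1:5, function(i) {
    x <- rnorm(40)
    cbind(a = x, b = x)
  })
  Y2 <- lapply(X2, function(x) as.numeric(x[, 1] + rnorm(40, 0, 0.3)))
  vp2 <- variance_partition(Y2, X2, n_perm = 100, seed = 7)
  expect_lt(max(abs(vp2$unique_R2)), 1e-10)
  expect_gt(vp2$R2_full, 0.5)
})

test_that("permutation and bootstrap results are reproducible under a seed", {
  set.seed(8)
  X <- lapply(1:6, function(i) cbind(x1 = rnorm(30), x2 = rnorm(30)))
  Y <- lapply(X, function(x) as.numeric(x[, 1] + rnorm(30)))
  v1 <- variance_partition(Y, X, n_perm = 200, seed = 11)
  v2 <- variance_partition(Y, X, n_perm = 200, seed = 11)
  expect_identical(v1$p, v2$p)
  g1 <- multilevel_glm(Y, X, n_boot = 200, seed = 12)
  g2 <- multilevel_glm(Y, X, n_boot = 200, seed = 12)
  expect_identical(g1$group$p_two, g2$group$p_two)
})

test_that("an exact mediation chain returns the textbook path values", {
  x <- rep(c(1, -1), 3)
  w <- 0.1 * c(1, 1, -2, 1, 1, -2)   # mean-zero, orthogonal to x
  M <- x + w
  Y <- 2 * M
  subj <- function() list(x = x, m = M, y = Y)
  med <- mediate_multilevel(x = list(x, x, x), m = list(M, M, M),
                            y = list(Y, Y, Y), n_boot = 200, seed = 1)
  est <- function(path) med$paths$estimate[med$paths$path == path]
  expect_equal(est("a"), 1, tolerance = 1e-10)
  expect_equal(est("b"), 2, tolerance = 1e-10)
  expect_equal(est("cprime"), 0, tolerance = 1e-10)
  expect_equal(est("ab"), 2, tolerance = 1e-10)
  expect_equal(est("c"), 2, tolerance = 1e-10)
})

test_that("condition labels are coded via the supplied map and unknowns error", {
  x <- c("LM", "HM", "LM", "HM", "LM", "HM")
  coding <- c(LM = 1, HM = -1)
  expect_equal(painsig:::apply_coding(x, coding), c(1, -1, 1, -1, 1, -1))
  expect_error(painsig:::apply_coding(c(x, "XX"), coding), "absent from coding")
})

test_that("group indirect is null when the mediator ignores the manipulation", {
  set.seed(9)
  abs_est <- replicate(30, {
    n_sub <- 8; n_tr <- 40
    x <- lapply(1:n_sub, function(i) sample(rep(c(1, -1), n_tr / 2)))
    m <- lapply(1:n_sub, function(i) rnorm(n_tr))
    y <- lapply(1:n_sub, function(i) 0.5 * m[[i]] + rnorm(n_tr))
    med <- mediate_multilevel(x, m, y, n_boot = 50, seed = 1)
    med$paths$estimate[med$paths$path == "ab"]
  })
  expect_lt(abs(mean(abs_est)), 3 * sd(abs_est) / sqrt(length(abs_est)))
})

test_that("three-path chain with unit links has unit serial indirect", {
  set.seed(10)
  n <- 24
  x <- rep(c(1, -1), n / 2)
  orth <- function(target, basis) {
    r <- resid(lm(target ~ basis))
    as.numeric(r / sd(r)) * 0.5
  }
  m1 <- x + orth(rnorm(n), cbind(x))
  m2 <- m1 + orth(rnorm(n), cbind(x, m1))
  y <- m2 + orth(rnorm(n), cbind(x, m1, m2))
  med <- mediate_three_path(x = list(x, x, x), m1 = list(m1, m1, m1),
                            m2 = list(m2, m2, m2), y = list(y, y, y),
                            n_boot = 200, seed = 2)
  est <- function(path) med$paths$estimate[med$paths$path == path]
  expect_equal(est("a"), 1, tolerance = 1e-8)
  expect_equal(est("d"), 1, tolerance = 1e-8)
  expect_equal(est("b"), 1, tolerance = 1e-8)
  expect_equal(est("adb"), 1, tolerance = 1e-8)
})

test_that("breaking any link zeroes the serial indirect but not the others", {
  set.seed(11)
  n_sub <- 10; n_tr <- 50
  sim <- function(a_on, d_on, b_on) {
    x <- m1 <- m2 <- y <- vector("list", n_sub)
    for (i in 1:n_sub) {
      x[[i]] <- sample(rep(c(1, -1), n_tr / 2))
      m1[[i]] <- a_on * x[[i]] + rnorm(n_tr)
      m2[[i]] <- d_on * m1[[i]] + rnorm(n_tr)
      y[[i]] <- b_on * m2[[i]] + rnorm(n_tr)
    }
    mediate_three_path(x, m1, m2, y, n_boot = 100, seed = 3)
  }
  full <- sim(1, 1, 1)
  est <- function(m, path) m$paths$estimate[m$paths$path == path]
  expect_gt(est(full, "adb"), 0.5)
  broken <- sim(1, 0, 1)
  expect_lt(abs(est(broken, "adb")), 0.15)
  expect_gt(est(broken, "a"), 0.7)     # other links keep their planted values
  expect_gt(est(broken, "b"), 0.7)
})
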