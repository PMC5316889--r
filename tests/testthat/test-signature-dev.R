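gridf <- make_grid(c(4, 4, 2), "full")   # 32 voxels for arithmetic fixtures

test_that("residualization mean-centres within intensity level", {
  X <- matrix(rnorm(6 * gridf$n_vox), 6)
  d <- manual_dataset(X, ratings = c(3, 4, 5, 6, 7, 8),
                      intensity = c(1, 1, 1, 2, 2, 2), grid = gridf)
  ref <- weight_map(rep(0, gridf$n_vox), gridf)  # constant (zero) responses
  expect_warning(res <- residualize_subject(d, ref), "constant")
  expect_equal(res$y_res, c(-1, 0, 1, -1, 0, 1))
})

test_that("residuals are orthogonal to the design and match the hat-matrix oracle", {
  set.seed(2)
  X <- matrix(rnorm(12 * gridf$n_vox), 12)
  d <- manual_dataset(X, ratings = rnorm(12),
                      intensity = rep(c(1, 2, 3), each = 4), grid = gridf)
  ref <- generate_reference_signature(gridf, 1, seed = 9)
  res <- residualize_subject(d, ref)
  expect_lt(max(abs(crossprod(res$design, res$y_res))), 1e-8)
  expect_lt(max(abs(crossprod(res$design, res$X_res))), 1e-8)
  # independent oracle: (I - H) y with H built from the explicit design
  D <- cbind(1, d$intensity == 2, d$intensity == 3, X %*% ref$values)
  H <- D %*% solve(crossprod(D)) %*% t(D)
  expect_equal(res$y_res, as.numeric((diag(12) - H) %*% d$ratings),
               tolerance = 1e-8)
  expect_equal(res$X_res, (diag(12) - H) %*% X, tolerance = 1e-8)
})

test_that("a single-trial intensity level yields zero residuals and a warning", {
  X <- matrix(rnorm(5 * gridf$n_vox), 5)
  d <- manual_dataset(X, ratings = c(1, 2, 3, 4, 9),
                      intensity = c(1, 1, 2, 2, 3), grid = gridf)
  expect_warning(res <- residualize_subject(d), "single trial")
  expect_equal(res$y_res[5], 0)
})

test_that("PCR with all components solves the small normal-equations fixture", {
  X <- rbind(c(1, 0), c(0, 1), c(-1, 0), c(0, -1))
  y <- c(2, 1, -2, -1)
  g2 <- make_grid(c(2, 1, 1), "full")
  m <- fit_subject_pcr(X, y)
  expect_equal(m$weights, c(2, 1), tolerance = 1e-10)
  expect_equal(m$intercept, 0, tolerance = 1e-10)
})

test_that("constant outcomes give zero weights", {
  set.seed(3)
  m <- fit_subject_pcr(matrix(rnorm(40), 10), rep(2, 10))
  expect_true(all(m$weights == 0))
  expect_equal(m$intercept, 2)
})

test_that("all-component PCR equals OLS on tall full-rank fixtures", {
  set.seed(4)
  X <- matrix(rnorm(60 * 8), 60)
  y <- rnorm(60)
  m <- fit_subject_pcr(X, y)
  ols <- lm(y ~ X)
  expect_equal(m$weights, unname(coef(ols)[-1]), tolerance = 1e-8)
  expect_equal(predict_subject_model <- painsig:::predict_subject_model(m, X),
               unname(fitted(ols)), tolerance = 1e-8)
})

test_that("component clamping warns and matches the requested rank", {
  set.seed(5)
  X <- matrix(rnorm(10 * 4), 10)
  expect_warning(m <- fit_subject_pcr(X, rnorm(10), n_components = 9),
                 "clamped")
  expect_equal(m$n_components, 4)
})

test_that("cross-validated correlation is near 1 on noiseless signal and seeded", {
  set.seed(6)
  X <- matrix(rnorm(200 * 20), 200)
  y <- as.numeric(X[, 1:5] %*% c(3, -1, 2, 1, -2))
  r1 <- crossval_prediction_corr(X, y, seed = 42)
  expect_gt(r1, 0.99)
  expect_identical(r1, crossval_prediction_corr(X, y, seed = 42))
  yn <- y + rnorm(200, 0, 2)
  expect_identical(crossval_prediction_corr(X, yn, seed = 42),
                   crossval_prediction_corr(X, yn, seed = 42))
  expect_false(identical(crossval_prediction_corr(X, yn, seed = 42),
                         crossval_prediction_corr(X, yn, seed = 43)))
})

test_that("cross-validated correlation is null-centred for permuted outcomes", {
  set.seed(7)
  X <- matrix(rnorm(60 * 15), 60)
  y <- as.numeric(X[, 1] + rnorm(60))
  rs <- vapply(1:100, function(s) {
    yp <- sample(y)
    crossval_prediction_corr(X, yp, seed = s)
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
})

test_that("group aggregation is the cv_r-weighted mean of sd-normalized maps", {
  mk <- function(w, cv) structure(list(weights = w, intercept = 0,
                                       n_components = 1, n_trials_used = 10,
                                       cv_r = cv, subject_id = "x"),
                                  class = "subject_model")
  # identical maps: any positive weights return the shared normalized map
  shared <- c(1, 2, 3, 4)
  agg <- aggregate_group_map(list(mk(shared, 0.9), mk(shared, 0.2)))
  expect_equal(agg$weights, shared / sd(shared))
  # hand-computed weighted mean of the sd-normalized orthogonal maps:
  # group = (0.3 * n1 + 0.1 * n2) / 0.4 = 0.75 n1 + 0.25 n2
  m1 <- c(1, 0); m2 <- c(0, 1)
  agg2 <- aggregate_group_map(list(mk(m1, 0.3), mk(m2, 0.1)))
  expect_equal(agg2$weights, 0.75 * m1 / sd(m1) + 0.25 * m2 / sd(m2),
               tolerance = 1e-12)
  # zero cv_r contributes nothing; all non-positive is an error
  agg3 <- aggregate_group_map(list(mk(m1, 0.4), mk(m2, 0)))
  expect_equal(agg3$weights, m1 / sd(m1))
  expect_error(aggregate_group_map(list(mk(m1, 0), mk(m2, -0.2))),
               "no positive precision")
})

test_that("weighted t-test reduces to the classical test at equal weights", {
  x <- c(1, 2, 3, 4)
  wt <- weighted_one_sample_ttest(x)
  ref <- t.test(x)
  expect_equal(wt$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(wt$p, ref$p.value, tolerance = 1e-10)
  expect_equal(wt$t, 3.873, tolerance = 1e-3)
  # all-zero values
  z <- weighted_one_sample_ttest(rep(0, 5))
  expect_equal(z$t, 0)
  expect_equal(z$p, 1)
  # zero-weight subjects are equivalent to dropping them
  set.seed(8)
  v <- rnorm(6)
  a <- weighted_one_sample_ttest(v, c(2, 1, 3, 0, 0, 0))
  b <- weighted_one_sample_ttest(v[1:3], c(2, 1, 3))
  expect_equal(a$t, b$t, tolerance = 1e-12)
  expect_equal(a$p, b$p, tolerance = 1e-12)
})

test_that("BH rejection matches the brute-force step-up definition", {
  p <- c(0.001, 0.01, 0.02, 0.04, 0.2)
  expect_equal(bh_fdr(p, 0.05), c(TRUE, TRUE, TRUE, TRUE, FALSE))
  expect_equal(bh_fdr(rep(1, 10), 0.05), rep(FALSE, 10))
  expect_equal(bh_fdr(rep(1e-6, 100), 0.05), rep(TRUE, 100))
  expect_length(bh_fdr(numeric(0)), 0)
  # brute force on random p-values: reject 1..k*, k* = max k with
  # p_(k) <= k q / m
  set.seed(9)
  for (rep in 1:20) {
    pv <- runif(37)^2
    q <- 0.1
    ps <- sort(pv)
    k <- which(ps <= seq_along(ps) * q / length(ps))
    thr <- if (length(k)) ps[max(k)] else -1
    expect_identical(bh_fdr(pv, q), pv <= thr)
  }
})

test_that("region extraction respects size, sign and the allowlist", {
  g <- make_grid(c(10, 10, 4), "full")
  vol <- array(0, g$shape)
  vol[1:5, 1:2, 1:2] <- 1      # 20-voxel positive blob
  vol[7:10, 9:10, 1] <- 1      # 8-voxel positive blob (NAc-sized)
  vol[1:5, 8:10, 3:4] <- -1    # 30-voxel negative blob
  vals <- vol_to_vec(vol, g)
  mask <- vals != 0
  regs <- extract_regions(vals, g, mask, min_size = 15)
  expect_length(regs, 2)
  expect_setequal(vapply(regs, `[[`, numeric(1), "sign"), c(1, -1))
  # allowlist admits the small blob by label
  regs2 <- extract_regions(vals, g, mask, min_size = 15,
                           allowlist = c(pos_02 = 7))
  expect_length(regs2, 3)
  expect_equal(sum(vapply(regs2, `[[`, numeric(1), "size")), 58)
  # empty mask
  expect_length(extract_regions(vals, g, rep(FALSE, g$n_vox)), 0)
})

test_that("touching positive and negative blobs split into two regions", {
  g <- make_grid(c(8, 4, 4), "full")
  vol <- array(0, g$shape)
  vol[1:4, 1:4, 1:2] <- 1
  vol[5:8, 1:4, 1:2] <- -1    # adjacent to the positive blob
  vals <- vol_to_vec(vol, g)
  regs <- extract_regions(vals, g, vals != 0, min_size = 15)
  expect_length(regs, 2)
  expect_setequal(vapply(regs, `[[`, numeric(1), "sign"), c(1, -1))
})

test_that("connectivity choice changes diagonal adjacency", {
  g <- make_grid(c(4, 4, 1), "full")
  vol <- array(0, g$shape)
  vol[1, 1, 1] <- 1
  vol[2, 2, 1] <- 1            # diagonal neighbour
  vals <- vol_to_vec(vol, g)
  r26 <- extract_regions(vals, g, vals != 0, min_size = 1, connectivity = 26)
  r6 <- extract_regions(vals, g, vals != 0, min_size = 1, connectivity = 6)
  expect_length(r26, 1)
  expect_length(r6, 2)
})

test_that("univariate encode-decode follows the elementwise arithmetic", {
  # single voxel with activity exactly 2 x rating
  g1 <- make_grid(c(1, 1, 1), "full")
  y <- c(1, 2, 3, 4)
  r1 <- list(X_res = matrix(2 * y, 4, 1), y_res = y)
  ed <- univariate_encode_decode(list(r1))
  expect_equal(ed$beta_map, 2, tolerance = 1e-12)
  expect_equal(ed$predict(5), 10)
  # three-voxel fixture, hand-computed mean of elementwise products
  betas <- c(1, -2, 0.5)
  r3 <- list(X_res = outer(y, betas), y_res = y)
  ed3 <- univariate_encode_decode(list(r3))
  expect_equal(ed3$beta_map, betas, tolerance = 1e-12)
  img <- c(2, 1, 4)
  expect_equal(ed3$predict(img), mean(betas * img))
  # zero map predicts zero
  r0 <- list(X_res = matrix(rnorm(12), 4), y_res = rep(1, 4))
  expect_equal(univariate_encode_decode(list(r0))$predict(c(1, 1, 1)), 0)
})
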