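test_that("canonical HRF has unit peak, causal onset, and a late undershoot", {
  h <- canonical_hrf(0.1)
  t <- seq(0, 32, by = 0.1)
  expect_equal(max(h), 1)
  expect_equal(h[1], 0)
  v5 <- h[which.min(abs(t - 5))]
  v15 <- h[which.min(abs(t - 15))]
  expect_gt(abs(v5), abs(v15))
  expect_lt(v15, 0)
  expect_equal(t[which.max(h)], 5, tolerance = 0.3)
  # evaluate the double-gamma closed form independently at the read-out points
  dg <- function(tt) dgamma(tt, 6, 1) - dgamma(tt, 16, 1) / 6
  expect_equal(v5, dg(5) / max(dg(t)), tolerance = 1e-10)
  expect_error(canonical_hrf(0), "positive")
})

test_that("well-separated trial regressors have VIF near 1", {
  events <- data.frame(onset = c(20, 120), duration = 8)
  d <- build_single_trial_design(events, n_scans = 120, tr = 2)
  expect_equal(d$labels[d$trial_cols], c("trial", "trial"))
  expect_true(all(d$vif >= 1))
  expect_true(all(d$vif < 1.05))
})

test_that("VIF matches 1/(1 - R^2) from an independent per-column regression", {
  events <- data.frame(onset = c(10, 22, 30, 55), duration = 10)
  nuis <- matrix(rnorm(120 * 2), 120)
  d <- build_single_trial_design(events, n_scans = 120, tr = 1, nuisance = nuis)
  X <- d$matrix
  for (j in seq_along(d$trial_cols)) {
    col <- d$trial_cols[j]
    fit <- lm(X[, col] ~ X[, setdiff(seq_len(ncol(X)), col)])
    r2 <- summary(fit)$r.squared
    expect_equal(d$vif[j], 1 / (1 - r2), tolerance = 1e-6)
  }
})

test_that("correlated regressors follow the 1/(1-r^2) closed form", {
  # two regressors with sample correlation exactly 0.9, plus an intercept
  set.seed(4)
  x1 <- as.numeric(scale(rnorm(100)))
  e <- as.numeric(scale(resid(lm(rnorm(100) ~ x1))))
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * e
  X <- cbind(x1, x2, 1)
  expect_equal(cor(x1, x2), 0.9, tolerance = 1e-12)
  expect_equal(painsig:::vif_of_column(X, 1), 1 / (1 - 0.81), tolerance = 1e-8)
  # duplicated regressor: infinite VIF
  Xd <- cbind(x1, x1, 1)
  expect_equal(painsig:::vif_of_column(Xd, 1), Inf)
})

test_that("duplicated trial events give infinite VIF without an exception", {
  events <- data.frame(onset = c(30, 30), duration = 8)
  d <- build_single_trial_design(events, n_scans = 100, tr = 2)
  expect_true(all(is.infinite(d$vif)))
})

test_that("trials are flagged strictly above the VIF threshold", {
  set.seed(1)
  des <- structure(list(
    matrix = matrix(rnorm(40), 10, 4), labels = rep("trial", 2),
    trial_cols = 1:2, vif = c(2.6, 2.4), tr = 1, dt = 0.1, trial_id = 1:2
  ), class = "design_matrix")
  fit <- estimate_trial_betas(matrix(rnorm(30), 10, 3), des,
                              vif_threshold = 2.5)
  expect_equal(fit$qc$excluded_trials, 1L)
  expect_equal(dim(fit$betas), c(2L, 3L))
})

test_that("all-zero timeseries give all-zero betas; short runs error", {
  events <- data.frame(onset = c(10, 40), duration = 8)
  d <- build_single_trial_design(events, n_scans = 60, tr = 2)
  fit <- estimate_trial_betas(matrix(0, 60, 5), d)
  expect_true(all(fit$betas == 0))
  expect_error(estimate_trial_betas(matrix(0, 3, 5), d), "match the design")
  dd <- d
  dd$matrix <- d$matrix[1:3, ]
  expect_error(estimate_trial_betas(matrix(0, 3, 5), dd), "fewer time points")
})

test_that("OLS betas agree with a direct normal-equations solve", {
  set.seed(8)
  events <- data.frame(onset = c(10, 35, 70, 95), duration = 10)
  d <- build_single_trial_design(events, n_scans = 80, tr = 2,
                                 nuisance = matrix(rnorm(160), 80))
  Y <- matrix(rnorm(80 * 6), 80)
  fit <- estimate_trial_betas(Y, d)
  X <- d$matrix
  ref <- solve(crossprod(X), crossprod(X, Y))[d$trial_cols, ]
  expect_equal(fit$betas, ref, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("spike detection flags an injected slice shift and behaves under the null", {
  set.seed(10)
  stack <- array(rnorm(10 * 10 * 6 * 200), c(10, 10, 6, 200))
  qc0 <- detect_spikes(stack)
  expect_lt(length(qc0$spike_indices) / 200, 0.01)
  stack[, , 3, 7] <- stack[, , 3, 7] + 50
  qc <- detect_spikes(stack)
  expect_true(7 %in% qc$spike_indices)
  # degenerate: constant volumes
  const <- array(1, c(6, 6, 4, 12))
  expect_warning(qc2 <- detect_spikes(const), "constant")
  expect_length(qc2$spike_indices, 0)
})

test_that("flexible three-basis AUC is linear and exact on basis signals", {
  n_scans <- 90; tr <- 1
  events <- data.frame(onset = 20, duration = 8)
  reg1 <- painsig:::convolved_regressors(events$onset, events$duration,
                                         n_scans, tr, shift = 0)
  # signal equal to basis kernel 1 with amplitude 2
  auc <- flexible_basis_auc(2 * reg1, events, n_scans, tr, drift = FALSE)
  ref_auc <- painsig:::trapz_auc(as.numeric(reg1), dx = tr)
  expect_equal(as.numeric(auc), 2 * ref_auc, tolerance = 1e-6)
  # zero signal
  auc0 <- flexible_basis_auc(matrix(0, n_scans, 2), events, n_scans, tr)
  expect_true(all(abs(auc0) < 1e-10))
})

test_that("a time-shifted response is captured within 10% by the basis set", {
  n_scans <- 120; tr <- 1
  events <- data.frame(onset = 30, duration = 8)
  shifted <- painsig:::convolved_regressors(events$onset, events$duration,
                                            n_scans, tr, shift = 1.5)
  true_area <- painsig:::trapz_auc(as.numeric(shifted), dx = tr)
  auc <- flexible_basis_auc(shifted, events, n_scans, tr)
  expect_lt(abs(as.numeric(auc) - true_area), 0.10 * abs(true_area))
})
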