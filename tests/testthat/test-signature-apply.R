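g3 <- make_grid(c(3, 1, 1), "full")
w3 <- weight_map(c(1, -1, 2), g3)

test_that("signature response is the in-mask dot product", {
  expect_equal(signature_response(c(2, 3, 1), w3), 1)
  expect_equal(signature_response(c(1, 1, 0), w3), 0)   # orthogonal image
  # linearity on random fixtures
  set.seed(1)
  for (i in 1:10) {
    im1 <- rnorm(3); im2 <- rnorm(3); a <- rnorm(1); b <- rnorm(1)
    expect_equal(signature_response(a * im1 + b * im2, w3),
                 a * signature_response(im1, w3) + b * signature_response(im2, w3),
                 tolerance = 1e-12)
  }
  # matrix input scores per row
  M <- rbind(c(2, 3, 1), c(1, 1, 0))
  expect_equal(signature_response(M, w3), c(1, 0))
  expect_error(signature_response(c(1, 2), w3), "grid mismatch")
})

test_that("local pattern expression uses absolute weights when asked", {
  img <- c(2, 3, 1)
  all_vox <- 1:3
  expect_equal(local_pattern_expression(img, all_vox, w3, absolute = TRUE), 7)
  expect_equal(local_pattern_expression(img, all_vox, w3, absolute = FALSE), 1)
  expect_equal(local_pattern_expression(img, 2L, w3, absolute = FALSE), -3)
  expect_error(local_pattern_expression(img, 9L, w3), "outside")
})

test_that("signed local expressions over a partition sum to the global response", {
  g <- make_grid(c(6, 5, 4), "full")
  set.seed(2)
  w <- weight_map(rnorm(g$n_vox), g)
  img <- rnorm(g$n_vox)
  parts <- split(seq_len(g$n_vox), rep(1:4, length.out = g$n_vox))
  locals <- vapply(parts, function(vox) {
    local_pattern_expression(img, vox, w, absolute = FALSE)
  }, numeric(1))
  expect_equal(sum(locals), signature_response(img, w), tolerance = 1e-10)
})

test_that("intensity correlation analysis applies Fisher z and Bonferroni", {
  expect_equal(bonferroni_alpha(0.05, 44), 0.05 / 44)
  datasets <- ref_datasets()[1:6]
  truth <- ref_truth()
  regions <- lapply(truth$subregions[1:4], function(s) s$voxels)
  rep <- intensity_correlation_analysis(datasets, regions,
                                        truth$nociceptive_pattern)
  expect_equal(rep$alpha_corrected, 0.05 / 4)
  expect_equal(rep$z, atanh(rep$r), tolerance = 1e-10)
  expect_equal(dim(rep$r), c(6L, 4L))
  # atanh oracle values
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  expect_equal(atanh(0), 0)
  expect_error(intensity_correlation_analysis(datasets[1:2], regions,
                                              truth$nociceptive_pattern),
               "3 subjects")
})

test_that("regions on the nociceptive support track intensity, endo-only ones do not", {
  datasets <- ref_datasets()[1:8]
  truth <- ref_truth()
  # a combined signature carrying both planted patterns
  combo <- weight_map(truth$nociceptive_pattern$values +
                        truth$endogenous_pattern$values, ref_grid())
  noci_vox <- order(-abs(truth$nociceptive_pattern$values))[1:40]
  endo_only <- setdiff(which(truth$endogenous_pattern$values != 0),
                       which(truth$nociceptive_pattern$values != 0))
  rep <- intensity_correlation_analysis(
    datasets, list(noci = noci_vox, endo = endo_only), combo,
    family_alpha = 0.05)
  expect_true(rep$significant[1])
  expect_gt(rep$mean_r[1], 0.25)
  expect_false(rep$significant[2])
  expect_lt(abs(rep$mean_r[2]), 0.2)
})

test_that("leave-one-subject-out scoring has no leakage and is symmetric", {
  g <- ref_grid()
  truth <- ref_truth()
  des <- make_study_design("generic")
  base <- lapply(1:4, function(i) {
    generate_trial_dataset(des, g, truth, sprintf("s%02d", i), seed = 300 + i)
  })
  # identical subjects: identical held-out maps
  same <- lapply(1:3, function(i) {
    d <- base[[1]]
    d$subject_id <- sprintf("c%02d", i)
    d
  })
  ls <- loso_develop_and_apply(same, ref_reference(), seed = 5)
  expect_equal(ls[[1]]$map$values, ls[[2]]$map$values, tolerance = 1e-12)
  expect_equal(ls[[2]]$map$values, ls[[3]]$map$values, tolerance = 1e-12)
  # perturbing a held-out subject's ratings leaves its own map unchanged
  ls0 <- loso_develop_and_apply(base, ref_reference(), seed = 5)
  pert <- base
  set.seed(9)
  pert[[2]]$ratings <- sample(pert[[2]]$ratings)
  ls1 <- loso_develop_and_apply(pert, ref_reference(), seed = 5)
  expect_equal(ls0[[2]]$map$values, ls1[[2]]$map$values, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ls0[[1]]$map$values, ls1[[1]]$map$values)))
  expect_error(loso_develop_and_apply(base[1:2], ref_reference()), "3 subjects")
})

test_that("quartile-binned correlation hits the exact endpoints and the null", {
  set.seed(3)
  y <- rnorm(40)
  expect_equal(quartile_binned_correlation(y, y), 1)
  expect_equal(quartile_binned_correlation(-y, y), -1)
  expect_error(quartile_binned_correlation(y[1:5], y[1:5]), "8 trials")
  # independent prediction: null-centred across simulated subjects
  rs <- vapply(1:3000, function(i) {
    quartile_binned_correlation(rnorm(16), rnorm(16))
  }, numeric(1))
  expect_lt(abs(mean(rs)), 3 * sd(rs) / sqrt(length(rs)))
})

test_that("forced-choice accuracy is exact for perfect responses and null at 0.5", {
  set.seed(4)
  y <- rnorm(60)
  expect_equal(forced_choice_accuracy(y, y, n_avg = 1), 1)
  expect_equal(forced_choice_accuracy(y, y, n_avg = 4), 1)
  acc_null <- vapply(1:300, function(s) {
    forced_choice_accuracy(rnorm(40), rnorm(40), seed = s)
  }, numeric(1))
  expect_lt(abs(mean(acc_null) - 0.5), 3 * sd(acc_null) / sqrt(300))
  expect_error(forced_choice_accuracy(y[1:10], y[1:10], frac = 0.1, n_avg = 4),
               "too few")
})
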