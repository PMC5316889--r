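#' Signature response: dot-product pattern expression
#'
#' The scalar expression of a weight map in an activation image: the dot
#' product over in-mask voxels. Images must live on the map's grid; no
#' implicit resampling is performed.
#'
#' @param image numeric vector of length `n_vox`, or a trials x voxels
#'   matrix (one response per row), or a `weight_map`.
#' @param map a `weight_map`.
#' @return scalar, or a vector with one response per image row.
#' @export
signature_response <- function(image, map) {
  if (inherits(image, "weight_map")) {
    stop_if_grid_mismatch(image$grid, map$grid, "image")
    image <- image$values
  }
  if (is.matrix(image)) {
    if (ncol(image) != length(map$values)) stop("grid mismatch: image has wrong voxel count")
    return(as.numeric(image %*% map$values))
  }
  if (length(image) != length(map$values)) stop("grid mismatch: image has wrong voxel count")
  sum(image * map$values)
}

#' Local pattern expression within a region
#'
#' The dot product restricted to a region's voxels. With `absolute = TRUE`
#' (the convention for intensity-correlation analyses) the weights are
#' replaced by their absolute values, so a positive correlation with
#' stimulus intensity always means the region's activity increases with
#' intensity regardless of the weights' signs.
#'
#' @param image image vector or trials x voxels matrix.
#' @param region a `region` (from [extract_regions()]) or an integer vector
#'   of grid-linearization voxel indices.
#' @param map the `weight_map` supplying the local weights.
#' @param absolute use absolute weights.
#' @return scalar or per-row vector.
#' @export
local_pattern_expression <- function(image, region, map, absolute = TRUE) {
  vox <- if (inherits(region, "region")) region$voxels else as.integer(region)
  if (any(vox < 1 | vox > length(map$values))) {
    stop("region voxels fall outside the map's grid")
  }
  w <- map$values[vox]
  if (absolute) w <- abs(w)
  if (is.matrix(image)) {
    if (ncol(image) != length(map$values)) stop("grid mismatch: image has wrong voxel count")
    return(as.numeric(image[, vox, drop = FALSE] %*% w))
  }
  if (length(image) != length(map$values)) stop("grid mismatch: image has wrong voxel count")
  sum(image[vox] * w)
}

#' Region-wise correlation with stimulus intensity
#'
#' For every region and subject, the Pearson correlation between
#' trial-by-trial local pattern expression (absolute weights) and the
#' stimulus-intensity level; correlations are Fisher z-transformed and a
#' one-sample t-test across subjects is run per region, with a Bonferroni
#' per-test threshold of `family_alpha / m` over the m regions. This sorts
#' regions into intensity-tracking versus intensity-independent
#' contributors to the signature.
#'
#' @param datasets list of `trial_dataset`s (>= 3; painful trials are used).
#' @param regions list of regions (or voxel-index vectors).
#' @param map the signature `weight_map`.
#' @param family_alpha family-wise level for the Bonferroni correction.
#' @return a `correlation_report`: `r` (subjects x regions), `z`
#'   (Fisher-transformed), per-region `t`, `p`, `mean_r`, `significant`,
#'   and `alpha_corrected = family_alpha / m`.
#' @export
intensity_correlation_analysis <- function(datasets, regions, map,
                                           family_alpha = 0.05) {
  if (length(datasets) < 3) stop("need at least 3 subjects")
  m <- length(regions)
  if (m == 0) stop("no regions supplied")
  r <- matrix(NA_real_, length(datasets), m)
  for (s in seq_along(datasets)) {
    d <- datasets[[s]]
    inc <- which(d$painful_flag & !d$excluded_flag)
    intensity <- d$intensity[inc]
    if (stats::sd(intensity) == 0) {
      warning(sprintf("subject %s has constant intensity; skipped", d$subject_id))
      next
    }
    for (j in seq_len(m)) {
      expr <- local_pattern_expression(d$X[inc, , drop = FALSE], regions[[j]],
                                       map, absolute = TRUE)
      if (stats::sd(expr) > 0) r[s, j] <- stats::cor(expr, intensity)
    }
  }
  z <- atanh(pmin(pmax(r, -1 + 1e-12), 1 - 1e-12))
  alpha_corrected <- family_alpha / m
  t <- p <- numeric(m)
  for (j in seq_len(m)) {
    zj <- z[!is.na(z[, j]), j]
    if (length(zj) < 3 || stats::sd(zj) == 0) {
      t[j] <- NA_real_; p[j] <- NA_real_
    } else {
      tt <- stats::t.test(zj)
      t[j] <- unname(tt$statistic); p[j] <- tt$p.value
    }
  }
  structure(list(r = r, z = z, t = t, p = p,
                 mean_r = colMeans(r, na.rm = TRUE),
                 significant = !is.na(p) & p < alpha_corrected,
                 alpha_corrected = alpha_corrected,
                 family_alpha = family_alpha, n_regions = m),
            class = "correlation_report")
}

#' Bonferroni per-test threshold
#'
#' @param family_alpha family-wise level.
#' @param m number of tests.
#' @return `family_alpha / m`.
#' @export
bonferroni_alpha <- function(family_alpha = 0.05, m = 44) family_alpha / m

#' Leave-one-subject-out signature development and application
#'
#' For every subject, the group signature is aggregated from the *other*
#' subjects' decoder maps and applied to the held-out subject's trial
#' images, so no subject ever influences its own scoring. Because the
#' development pipeline is per-subject up to the aggregation step, subject
#' models are fitted once and reused across folds.
#'
#' @inheritParams develop_signature
#' @return list with one element per subject: `responses` (held-out
#'   signature response per painful trial), `ratings`, `residual_ratings`
#'   (after intensity/reference residualization), `map` (the held-out
#'   `weight_map`), `cor` (response vs residual rating).
#' @export
loso_develop_and_apply <- function(datasets, reference_map = NULL,
                                   n_components = "all", k = 10,
                                   folds = "random", seed = 1) {
  n <- length(datasets)
  if (n < 3) stop("leave-one-subject-out needs at least 3 subjects")
  grid <- datasets[[1]]$grid
  models <- lapply(seq_len(n), function(i) {
    fit_subject_model(datasets[[i]], reference_map,
                      n_components = n_components, k = k,
                      seed = seed + i, folds = folds)
  })
  residuals <- lapply(datasets, residualize_subject, reference_map = reference_map)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    agg <- aggregate_group_map(models[-i])
    map <- weight_map(agg$weights, grid, sprintf("loso_wo_%s", datasets[[i]]$subject_id))
    inc <- residuals[[i]]$included
    resp <- signature_response(datasets[[i]]$X[inc, , drop = FALSE], map)
    yres <- residuals[[i]]$y_res
    out[[i]] <- list(
      subject_id = datasets[[i]]$subject_id,
      responses = resp,
      ratings = datasets[[i]]$ratings[inc],
      residual_ratings = yres,
      map = map,
      cor = if (stats::sd(resp) > 0 && stats::sd(yres) > 0) {
        stats::cor(resp, yres)
      } else NA_real_
    )
  }
  names(out) <- vapply(datasets, function(d) d$subject_id, character(1))
  out
}

#' Quartile-binned prediction-outcome correlation
#'
#' Both series are z-scored, trials are binned into quartiles of the actual
#' outcome (stable sort: ties keep trial order), both series are averaged
#' within bins, and the Pearson correlation over the four bin means is
#' returned. Binning before correlating summarizes the monotone
#' prediction-outcome relationship robustly at the subject level.
#'
#' @param predicted,actual per-trial series (>= 8 trials).
#' @return correlation over the 4 bin means.
#' @export
quartile_binned_correlation <- function(predicted, actual) {
  n <- length(actual)
  if (length(predicted) != n) stop("length mismatch")
  if (n < 8) stop("need at least 8 trials for quartile binning")
  zp <- as.numeric(scale(predicted))
  za <- as.numeric(scale(actual))
  ord <- order(za, seq_len(n))     # stable: ties broken by trial index
  bin <- rep(1:4, times = diff(floor(seq(0, n, length.out = 5))))
  bp <- tapply(zp[ord], bin, mean)
  ba <- tapply(za[ord], bin, mean)
  stats::cor(bp, ba)
}

#' Forced-choice discrimination accuracy
#'
#' Trials are ranked by rating; the top and bottom `frac` form the high and
#' low classes. Each class is randomly partitioned (seeded) into sets of
#' `n_avg` trials whose responses are averaged; accuracy is the fraction of
#' all high-set x low-set pairs in which the high average exceeds the low
#' average (ties count 1/2). Averaging over several trials before the
#' comparison trades trial count for per-comparison reliability.
#'
#' @param responses signature responses per trial.
#' @param ratings pain ratings per trial.
#' @param frac fraction of trials in each class.
#' @param n_avg trials averaged per set.
#' @param seed grouping seed.
#' @return accuracy in \[0, 1\].
#' @export
forced_choice_accuracy <- function(responses, ratings, frac = 0.30,
                                   n_avg = 1, seed = 1) {
  n <- length(ratings)
  if (length(responses) != n) stop("length mismatch")
  k <- floor(frac * n)
  if (k < n_avg) stop("too few trials for a single averaged pair")
  ord <- order(ratings, seq_len(n))
  low_idx <- ord[seq_len(k)]
  high_idx <- ord[seq(n - k + 1, n)]
  local_seed(seed, {
    grp <- function(idx) {
      idx <- sample(idx)
      m <- floor(length(idx) / n_avg)
      vapply(seq_len(m), function(g) {
        mean(responses[idx[seq((g - 1) * n_avg + 1, g * n_avg)]])
      }, numeric(1))
    }
    hi <- grp(high_idx)
    lo <- grp(low_idx)
    cmp <- outer(hi, lo, `-`)
    mean((cmp > 0) + 0.5 * (cmp == 0))
  })
}
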