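#' Residualize a subject's trials against intensity and a reference signature
#'
#' Removes everything a stimulus-intensity-tracking model can explain from
#' both the ratings and every voxel: builds the per-subject design
#' \[intercept, one indicator per intensity level above the lowest, the
#' reference-signature response per trial\], projects it out of the rating
#' vector and of every voxel column, and returns the residuals. Indicators
#' model *all possible differences among levels* (no linearity assumption).
#' Only painful, non-excluded trials enter.
#'
#' Residuals are orthogonal to every design column to 1e-8 by construction.
#' A level observed on a single trial has its residual forced to exactly 0
#' (with a warning); a constant reference response is dropped with a
#' warning.
#'
#' @param dataset a `trial_dataset`.
#' @param reference_map optional [weight_map()] reference signature (its
#'   dot-product response per trial is an additional regressor).
#' @return list with `X_res` (included trials x voxels), `y_res`,
#'   `included` (trial indices used), `design` (the projection design),
#'   `ref_response`.
#' @export
residualize_subject <- function(dataset, reference_map = NULL) {
  inc <- included_trials(dataset)
  y <- dataset$ratings[inc]
  Xv <- dataset$X[inc, , drop = FALSE]
  lev <- dataset$intensity[inc]
  tab <- table(lev)
  if (any(tab < 2)) {
    warning("intensity level(s) with a single trial: residuals there are exactly 0")
  }
  if (length(tab) < 1 || length(inc) < 2) stop("too few included trials to residualize")

  levs <- sort(unique(lev))
  D <- matrix(1, length(inc), 1)
  cn <- "intercept"
  for (l in levs[-1]) {   # lowest level is the reference category
    D <- cbind(D, as.numeric(lev == l))
    cn <- c(cn, paste0("level_", l))
  }
  ref_resp <- NULL
  if (!is.null(reference_map)) {
    stop_if_grid_mismatch(dataset$grid, reference_map$grid, "reference map")
    ref_resp <- as.numeric(Xv %*% reference_map$values)
    if (stats::sd(ref_resp) == 0) {
      warning("reference-signature responses are constant; dropping that regressor")
    } else {
      D <- cbind(D, ref_resp)
      cn <- c(cn, "reference")
    }
  }
  colnames(D) <- cn
  qd <- qr(D)
  y_res <- qr.resid(qd, y)
  X_res <- qr.resid(qd, Xv)
  list(X_res = X_res, y_res = as.numeric(y_res), included = inc,
       design = D, ref_response = ref_resp)
}

#' Principal component regression decoder for one subject
#'
#' Centres the trial matrix and ratings, takes the singular value
#' decomposition, regresses the ratings on the leading component scores and
#' maps the coefficients back to voxel space. With `n_components = "all"`
#' every component with a nonzero singular value is kept, which equals
#' ordinary least squares on tall full-rank data and the minimum-norm least
#' squares solution when trials < voxels.
#'
#' @param X_res trials x voxels residual matrix.
#' @param y_res residual ratings.
#' @param n_components `"all"` or a positive integer (clamped to the rank
#'   with a warning).
#' @return a `subject_model` with `weights`, `intercept`, `n_components`,
#'   `n_trials_used`, and `cv_r = NA` (filled by
#'   [crossval_prediction_corr()] or [fit_subject_model()]).
#' @export
fit_subject_pcr <- function(X_res, y_res, n_components = "all") {
  X_res <- as.matrix(X_res)
  stopifnot(nrow(X_res) == length(y_res))
  xm <- colMeans(X_res)
  ym <- mean(y_res)
  Xc <- sweep(X_res, 2, xm)
  yc <- y_res - ym
  sv <- svd(Xc)
  tol <- max(dim(Xc)) * .Machine$double.eps * max(sv$d, 0)
  rank <- sum(sv$d > tol)
  k <- if (identical(n_components, "all")) rank else as.integer(n_components)
  if (k > rank) {
    warning(sprintf("n_components clamped from %d to rank %d", k, rank))
    k <- rank
  }
  if (k == 0 || stats::sd(y_res) == 0) {
    w <- numeric(ncol(X_res))
  } else {
    idx <- seq_len(k)
    # score regression: gamma = (S'S)^-1 S'y with S = U D  =>  U'y / d
    gamma <- crossprod(sv$u[, idx, drop = FALSE], yc)[, 1] / sv$d[idx]
    w <- as.numeric(sv$v[, idx, drop = FALSE] %*% gamma)
  }
  structure(list(weights = w, intercept = ym - sum(xm * w),
                 n_components = k, n_trials_used = nrow(X_res),
                 cv_r = NA_real_, subject_id = NULL),
            class = "subject_model")
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf("<subject_model>%s %d voxels, %d components, cv_r = %s\n",
              if (!is.null(x$subject_id)) paste0(" ", x$subject_id) else "",
              length(x$weights), x$n_components,
              if (is.na(x$cv_r)) "NA" else sprintf("%.3f", x$cv_r)))
  invisible(x)
}

predict_subject_model <- function(model, X) {
  as.numeric(as.matrix(X) %*% model$weights) + model$intercept
}

#' Cross-validated prediction-outcome correlation
#'
#' Partitions trials into `k` folds (seeded random partition, or contiguous
#' run-blocks via `folds = "contiguous"` when trial autocorrelation is a
#' concern), fits the PCR decoder on k-1 folds, predicts the held-out fold,
#' and returns the Pearson correlation between the concatenated out-of-fold
#' predictions and the outcomes. This is the subject's precision weight for
#' group aggregation.
#'
#' @param X_res,y_res residualized trials and ratings.
#' @param k number of folds (default 10).
#' @param seed partition seed.
#' @param n_components passed to [fit_subject_pcr()].
#' @param folds `"random"` or `"contiguous"`.
#' @return scalar correlation (0, with a warning, if predictions are
#'   constant).
#' @export
crossval_prediction_corr <- function(X_res, y_res, k = 10, seed = 1,
                                     n_components = "all",
                                     folds = c("random", "contiguous")) {
  folds <- match.arg(folds)
  n <- length(y_res)
  if (n < k) stop("need at least k trials")
  fold_id <- if (folds == "random") {
    local_seed(seed, sample(rep(seq_len(k), length.out = n)))
  } else {
    sort(rep(seq_len(k), length.out = n))
  }
  pred <- numeric(n)
  for (f in seq_len(k)) {
    test <- fold_id == f
    m <- fit_subject_pcr(X_res[!test, , drop = FALSE], y_res[!test],
                         n_components = n_components)
    pred[test] <- predict_subject_model(m, X_res[test, , drop = FALSE])
  }
  if (stats::sd(pred) == 0 || stats::sd(y_res) == 0) {
    warning("constant cross-validated predictions; cv_r set to 0")
    return(0)
  }
  stats::cor(pred, y_res)
}

#' Residualize, fit, and cross-validate one subject
#'
#' Convenience wrapper running [residualize_subject()],
#' [fit_subject_pcr()] and [crossval_prediction_corr()] for one dataset.
#'
#' @inheritParams residualize_subject
#' @inheritParams crossval_prediction_corr
#' @return a `subject_model` with `cv_r` filled in.
#' @export
fit_subject_model <- function(dataset, reference_map = NULL,
                              n_components = "all", k = 10, seed = 1,
                              folds = "random") {
  res <- residualize_subject(dataset, reference_map)
  m <- fit_subject_pcr(res$X_res, res$y_res, n_components = n_components)
  m$cv_r <- crossval_prediction_corr(res$X_res, res$y_res, k = k, seed = seed,
                                     n_components = n_components,
                                     folds = folds)
  m$subject_id <- dataset$subject_id
  m
}

#' Precision-weighted group aggregation of subject decoder maps
#'
#' Each subject's weight map is first normalized by the standard deviation
#' of its own weights (so scale differences across subjects and studies do
#' not dominate), then averaged with the cross-validated prediction-outcome
#' correlations as weights. Negative correlations are clipped to zero so a
#' subject whose decoder failed contributes nothing rather than subtracting.
#'
#' @param models list of `subject_model`s with `cv_r` set.
#' @return list with `weights` (the group map vector), `subject_weights`
#'   (the clipped cv_r used), `normalized_maps` (subjects x voxels matrix of
#'   sd-normalized maps, reused by the weighted t-test).
#' @export
aggregate_group_map <- function(models) {
  cv <- vapply(models, function(m) m$cv_r, numeric(1))
  if (anyNA(cv)) stop("all subject models need a cv_r (run crossval first)")
  w <- pmax(cv, 0)
  if (sum(w) <= 0) stop("no positive precision mass: all cv_r <= 0")
  maps <- t(vapply(models, function(m) {
    s <- stats::sd(m$weights)
    if (s == 0) m$weights else m$weights / s
  }, numeric(length(models[[1]]$weights))))
  list(weights = as.numeric(crossprod(maps, w) / sum(w)),
       subject_weights = w, normalized_maps = maps)
}

#' Weighted one-sample t-test
#'
#' Reliability-weights form: zero-weight subjects are dropped (so the test
#' depends only on the weight support), the remaining weights are
#' normalized to sum to n, and the weighted mean m and weighted variance
#' s2 = sum(w (x - m)^2) / (n - 1) give t = m / sqrt(s2 / n) on n - 1
#' degrees of freedom, two-tailed. With equal weights this is exactly the
#' classical one-sample t-test. Applied column-wise when `x` is a matrix
#' (subjects x voxels).
#'
#' @param x numeric vector (one value per subject) or subjects x voxels
#'   matrix.
#' @param weights nonnegative, not all zero; default equal.
#' @return list with `t`, `p` (two-tailed), `df`, `mean`. Zero-variance
#'   columns give infinite t with the sign of the mean and p = 0.
#' @export
weighted_one_sample_ttest <- function(x, weights = NULL) {
  x <- as.matrix(x)
  if (is.null(weights)) weights <- rep(1, nrow(x))
  if (any(weights < 0) || sum(weights) == 0) {
    stop("weights must be nonnegative and not all zero")
  }
  keep <- weights > 0
  x <- x[keep, , drop = FALSE]
  weights <- weights[keep]
  n <- nrow(x)
  if (n < 3) stop("need at least 3 subjects with positive weight")
  w <- weights * n / sum(weights)
  m <- colSums(w * x) / n
  s2 <- colSums(w * sweep(x, 2, m)^2) / (n - 1)
  t <- ifelse(s2 > 0, m / sqrt(s2 / n), sign(m) * Inf)
  t[s2 == 0 & m == 0] <- 0
  p <- ifelse(is.finite(t), 2 * stats::pt(-abs(t), df = n - 1),
              0)
  p[t == 0 & s2 == 0] <- 1
  list(t = as.numeric(t), p = as.numeric(p), df = n - 1, mean = as.numeric(m))
}

#' Benjamini-Hochberg rejection mask
#'
#' Step-up false discovery rate control at level `q`.
#'
#' @param p p-values.
#' @param q FDR level.
#' @return logical rejection mask (empty input gives an empty mask).
#' @export
bh_fdr <- function(p, q = 0.05) {
  if (length(p) == 0) return(logical(0))
  stats::p.adjust(p, method = "BH") <= q
}

#' Extract contiguous signed regions from a thresholded map
#'
#' Connected components are computed separately for surviving positive and
#' surviving negative voxels (a positive and a negative blob that touch are
#' two regions), under a 6, 18, or 26 neighbourhood. Components smaller
#' than `min_size` are dropped unless their label appears in `allowlist`
#' with a lower bound they meet.
#'
#' @param values weight/stat vector on the grid linearization (signs split
#'   the components).
#' @param grid the `grid_spec`.
#' @param mask logical vector of surviving voxels (e.g. the FDR mask).
#' @param min_size minimum component size in voxels.
#' @param connectivity 6, 18 or 26.
#' @param allowlist optional named numeric vector: label -> lower size
#'   bound (labels are assigned by sign and decreasing size, e.g.
#'   `"pos_01"`).
#' @return list of `region` objects: `voxels` (grid-linearization indices),
#'   `size`, `mean_weight`, `sign`, `label`.
#' @export
extract_regions <- function(values, grid, mask, min_size = 15,
                            connectivity = 26, allowlist = NULL) {
  stopifnot(length(values) == grid$n_vox, length(mask) == grid$n_vox)
  regions <- list()
  for (sgn in c(1, -1)) {
    sel <- which(mask & sign(values) == sgn)
    comps <- connected_components(sel, grid, connectivity)
    if (!length(comps)) next
    comps <- comps[order(-vapply(comps, length, integer(1)))]
    for (i in seq_along(comps)) {
      vox <- comps[[i]]
      lab <- sprintf("%s_%02d", if (sgn > 0) "pos" else "neg", i)
      bound <- if (!is.null(allowlist) && lab %in% names(allowlist)) {
        allowlist[[lab]]
      } else min_size
      if (length(vox) < bound) next
      regions[[length(regions) + 1]] <- structure(list(
        voxels = vox, size = length(vox),
        mean_weight = mean(values[vox]), sign = sgn, label = lab
      ), class = "region")
    }
  }
  regions
}

# Flood-fill connected components over in-mask voxel subsets.
connected_components <- function(vox, grid, connectivity = 26) {
  if (!length(vox)) return(list())
  off <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nd <- rowSums(abs(off))
  off <- switch(as.character(connectivity),
    "6" = off[nd == 1, , drop = FALSE],
    "18" = off[nd >= 1 & nd <= 2, , drop = FALSE],
    "26" = off[nd >= 1, , drop = FALSE],
    stop("connectivity must be 6, 18 or 26")
  )
  lin <- grid$vox_idx[vox]                  # full-array linear indices
  coords <- arrayInd(lin, grid$shape)
  in_set <- array(0L, grid$shape)
  in_set[lin] <- seq_along(vox)             # position within `vox`
  seen <- logical(length(vox))
  comps <- list()
  for (s in seq_along(vox)) {
    if (seen[s]) next
    queue <- s
    seen[s] <- TRUE
    members <- integer(0)
    while (length(queue)) {
      cur <- queue[[1]]
      queue <- queue[-1]
      members <- c(members, cur)
      co <- coords[cur, ]
      nb <- sweep(off, 2, co, `+`)
      okb <- nb[, 1] >= 1 & nb[, 1] <= grid$shape[1] &
             nb[, 2] >= 1 & nb[, 2] <= grid$shape[2] &
             nb[, 3] >= 1 & nb[, 3] <= grid$shape[3]
      nb <- nb[okb, , drop = FALSE]
      ids <- in_set[nb]
      ids <- ids[ids > 0L]
      ids <- ids[!seen[ids]]
      if (length(ids)) {
        seen[ids] <- TRUE
        queue <- c(queue, ids)
      }
    }
    comps[[length(comps) + 1]] <- sort(vox[members])
  }
  comps
}

#' Develop a group signature from multiple subjects
#'
#' The full development pipeline: per subject, residualize against
#' intensity indicators and the reference signature, fit the PCR decoder,
#' cross-validate its prediction-outcome correlation; then aggregate the
#' sd-normalized subject maps with the (clipped) correlations as precision
#' weights, run the weighted one-sample t-test per voxel across subjects,
#' threshold at FDR `q`, and extract contiguous signed regions.
#'
#' @param datasets list of `trial_dataset`s (>= 3).
#' @param reference_map optional reference `weight_map`.
#' @param n_components,k,folds decoder settings, see [fit_subject_pcr()]
#'   and [crossval_prediction_corr()].
#' @param q FDR level for the voxel mask.
#' @param min_size,connectivity,allowlist region extraction settings.
#' @param seed cross-validation partition seed.
#' @return a `group_signature`: `weights` (the signature `weight_map`),
#'   `t`, `p`, `q_mask`, `regions`, `models` (per-subject), and
#'   `subject_weights`.
#' @export
develop_signature <- function(datasets, reference_map = NULL,
                              n_components = "all", k = 10, folds = "random",
                              q = 0.05, min_size = 15, connectivity = 26,
                              allowlist = NULL, seed = 1) {
  if (length(datasets) < 3) stop("signature development needs at least 3 subjects")
  grid <- datasets[[1]]$grid
  models <- lapply(seq_along(datasets), function(i) {
    fit_subject_model(datasets[[i]], reference_map,
                      n_components = n_components, k = k,
                      seed = seed + i, folds = folds)
  })
  agg <- aggregate_group_map(models)
  tt <- weighted_one_sample_ttest(agg$normalized_maps, agg$subject_weights)
  qm <- bh_fdr(tt$p, q)
  regions <- extract_regions(agg$weights, grid, qm, min_size = min_size,
                             connectivity = connectivity,
                             allowlist = allowlist)
  structure(list(
    weights = weight_map(agg$weights, grid, "group signature"),
    t = tt$t, p = tt$p, q_mask = qm, q = q,
    regions = regions, models = models,
    subject_weights = agg$subject_weights, n_subjects = length(datasets)
  ), class = "group_signature")
}

#' @export
print.group_signature <- function(x, ...) {
  cat(sprintf("<group_signature> %d subjects, %d voxels, %d FDR-surviving, %d regions\n",
              x$n_subjects, length(x$weights$values), sum(x$q_mask),
              length(x$regions)))
  invisible(x)
}

#' Univariate encode-decode baseline
#'
#' The mass-univariate counterpart of the multivariate decoder: per subject
#' and voxel, the OLS slope of residual activity on residual rating
#' (encoding direction); slopes are averaged across subjects without
#' weighting; a test image's prediction is the mean over in-mask voxels of
#' slope times image value.
#'
#' @param residuals list of per-subject lists with `X_res` and `y_res`
#'   (as returned by [residualize_subject()]).
#' @return list with `beta_map` (group-average slope vector) and
#'   `predict(image)` returning the scalar prediction for an image vector
#'   or a matrix of images (rows).
#' @export
univariate_encode_decode <- function(residuals) {
  betas <- vapply(residuals, function(r) {
    yc <- r$y_res - mean(r$y_res)
    v <- sum(yc^2)
    if (v == 0) return(numeric(ncol(r$X_res)))
    as.numeric(crossprod(sweep(r$X_res, 2, colMeans(r$X_res)), yc)) / v
  }, numeric(ncol(residuals[[1]]$X_res)))
  betas <- matrix(betas, nrow = ncol(residuals[[1]]$X_res))
  beta_map <- rowMeans(betas)
  list(
    beta_map = beta_map,
    predict = function(image) {
      if (is.matrix(image)) as.numeric(image %*% beta_map) / length(beta_map)
      else mean(beta_map * image)
    }
  )
}
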