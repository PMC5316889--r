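#' Canonical haemodynamic response function
#'
#' The standard double-gamma kernel: a positive gamma density peaking near
#' 5 s minus a scaled undershoot gamma peaking near 15 s, sampled on a
#' regular time grid over 32 s of support and scaled to unit peak. The
#' kernel is causal (zero at t = 0).
#'
#' @param dt sampling interval in seconds (> 0).
#' @param duration kernel support in seconds.
#' @param peak_delay,undershoot_delay gamma shape parameters (seconds, with
#'   unit dispersion these are the modes + 1).
#' @param dispersion,u_dispersion gamma scale parameters.
#' @param ratio undershoot amplitude relative to the peak gamma.
#' @return numeric vector of kernel values at `seq(0, duration, by = dt)`.
#' @export
canonical_hrf <- function(dt, duration = 32, peak_delay = 6,
                          undershoot_delay = 16, dispersion = 1,
                          u_dispersion = 1, ratio = 1 / 6) {
  if (dt <= 0) stop("`dt` must be positive")
  t <- seq(0, duration, by = dt)
  h <- stats::dgamma(t, shape = peak_delay / dispersion, scale = dispersion) -
    ratio * stats::dgamma(t, shape = undershoot_delay / u_dispersion,
                          scale = u_dispersion)
  h / max(h)
}

# One convolved boxcar regressor per event, sampled at scan times.
# Convolution runs on a fine grid (dt seconds) and is read out at
# t = (0:(n_scans-1)) * tr. `shift` delays the kernel (used by the flexible
# basis set).
convolved_regressors <- function(onsets, durations, n_scans, tr, dt = 0.1,
                                 kernel = NULL, shift = 0) {
  if (is.null(kernel)) kernel <- canonical_hrf(dt)
  durations <- rep(durations, length.out = length(onsets))
  n_hr <- ceiling(n_scans * tr / dt) + length(kernel) + 1
  scan_idx <- round((seq_len(n_scans) - 1) * tr / dt) + 1
  out <- matrix(0, n_scans, length(onsets))
  for (e in seq_along(onsets)) {
    box <- numeric(n_hr)
    i0 <- floor((onsets[e] + shift) / dt) + 1
    i1 <- min(n_hr, floor((onsets[e] + shift + durations[e]) / dt) + 1)
    if (i0 >= 1 && i0 <= n_hr) box[i0:i1] <- 1
    conv <- stats::filter(box, kernel, method = "convolution", sides = 1)
    conv[is.na(conv)] <- 0
    # sides=1 filter computes sum_k kernel[k] * box[i-k+1]; rescale by dt to
    # approximate the continuous convolution integral
    out[, e] <- conv[scan_idx] * dt
  }
  out
}

#' Build a beta-series (single-trial) design matrix
#'
#' One convolved boxcar regressor per trial, plus an intercept, an optional
#' linear drift, caller-supplied nuisance columns (for example head-motion
#' estimates), and one indicator column per flagged spike volume. A
#' variance inflation factor is computed for every trial regressor as
#' 1 / (1 - R^2) from regressing it on all other columns; rank-deficient
#' designs yield infinite VIFs rather than an error.
#'
#' @param events data frame with `onset` and `duration` (seconds) and
#'   optionally `trial` ids.
#' @param n_scans number of volumes in the run.
#' @param tr repetition time in seconds.
#' @param nuisance optional numeric matrix with `n_scans` rows.
#' @param spike_volumes 1-based indices of volumes to absorb with
#'   indicator regressors.
#' @param drift include a linear drift column.
#' @param dt high-resolution convolution grid (seconds).
#' @param hrf kernel sampled at `dt`; defaults to [canonical_hrf()].
#' @return A `design_matrix`: `matrix` (n_scans x p), `labels` (one of
#'   "trial", "intercept", "drift", "nuisance", "spike"), `trial_cols`,
#'   `vif` (per trial regressor), `tr`, `dt`.
#' @export
build_single_trial_design <- function(events, n_scans, tr, nuisance = NULL,
                                      spike_volumes = NULL, drift = TRUE,
                                      dt = 0.1, hrf = NULL) {
  stopifnot(all(c("onset", "duration") %in% names(events)))
  if (any(events$onset < 0) || any(events$onset >= n_scans * tr)) {
    stop("event onsets must lie within the run")
  }
  trials <- convolved_regressors(events$onset, events$duration, n_scans, tr,
                                 dt = dt, kernel = hrf)
  n_trials <- ncol(trials)
  cols <- list(trials)
  labels <- rep("trial", n_trials)
  cols <- c(cols, list(matrix(1, n_scans, 1)))
  labels <- c(labels, "intercept")
  if (drift) {
    cols <- c(cols, list(matrix(seq_len(n_scans) - (n_scans + 1) / 2, ncol = 1)))
    labels <- c(labels, "drift")
  }
  if (!is.null(nuisance)) {
    nuisance <- as.matrix(nuisance)
    if (nrow(nuisance) != n_scans) stop("nuisance rows must equal n_scans")
    cols <- c(cols, list(nuisance))
    labels <- c(labels, rep("nuisance", ncol(nuisance)))
  }
  if (length(spike_volumes)) {
    sp <- matrix(0, n_scans, length(spike_volumes))
    sp[cbind(spike_volumes, seq_along(spike_volumes))] <- 1
    cols <- c(cols, list(sp))
    labels <- c(labels, rep("spike", ncol(sp)))
  }
  X <- do.call(cbind, cols)
  colnames(X) <- make.unique(labels)
  trial_cols <- which(labels == "trial")
  vif <- vapply(trial_cols, function(j) vif_of_column(X, j), numeric(1))
  structure(list(matrix = X, labels = labels, trial_cols = trial_cols,
                 vif = vif, tr = tr, dt = dt,
                 trial_id = events$trial %||% seq_len(n_trials)),
            class = "design_matrix")
}

# VIF of column j: 1/(1 - R^2) of the regression of X[, j] on all other
# columns. R^2 is taken about the mean (an intercept is part of the design).
# Residual variance at numerical zero => infinite VIF.
vif_of_column <- function(X, j) {
  y <- X[, j]
  Z <- X[, -j, drop = FALSE]
  sst <- sum((y - mean(y))^2)
  if (sst == 0) return(Inf)
  qz <- qr(Z)
  res <- qr.resid(qz, y)
  sse <- sum(res^2)
  r2 <- 1 - sse / sst
  if (r2 >= 1 - 1e-12) return(Inf)
  1 / (1 - r2)
}

#' Estimate trial betas by ordinary least squares
#'
#' Fits the beta-series design to every voxel time course and returns the
#' trial-regressor coefficients, flagging (never deleting) trials whose
#' design VIF exceeds the threshold. Rank-deficient designs are solved by
#' the minimum-norm (pseudoinverse) solution so flagged trials still get a
#' numeric estimate.
#'
#' @param timeseries n_scans x voxels matrix.
#' @param design a [build_single_trial_design()] object.
#' @param vif_threshold trials with VIF above this are flagged excluded.
#' @return list with `betas` (trials x voxels) and `qc` (a `qc_report` with
#'   `excluded_trials`, `vif`, `vif_threshold`).
#' @export
estimate_trial_betas <- function(timeseries, design, vif_threshold = 2.5) {
  timeseries <- as.matrix(timeseries)
  X <- design$matrix
  if (nrow(timeseries) != nrow(X)) stop("timeseries rows must match the design")
  if (nrow(X) < ncol(X)) stop("fewer time points than regressors")
  coef <- pinv_solve(X, timeseries)
  betas <- coef[design$trial_cols, , drop = FALSE]
  excluded <- design$trial_id[design$vif > vif_threshold]
  qc <- structure(list(excluded_trials = excluded, vif = design$vif,
                       vif_threshold = vif_threshold,
                       spike_indices = integer(0)),
                  class = "qc_report")
  list(betas = betas, qc = qc)
}

# Minimum-norm least squares via SVD (handles rank deficiency).
pinv_solve <- function(X, Y) {
  sv <- svd(X)
  tol <- max(dim(X)) * .Machine$double.eps * sv$d[1]
  pos <- sv$d > tol
  dinv <- ifelse(pos, 1 / sv$d, 0)
  sv$v %*% (dinv * crossprod(sv$u, Y))
}

#' Detect image-intensity outlier volumes ("spikes")
#'
#' For each volume, slice-wise means and standard deviations (along the
#' third axis) are concatenated into a feature vector; squared Mahalanobis
#' distances of these vectors to their sample distribution are referred to
#' a chi-square law with df = number of features, and volumes significant
#' under the stricter of Bonferroni and Benjamini-Hochberg correction at
#' `alpha` are flagged.
#'
#' @param stack 4-D array (x, y, z, time), at least 10 volumes.
#' @param alpha family-wise level for the corrections.
#' @return a `qc_report` with `spike_indices`, `spike_stat` (squared
#'   Mahalanobis distance per volume), `p`, `chi2_threshold` (the applied
#'   per-volume chi-square cutoff), `df`.
#' @export
detect_spikes <- function(stack, alpha = 0.05) {
  stopifnot(length(dim(stack)) == 4)
  n_t <- dim(stack)[4]
  if (n_t < 10) stop("need at least 10 volumes")
  nz <- dim(stack)[3]
  # slice-wise mean and s.d. per volume: reshape to (in-slice voxels) x
  # (slice, volume) and take column statistics
  m <- matrix(stack, prod(dim(stack)[1:2]), nz * n_t)
  sl_mean <- matrix(colMeans(m), nz, n_t)
  sl_sd <- matrix(sqrt(colMeans(m^2) - colMeans(m)^2) *
                    sqrt(nrow(m) / (nrow(m) - 1)), nz, n_t)
  feats <- cbind(t(sl_mean), t(sl_sd))
  keep <- apply(feats, 2, stats::sd) > 0
  if (!any(keep)) {
    warning("all slice statistics are constant; no spikes flagged")
    return(structure(list(spike_indices = integer(0),
                          spike_stat = rep(0, n_t), p = rep(1, n_t),
                          chi2_threshold = Inf, df = 0L,
                          excluded_trials = integer(0)),
                     class = "qc_report"))
  }
  F <- feats[, keep, drop = FALSE]
  S <- stats::cov(F)
  ev_min <- min(eigen(S, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < 1e-10 * mean(diag(S))) {
    warning("singular slice-statistic covariance; ridge-regularizing")
    S <- S + diag(1e-6 * mean(diag(S)), ncol(S))
  }
  d2 <- stats::mahalanobis(F, colMeans(F), S)
  df <- ncol(F)
  p <- stats::pchisq(d2, df = df, lower.tail = FALSE)
  bonf <- p < alpha / n_t
  bh <- stats::p.adjust(p, method = "BH") < alpha
  flags <- which(bonf & bh)  # the stricter of the two corrections
  structure(list(spike_indices = flags, spike_stat = d2, p = p,
                 chi2_threshold = stats::qchisq(alpha / n_t, df = df,
                                                lower.tail = FALSE),
                 df = df, excluded_trials = integer(0)),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("<qc_report> %d spike volumes, %d excluded trials\n",
              length(x$spike_indices), length(x$excluded_trials)))
  invisible(x)
}

#' Trial response area under the curve from a flexible basis set
#'
#' Fits three time-shifted canonical kernels per trial (shifts configurable;
#' default 0, +2, +4 s), reconstructs each trial's fitted response in each
#' voxel, and returns its trapezoidal area under the curve. This lets the
#' modelled response shape vary across trials and voxels, which suits the
#' slow thermal-pain response better than a single fixed kernel.
#'
#' @param timeseries n_scans x voxels matrix.
#' @param events data frame with `onset`, `duration`.
#' @param n_scans,tr run geometry.
#' @param shifts numeric vector of three kernel time shifts in seconds.
#' @param nuisance,drift,dt as in [build_single_trial_design()].
#' @return trials x voxels matrix of signed AUCs (scan-time units).
#' @export
flexible_basis_auc <- function(timeseries, events, n_scans, tr,
                               shifts = c(0, 2, 4), nuisance = NULL,
                               drift = TRUE, dt = 0.1) {
  if (length(shifts) != 3) stop("the basis set has three kernels")
  timeseries <- as.matrix(timeseries)
  if (nrow(timeseries) != n_scans) stop("timeseries rows must equal n_scans")
  kernel <- canonical_hrf(dt)
  n_trials <- nrow(events)
  regs <- lapply(shifts, function(s) {
    convolved_regressors(events$onset, events$duration, n_scans, tr,
                         dt = dt, kernel = kernel, shift = s)
  })
  # columns ordered trial-major: (trial 1: b1 b2 b3), (trial 2: ...), ...
  Xtr <- matrix(0, n_scans, 3 * n_trials)
  for (j in 1:3) Xtr[, seq(j, by = 3, length.out = n_trials)] <- regs[[j]]
  extra <- cbind(rep(1, n_scans),
                 if (drift) seq_len(n_scans) - (n_scans + 1) / 2,
                 nuisance)
  X <- cbind(Xtr, extra)
  if (nrow(X) < ncol(X)) stop("fewer time points than regressors")
  coef <- pinv_solve(X, timeseries)
  # per-basis AUC of each trial's regressor on the scan grid (trapezoid)
  auc <- matrix(0, n_trials, ncol(timeseries))
  for (tri in seq_len(n_trials)) {
    fitted <- matrix(0, n_scans, ncol(timeseries))
    for (j in 1:3) {
      cidx <- (tri - 1) * 3 + j
      fitted <- fitted + tcrossprod(regs[[j]][, tri], coef[cidx, ])
    }
    auc[tri, ] <- apply(fitted, 2, trapz_auc, dx = tr)
  }
  auc
}

trapz_auc <- function(y, dx) dx * (sum(y) - (y[1] + y[length(y)]) / 2)
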