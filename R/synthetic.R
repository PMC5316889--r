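#' Generate one subject's trial-level dataset
#'
#' Simulates a trials x voxels activation matrix and per-trial behaviour
#' under the planted generative model:
#'
#' \deqn{X_t = g_I L_t u + g_E A_t v + \epsilon_t}
#'
#' where \eqn{u} is the nociceptive pattern, \eqn{v} the endogenous pattern,
#' \eqn{L_t} the intensity level and the endogenous amplitude
#' \eqn{A_t = a \cdot \mathrm{cue}_t + (\mathrm{via\ perceived\ control}) +
#' \delta_s + \eta_t} carries the condition manipulations, a subject random
#' effect and trial noise. Ratings follow
#' \deqn{y_t = r_0 + r_L L_t + b\, g_E A_t + c' \mathrm{code}_t + e_t}
#' with all rating-side coefficients rescaled to the design's rating bounds
#' (coefficients are specified on a 0-10 convention). When the design has a
#' `control` factor, a per-trial perceived-control rating
#' \eqn{M1_t = \mathrm{control}_t + e} is generated and the control
#' manipulation reaches the endogenous amplitude only through it (a
#' three-path chain); other factors load on the amplitude directly.
#'
#' A `nonpainful_frac` fraction of trials is flagged non-painful: level 0,
#' no condition effect, near-zero rating. Flags are carried, never dropped.
#'
#' @param design a [make_study_design()] `study_design`.
#' @param grid a `grid_spec` (must match `truth`).
#' @param truth a [make_ground_truth()] object.
#' @param subject_id character id.
#' @param seed integer; the dataset is a deterministic function of its
#'   arguments and the seed.
#' @return A `trial_dataset`: `X` (trials x voxels), `ratings`, `intensity`
#'   (level code, 0 for non-painful), `conditions` (data frame of +/-1
#'   codes), `perceived_control_rating` (or NULL), `painful_flag`,
#'   `excluded_flag`, `excluded_reason`, `mediation_flag`, `run`, `trial`,
#'   `truth_amplitude` (the planted \eqn{A_t}), `rating_bounds`, `grid`.
#' @export
generate_trial_dataset <- function(design, grid, truth, subject_id = "s01",
                                   seed = 1) {
  stop_if_grid_mismatch(grid, truth$grid, "ground truth")
  tr <- design$trials
  n <- nrow(tr)
  lev_codes <- design$intensity_levels
  pcols <- paste0("p_", names(lev_codes))
  scale_mult <- diff(design$rating_bounds) / 10
  lo <- design$rating_bounds[1]
  hi <- design$rating_bounds[2]

  local_seed(seed, {
    # realized intensity level per trial
    level <- vapply(seq_len(n), function(i) {
      p <- as.numeric(tr[i, pcols])
      lev_codes[[sample.int(length(lev_codes), 1, prob = p)]]
    }, numeric(1))

    painful <- rep(TRUE, n)
    if (design$nonpainful_frac > 0) {
      k <- round(design$nonpainful_frac * n)
      if (k > 0) painful[sample.int(n, k)] <- FALSE
    }
    level[!painful] <- 0

    conds <- tr[, design$factors, drop = FALSE]

    # perceived-control rating (first-stage mediator) and endogenous amplitude
    m1 <- NULL
    amp_manip <- numeric(n)
    for (f in design$factors) {
      if (f == "control" && design$has_control_rating) next
      amp_manip <- amp_manip + truth$manipulation_path * conds[[f]]
    }
    if (design$has_control_rating && "control" %in% design$factors) {
      m1 <- conds$control + stats::rnorm(n)
      amp_manip <- amp_manip + truth$manipulation_path * m1
    }
    amp_manip[!painful] <- 0
    subj_dev <- stats::rnorm(1, 0, truth$subject_sd)
    amp <- amp_manip + subj_dev + stats::rnorm(n, 0, truth$trial_sd)

    u <- truth$nociceptive_pattern$values
    v <- truth$endogenous_pattern$values
    X <- tcrossprod(truth$intensity_gain * level, u) +
         tcrossprod(truth$endogenous_gain * amp, v) +
         matrix(stats::rnorm(n * grid$n_vox, 0, truth$voxel_noise_sd), n)
    amp_sds <- truth$noise_amplitude_sds
    if (any(amp_sds > 0)) {
      A <- matrix(stats::rnorm(n * length(amp_sds)), n) %*% diag(amp_sds)
      X <- X + tcrossprod(A, truth$noise_patterns)
    }

    code_sum <- if (length(design$factors)) rowSums(conds) else numeric(n)
    rating <- lo + 2 * scale_mult +
      scale_mult * level +
      scale_mult * truth$mediator_path * truth$endogenous_gain * amp +
      scale_mult * truth$direct_path * code_sum * as.numeric(painful) +
      stats::rnorm(n, 0, scale_mult * truth$rating_noise_sd)
    rating[!painful] <- lo + abs(stats::rnorm(sum(!painful), 0, 0.2 * scale_mult))
    rating <- pmin(pmax(rating, lo), hi)

    mediation_flag <- switch(design$mediation_rule,
      medium_only = painful & level == lev_codes[["medium"]],
      painful
    )

    structure(list(
      subject_id = subject_id,
      X = X,
      ratings = rating,
      intensity = level,
      conditions = conds,
      perceived_control_rating = m1,
      painful_flag = painful,
      excluded_flag = rep(FALSE, n),
      excluded_reason = rep("", n),
      mediation_flag = mediation_flag,
      run = tr$run,
      trial = tr$trial,
      truth_amplitude = amp,
      rating_bounds = design$rating_bounds,
      design_label = design$label,
      grid = grid
    ), class = "trial_dataset")
  })
}

#' @export
print.trial_dataset <- function(x, ...) {
  cat(sprintf("<trial_dataset> %s: %d trials x %d voxels (%d painful, %d excluded)\n",
              x$subject_id, nrow(x$X), ncol(x$X), sum(x$painful_flag),
              sum(x$excluded_flag)))
  invisible(x)
}

# Trials entering signature development: painful and not QC-excluded.
included_trials <- function(dataset) {
  which(dataset$painful_flag & !dataset$excluded_flag)
}

#' Generate a synthetic BOLD run with known trial amplitudes
#'
#' Builds a time x voxels BOLD matrix in which each trial contributes its
#' per-voxel ground-truth beta times a boxcar convolved with the canonical
#' haemodynamic response, plus optional i.i.d. noise and optional injected
#' intensity spikes at recorded volumes. The per-trial, per-voxel betas are
#' returned so beta-series estimators can be checked against them exactly.
#'
#' By default the spatial betas follow the planted generative model (level
#' times nociceptive pattern plus amplitude times endogenous pattern); pass
#' `betas` to override with any trials x voxels matrix.
#'
#' @param design a `study_design` (supplies trial count and levels).
#' @param grid a `grid_spec`.
#' @param truth a `ground_truth`.
#' @param timing list with `n_scans`, `tr` (repetition time, s), `onsets`
#'   (s, one per trial), `durations` (s, scalar or per trial), optional
#'   `spike_volumes` (1-based volume indices) and `spike_size`.
#' @param seed integer seed.
#' @param noise_sd temporal noise s.d. (0 gives a noiseless run).
#' @param betas optional trials x voxels ground-truth beta override.
#' @return list with `bold` (n_scans x voxels), `events` (onset, duration,
#'   trial), `betas` (ground truth), `amplitudes` (planted endogenous
#'   amplitudes), `spike_volumes`, `tr`.
#' @export
generate_bold_run <- function(design, grid, truth, timing, seed = 1,
                              noise_sd = 0, betas = NULL) {
  stopifnot(!is.null(timing$n_scans), !is.null(timing$tr),
            !is.null(timing$onsets))
  onsets <- timing$onsets
  n_trials <- length(onsets)
  durations <- rep(timing$durations %||% 1, length.out = n_trials)
  run_len <- timing$n_scans * timing$tr
  if (any(onsets < 0) || any(onsets >= run_len)) stop("event onsets outside run")

  local_seed(seed, {
    amp <- NULL
    if (is.null(betas)) {
      lev_codes <- design$intensity_levels
      pcols <- paste0("p_", names(lev_codes))
      tr_rows <- design$trials[seq_len(n_trials), , drop = FALSE]
      level <- vapply(seq_len(n_trials), function(i) {
        p <- as.numeric(tr_rows[i, pcols])
        lev_codes[[sample.int(length(lev_codes), 1, prob = p)]]
      }, numeric(1))
      amp <- stats::rnorm(n_trials, 0, truth$trial_sd)
      betas <- tcrossprod(truth$intensity_gain * level,
                          truth$nociceptive_pattern$values) +
               tcrossprod(truth$endogenous_gain * amp,
                          truth$endogenous_pattern$values)
    } else {
      stopifnot(nrow(betas) == n_trials, ncol(betas) == grid$n_vox)
    }

    regs <- convolved_regressors(onsets, durations, timing$n_scans, timing$tr)
    bold <- regs %*% betas
    if (noise_sd > 0) {
      bold <- bold + matrix(stats::rnorm(length(bold), 0, noise_sd),
                            nrow(bold))
    }
    spike_volumes <- timing$spike_volumes %||% integer(0)
    if (length(spike_volumes)) {
      sz <- timing$spike_size %||% 50
      bold[spike_volumes, ] <- bold[spike_volumes, ] + sz
    }
    list(bold = bold,
         events = data.frame(onset = onsets, duration = durations,
                             trial = seq_len(n_trials)),
         betas = betas, amplitudes = amp,
         spike_volumes = spike_volumes, tr = timing$tr)
  })
}
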