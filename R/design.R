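#' Study design presets for synthetic trial generation
#'
#' Builds a `study_design`: the per-trial condition layout and the
#' probabilistic rule linking conditions to stimulus-intensity levels.
#' Three presets are provided.
#'
#' * `"study6"` — a 2x2 crossing of perceived control (HC/LC, block-wise by
#'   run) and expectancy cue (LE/HE) over 8 runs x 8 trials = 64 trials,
#'   16 per cell; within every cell low or high intensity is delivered with
#'   50% probability. Ratings on a 0-100 visual analogue scale; a per-trial
#'   perceived-control rating is generated.
#' * `"study5"` — an auditory-cue expectancy design: 6 test runs in which a
#'   low-pain cue is followed by low or medium intensity (50/50, trial types
#'   LL/LM) and a high-pain cue by medium or high (HM/HH). Only
#'   medium-intensity trials are flagged for mediation analysis. Ratings on
#'   a 0-10 scale.
#' * `"generic"` — configurable levels and a single balanced cue factor,
#'   sized so that roughly 50 painful trials per subject are generated by
#'   default (5 runs x 11 trials with a 10% non-painful fraction).
#'
#' Condition factors are coded +1 for anti-pain conditions (low-pain cue,
#' low expectancy, high control) and -1 for pro-pain conditions, matching
#' the coding used by the mediation models.
#'
#' @param preset one of `"study6"`, `"study5"`, `"generic"`.
#' @param n_runs,trials_per_run optional overrides of the preset layout.
#' @param intensity_levels optional named integer vector of level codes.
#' @param nonpainful_frac fraction of trials flagged non-painful (generic
#'   preset only by default).
#' @param rating_bounds length-2 numeric rating scale bounds.
#' @return A `study_design` with fields `label`, `n_runs`, `trials_per_run`,
#'   `n_trials`, `intensity_levels`, `factors`, `trials` (per-trial table:
#'   run, trial, one column per factor, and `p_<level>` probability
#'   columns), `rating_bounds`, `nonpainful_frac`, `mediation_rule`, and
#'   `has_control_rating`.
#' @examples
#' d <- make_study_design("study6")
#' d$n_trials                       # 64
#' table(d$trials$control, d$trials$expectancy)  # 16 per cell
#' @export
make_study_design <- function(preset = c("study6", "study5", "generic"),
                              n_runs = NULL, trials_per_run = NULL,
                              intensity_levels = NULL,
                              nonpainful_frac = NULL,
                              rating_bounds = NULL) {
  preset <- match.arg(preset)
  d <- switch(preset,
    study6 = design_study6(n_runs %||% 8L, trials_per_run %||% 8L),
    study5 = design_study5(n_runs %||% 6L, trials_per_run %||% 8L),
    generic = design_generic(n_runs %||% 5L, trials_per_run %||% 11L,
                             intensity_levels %||% c(L1 = 1L, L2 = 2L, L3 = 3L, L4 = 4L))
  )
  if (!is.null(nonpainful_frac)) d$nonpainful_frac <- nonpainful_frac
  if (!is.null(rating_bounds)) d$rating_bounds <- rating_bounds
  validate_design(d)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

new_design <- function(label, n_runs, trials_per_run, levels, factors, trials,
                       rating_bounds, nonpainful_frac = 0,
                       mediation_rule = "all", has_control_rating = FALSE) {
  structure(list(
    label = label, n_runs = as.integer(n_runs),
    trials_per_run = as.integer(trials_per_run),
    n_trials = nrow(trials),
    intensity_levels = levels, factors = factors, trials = trials,
    rating_bounds = rating_bounds, nonpainful_frac = nonpainful_frac,
    mediation_rule = mediation_rule, has_control_rating = has_control_rating
  ), class = "study_design")
}

validate_design <- function(d) {
  pcols <- paste0("p_", names(d$intensity_levels))
  if (!all(pcols %in% names(d$trials))) stop("missing intensity probability columns")
  rs <- rowSums(d$trials[, pcols, drop = FALSE])
  if (any(abs(rs - 1) > 1e-12)) {
    stop("intensity assignment probabilities must sum to 1 in every trial row")
  }
  for (f in d$factors) {
    if (!all(d$trials[[f]] %in% c(-1, 1))) stop("factor codes must be +/-1")
  }
  d
}

design_study6 <- function(n_runs, trials_per_run) {
  # Perceived control alternates by run (block manipulation); expectancy cues
  # are balanced within run. Low/high intensity is 50/50 in every cell.
  tr <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    control <- if (r %% 2 == 1) 1 else -1       # +1 = HC, -1 = LC
    expectancy <- rep(c(1, -1), length.out = trials_per_run)  # +1 = LE, -1 = HE
    data.frame(run = r, trial = seq_len(trials_per_run),
               control = control, expectancy = expectancy,
               p_low = 0.5, p_high = 0.5)
  }))
  new_design("study6", n_runs, trials_per_run,
             levels = c(low = 1L, high = 2L),
             factors = c("control", "expectancy"), trials = tr,
             rating_bounds = c(0, 100), mediation_rule = "all",
             has_control_rating = TRUE)
}

design_study5 <- function(n_runs, trials_per_run) {
  # +1 = low-pain cue (anti-pain), -1 = high-pain cue. Low cue -> low or
  # medium intensity (LL/LM), high cue -> medium or high (HM/HH), 50/50.
  tr <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    cue <- rep(c(1, -1), length.out = trials_per_run)
    data.frame(run = r, trial = seq_len(trials_per_run), cue = cue,
               p_low = ifelse(cue == 1, 0.5, 0),
               p_medium = 0.5,
               p_high = ifelse(cue == 1, 0, 0.5))
  }))
  new_design("study5", n_runs, trials_per_run,
             levels = c(low = 1L, medium = 2L, high = 3L),
             factors = "cue", trials = tr,
             rating_bounds = c(0, 10), mediation_rule = "medium_only")
}

design_generic <- function(n_runs, trials_per_run, levels) {
  p <- 1 / length(levels)
  tr <- do.call(rbind, lapply(seq_len(n_runs), function(r) {
    df <- data.frame(run = r, trial = seq_len(trials_per_run),
                     cue = rep(c(1, -1), length.out = trials_per_run))
    for (nm in names(levels)) df[[paste0("p_", nm)]] <- p
    df
  }))
  new_design("generic", n_runs, trials_per_run, levels = levels,
             factors = "cue", trials = tr, rating_bounds = c(0, 10),
             nonpainful_frac = 0.1)
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("<study_design> '%s': %d runs x %d trials = %d; levels: %s; factors: %s\n",
              x$label, x$n_runs, x$trials_per_run, x$n_trials,
              paste(names(x$intensity_levels), collapse = "/"),
              if (length(x$factors)) paste(x$factors, collapse = ", ") else "none"))
  invisible(x)
}
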