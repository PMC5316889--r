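#' Planted ground truth for synthetic datasets
#'
#' Builds the pair of spatial patterns and the effect sizes that the
#' synthetic generator plants in every trial image:
#'
#' * a *nociceptive* pattern — nonnegative weights on a random support,
#'   whose expression scales with stimulus-intensity level (the stand-in for
#'   an intensity-tracking signature);
#' * an *endogenous* pattern — piecewise-constant weights over a small set
#'   of compact spherical subregions with mixed signs (pro-pain positive,
#'   anti-pain negative), whose per-trial amplitude carries the
#'   intensity-independent contribution to pain and mediates condition
#'   effects.
#'
#' Both patterns have unit Euclidean norm; effect sizes below scale them.
#' The spatial overlap between the two supports is configurable and the
#' achieved value is recorded.
#'
#' Default effect sizes define the reference simulation conditions used
#' throughout the package's validation: per-trial endogenous pattern energy
#' about six times the per-voxel noise level, condition-to-amplitude path
#' 0.1, amplitude-to-rating path 0.15 per rating point (0-10 convention),
#' direct condition-to-rating path 0.05, unit trial-level amplitude noise,
#' between-subject amplitude s.d. 0.3, unit voxel and rating noise. These
#' are calibrated once so the planted structure is recoverable at the
#' reference scale (20 subjects x 50 painful trials on a 12^3 grid) while
#' condition effects on pain stay small, as in the designs they emulate.
#'
#' @param grid a [make_grid()] `grid_spec`.
#' @param n_pro,n_anti numbers of pro-pain (positive) and anti-pain
#'   (negative) subregions.
#' @param region_radius subregion sphere radius in voxels.
#' @param noci_support fraction of in-mask voxels in the nociceptive support.
#' @param overlap target fraction of endogenous-support voxels shared with
#'   the nociceptive support.
#' @param intensity_gain brain response per intensity-level step along the
#'   nociceptive pattern.
#' @param endogenous_gain brain response per unit endogenous amplitude along
#'   the endogenous pattern.
#' @param manipulation_path condition-code effect on endogenous amplitude
#'   (path a of the planted mediation).
#' @param mediator_path endogenous brain response effect on the rating (path
#'   b), per rating point on a 0-10 scale.
#' @param direct_path condition-code effect on the rating bypassing the
#'   brain (path c-prime), same units.
#' @param subject_sd,trial_sd between-subject and within-subject s.d. of
#'   endogenous amplitude.
#' @param voxel_noise_sd i.i.d. Gaussian noise s.d. per voxel and trial.
#' @param global_noise_sd amplitude s.d. of the global-signal and random
#'   structured noise components: besides i.i.d. voxel noise, each trial
#'   adds fixed unit-norm spatial patterns with independent Gaussian
#'   amplitudes — the global signal (uniform over the mask), a salience-like
#'   co-activation mode (below), and a random pattern — emulating
#'   global/physiological fluctuations.
#' @param salience_noise_sd amplitude s.d. of the salience-like component: a
#'   high-variance mode loading positively on the pain-predictive
#'   subregions with spatial correlation `salience_overlap` to the
#'   endogenous pattern. Rating-independent co-activation of
#'   pain-predictive regions is what makes a mass-univariate encoding map a
#'   contaminated decoder, while a multivariate pattern with mixed-sign
#'   weights can cancel the mode; it is the generator's analogue of arousal
#'   and attention fluctuations in the salience network.
#' @param salience_overlap cosine between the salience mode and the
#'   endogenous pattern.
#' @param rating_noise_sd rating noise s.d. (0-10 convention; rescaled to
#'   the design's rating bounds).
#' @param seed integer seed controlling the pattern geometry.
#' @return A `ground_truth` list with `weight_map`s `nociceptive_pattern`
#'   and `endogenous_pattern`, the `subregions` list (name, voxel indices,
#'   sign), all effect sizes, and `achieved_overlap`.
#' @export
make_ground_truth <- function(grid, n_pro = 4, n_anti = 2, region_radius = 2,
                              noci_support = 0.3, overlap = 0.25,
                              intensity_gain = 1, endogenous_gain = 6,
                              manipulation_path = 0.1, mediator_path = 0.15,
                              direct_path = 0.05,
                              subject_sd = 0.3, trial_sd = 1,
                              voxel_noise_sd = 1, rating_noise_sd = 1,
                              global_noise_sd = 3, salience_noise_sd = 20,
                              salience_overlap = 0.25, seed = 1) {
  if (!inherits(grid, "grid_spec")) stop("`grid` must be a grid_spec")
  out <- local_seed(seed, {
    sub <- place_subregions(grid, n_pro + n_anti, region_radius)
    signs <- c(rep(1, n_pro), rep(-1, n_anti))
    endo <- numeric(grid$n_vox)
    subregions <- vector("list", length(sub))
    for (i in seq_along(sub)) {
      endo[sub[[i]]] <- signs[i]
      subregions[[i]] <- list(
        name = sprintf("%s_%02d", if (signs[i] > 0) "pro" else "anti", i),
        voxels = sub[[i]], sign = signs[i]
      )
    }
    endo <- endo / sqrt(sum(endo^2))
    endo_support <- which(endo != 0)

    # Nociceptive support: include `overlap` of the endogenous support, fill
    # the rest from outside it.
    k <- max(1L, round(noci_support * grid$n_vox))
    k_in <- min(length(endo_support), round(overlap * length(endo_support)))
    pool <- setdiff(seq_len(grid$n_vox), endo_support)
    support <- c(sample(endo_support, k_in),
                 sample(pool, min(length(pool), k - k_in)))
    noci <- numeric(grid$n_vox)
    noci[support] <- abs(stats::rnorm(length(support)))
    noci <- noci / sqrt(sum(noci^2))
    # structured noise basis: global signal, salience co-activation with the
    # prescribed overlap to the endogenous pattern, and one random mode
    nv <- grid$n_vox
    u_glob <- rep(1 / sqrt(nv), nv)
    aend <- abs(endo)
    aend <- aend / sqrt(sum(aend^2))
    r <- stats::rnorm(nv)
    r <- r - sum(r * aend) * aend - sum(r * endo) * endo
    r <- r / sqrt(sum(r^2))
    a <- min(1, salience_overlap / sum(aend * endo))
    u_sal <- a * aend + sqrt(max(0, 1 - a^2)) * r
    u_sal <- u_sal / sqrt(sum(u_sal^2))
    u_rand <- stats::rnorm(nv)
    u_rand <- u_rand / sqrt(sum(u_rand^2))
    list(noci = noci, endo = endo, subregions = subregions,
         noise_patterns = cbind(global = u_glob, salience = u_sal,
                                random = u_rand),
         achieved_overlap = k_in / length(endo_support))
  })
  structure(list(
    grid = grid,
    nociceptive_pattern = weight_map(out$noci, grid, "nociceptive"),
    endogenous_pattern = weight_map(out$endo, grid, "endogenous"),
    subregions = out$subregions,
    noise_patterns = out$noise_patterns,
    achieved_overlap = out$achieved_overlap,
    intensity_gain = intensity_gain, endogenous_gain = endogenous_gain,
    manipulation_path = manipulation_path, mediator_path = mediator_path,
    direct_path = direct_path,
    subject_sd = subject_sd, trial_sd = trial_sd,
    voxel_noise_sd = voxel_noise_sd, rating_noise_sd = rating_noise_sd,
    global_noise_sd = global_noise_sd,
    salience_noise_sd = salience_noise_sd,
    salience_overlap = salience_overlap,
    noise_amplitude_sds = c(global_noise_sd, salience_noise_sd,
                            global_noise_sd),
    seed = seed
  ), class = "ground_truth")
}

# Greedy farthest-point placement of subregion centres over in-mask voxels:
# a random first centre, then each next centre maximizes the minimum
# distance to those already chosen. Centres must end up pairwise further
# apart than 2*radius so the voxelized spheres are disjoint; spheres are
# clipped by the mask at its edge.
place_subregions <- function(grid, n, radius, restarts = 50) {
  coords <- arrayInd(grid$vox_idx, grid$shape)
  centres <- NULL
  for (try in seq_len(restarts)) {
    chosen <- sample.int(nrow(coords), 1)
    mind <- sqrt(rowSums(sweep(coords, 2, coords[chosen, ])^2))
    ok <- TRUE
    while (length(chosen) < n) {
      nxt <- which.max(mind)
      if (mind[nxt] <= 2 * radius) {
        ok <- FALSE
        break
      }
      chosen <- c(chosen, nxt)
      mind <- pmin(mind, sqrt(rowSums(sweep(coords, 2, coords[nxt, ])^2)))
    }
    if (ok) {
      centres <- coords[chosen, , drop = FALSE]
      break
    }
  }
  if (is.null(centres)) {
    stop("could not place subregions; enlarge the grid or shrink them")
  }
  lin_of <- array(0L, grid$shape)
  lin_of[grid$vox_idx] <- seq_len(grid$n_vox)
  lapply(seq_len(n), function(i) {
    ctr <- centres[i, ]
    rng <- lapply(1:3, function(d) seq(max(1, ctr[d] - radius), min(grid$shape[d], ctr[d] + radius)))
    box <- as.matrix(expand.grid(rng[[1]], rng[[2]], rng[[3]]))
    d <- sqrt(rowSums((box - matrix(ctr, nrow(box), 3, byrow = TRUE))^2))
    box <- box[d <= radius, , drop = FALSE]
    lin <- lin_of[box]
    sort(lin[lin > 0L])
  })
}
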