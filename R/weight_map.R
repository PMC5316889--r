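#' Voxel weight map on a grid
#'
#' Thin container pairing a numeric weight vector (one value per in-mask
#' voxel, in the grid's linearization order) with its `grid_spec`. Used for
#' reference nociceptive signatures, per-subject decoder maps, and group
#' signatures alike.
#'
#' @param values numeric vector of length `grid$n_vox`.
#' @param grid a [make_grid()] `grid_spec`.
#' @param label optional character tag.
#' @return A `weight_map`.
#' @export
weight_map <- function(values, grid, label = "") {
  values <- as.numeric(values)
  if (length(values) != grid$n_vox) {
    stop("`values` length must equal the number of in-mask voxels")
  }
  structure(list(values = values, grid = grid, label = label),
            class = "weight_map")
}

#' @export
print.weight_map <- function(x, ...) {
  cat(sprintf("<weight_map>%s %d voxels, norm %.4g\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              length(x$values), sqrt(sum(x$values^2))))
  invisible(x)
}

#' Generate a random reference signature
#'
#' Draws a reference weight map standing in for a previously published
#' nociceptive signature (an NPS-like map): independent Gaussian weights on
#' a random subset of in-mask voxels, zero elsewhere, scaled to unit
#' Euclidean norm. Used as the covariate signature in residualization.
#'
#' @param grid a `grid_spec`.
#' @param support_fraction fraction of in-mask voxels with nonzero weight,
#'   in (0, 1].
#' @param seed integer seed; the map is a deterministic function of
#'   (grid, support_fraction, seed).
#' @return A unit-norm [weight_map()].
#' @export
generate_reference_signature <- function(grid, support_fraction = 1, seed = 1) {
  if (!inherits(grid, "grid_spec")) stop("`grid` must be a grid_spec")
  if (support_fraction <= 0 || support_fraction > 1) {
    stop("`support_fraction` must be in (0, 1]")
  }
  n <- grid$n_vox
  k <- max(1L, round(support_fraction * n))
  w <- local_seed(seed, {
    support <- sample.int(n, k)
    v <- numeric(n)
    v[support] <- stats::rnorm(k)
    v
  })
  weight_map(w / sqrt(sum(w^2)), grid, label = "reference")
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG afterwards so library code never clobbers user seeds.
local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
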