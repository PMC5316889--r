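#' Voxel grid specification
#'
#' A `grid_spec` fixes the 3-D array shape, the analysis mask, and the
#' linearization of in-mask voxels that every map and trial matrix in a
#' pipeline shares. The linearization is the column-major order of `TRUE`
#' mask entries and is therefore deterministic: two maps built on the same
#' `grid_spec` are voxel-wise comparable by construction.
#'
#' @param shape integer 3-vector of voxel counts per dimension.
#' @param mask_rule one of `"ellipsoid"` (voxels inside the ellipsoid with
#'   the given semi-axes, centred in the volume), `"full"` (every voxel), or
#'   `"custom"` (caller-supplied logical volume in `mask`).
#' @param semi_axes numeric 3-vector of ellipsoid semi-axes in voxel units;
#'   defaults to `shape / 2 - 1`.
#' @param mask logical array of dimension `shape`, used when
#'   `mask_rule = "custom"`.
#' @param seed unused for the deterministic rules; accepted so generator
#'   configurations can carry one seed through uniformly.
#' @return A `grid_spec` with fields `shape`, `mask` (logical array),
#'   `n_vox`, and `vox_idx` (linear indices of in-mask voxels, column-major).
#' @examples
#' g <- make_grid(c(12, 12, 12), "ellipsoid", semi_axes = c(5, 5, 5))
#' g$n_vox
#' @export
make_grid <- function(shape, mask_rule = c("ellipsoid", "full", "custom"),
                      semi_axes = NULL, mask = NULL, seed = NULL) {
  mask_rule <- match.arg(mask_rule)
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("`shape` must be a positive 3-vector")
  }
  m <- switch(mask_rule,
    full = array(TRUE, dim = shape),
    ellipsoid = {
      if (is.null(semi_axes)) semi_axes <- shape / 2 - 1
      ctr <- (shape + 1) / 2
      co <- as.matrix(expand.grid(
        i = seq_len(shape[1]), j = seq_len(shape[2]), k = seq_len(shape[3])
      ))
      d2 <- ((co[, 1] - ctr[1]) / semi_axes[1])^2 +
            ((co[, 2] - ctr[2]) / semi_axes[2])^2 +
            ((co[, 3] - ctr[3]) / semi_axes[3])^2
      array(d2 <= 1, dim = shape)
    },
    custom = {
      if (is.null(mask)) stop("mask_rule = 'custom' requires `mask`")
      if (!identical(dim(mask), shape)) stop("`mask` dimensions must equal `shape`")
      array(as.logical(mask), dim = shape)
    }
  )
  if (!any(m)) stop("mask is empty: no in-mask voxels")
  structure(
    list(shape = shape, mask = m, n_vox = sum(m), vox_idx = which(m)),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %s, %d in-mask voxels\n",
              paste(x$shape, collapse = "x"), x$n_vox))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) && identical(which(a$mask), which(b$mask))
}

stop_if_grid_mismatch <- function(a, b, what = "object") {
  if (!same_grid(a, b)) {
    stop(sprintf("grid mismatch: %s is not on the expected grid (no implicit resampling)",
                 what))
  }
  invisible(TRUE)
}

#' Convert between in-mask vectors and 3-D volumes
#'
#' `vec_to_vol()` scatters an `n_vox`-vector into a full 3-D array
#' (out-of-mask voxels get `fill`); `vol_to_vec()` extracts the in-mask
#' values in the grid's fixed linearization order.
#'
#' @param v numeric vector of length `grid$n_vox`.
#' @param grid a [make_grid()] `grid_spec`.
#' @param fill value for out-of-mask voxels.
#' @return An array of dimension `grid$shape`, or a numeric vector.
#' @export
vec_to_vol <- function(v, grid, fill = 0) {
  stopifnot(length(v) == grid$n_vox)
  out <- array(fill, dim = grid$shape)
  out[grid$vox_idx] <- v
  out
}

#' @rdname vec_to_vol
#' @param vol numeric array of dimension `grid$shape`.
#' @export
vol_to_vec <- function(vol, grid) {
  stopifnot(identical(dim(vol), grid$shape))
  as.numeric(vol[grid$vox_idx])
}
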