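# Structuring elements, per-plane Gaussian smoothing, and thin wrappers
# around the compiled morphology kernels.  All masks are logical 3D arrays
# in (z, y, x) order; out-of-bounds voxels count as background.

gaussian_kernel_1d <- function(sigma_px) {
  if (sigma_px <= 0) return(1.0)
  r <- max(1L, as.integer(ceiling(3 * sigma_px)))
  x <- (-r):r
  k <- exp(-x^2 / (2 * sigma_px^2))
  k / sum(k)
}

# 2D disk structuring element of pixel radius r, as (dz, dy, dx) offsets
disk_offsets_2d <- function(r) {
  g <- expand.grid(dy = -r:r, dx = -r:r)
  g <- g[g$dy^2 + g$dx^2 <= r^2, ]
  cbind(dz = 0L, dy = as.integer(g$dy), dx = as.integer(g$dx))
}

# 3D 6-connected cross (center + face neighbours)
cross_offsets_3d <- function() {
  rbind(c(0L, 0L, 0L),
        c(-1L, 0L, 0L), c(1L, 0L, 0L),
        c(0L, -1L, 0L), c(0L, 1L, 0L),
        c(0L, 0L, -1L), c(0L, 0L, 1L))
}

as_dim3 <- function(x) {
  x <- unclass(x)
  attributes(x) <- list(dim = dim(x))
  x
}

binary_dilate <- function(mask, offsets) {
  out <- cpp_binary_morph(as_dim3(mask), offsets, TRUE)
  attributes(out) <- attributes(mask)
  out
}

binary_erode <- function(mask, offsets) {
  out <- cpp_binary_morph(as_dim3(mask), offsets, FALSE)
  attributes(out) <- attributes(mask)
  out
}

fill_holes_by_plane <- function(mask) {
  out <- cpp_fill_holes_2d(as_dim3(mask))
  attributes(out) <- attributes(mask)
  out
}

label_components <- function(mask, connectivity = 26L) {
  cpp_label3d(as_dim3(mask), as.integer(connectivity))
}

#' Smooth every z-plane with an isotropic 2D Gaussian
#'
#' The physical sigma (micrometres) is converted to pixel units per axis via
#' the voxel spacing, so smoothing is isotropic in physical space even for
#' rectangular pixels. `sigma_um = 0` is the identity.
#'
#' @param grid a [voxel_grid()].
#' @param sigma_um Gaussian standard deviation in micrometres.
#' @return A [voxel_grid()] of the same shape and spacing.
#' @export
smooth_planes <- function(grid, sigma_um) {
  if (sigma_um < 0) stop("sigma_um must be >= 0")
  if (sigma_um == 0) return(grid)
  sp <- voxel_spacing(grid)
  ky <- gaussian_kernel_1d(sigma_um / sp[2])
  kx <- gaussian_kernel_1d(sigma_um / sp[3])
  out <- cpp_conv_planes(as_dim3(grid), ky, kx)
  voxel_grid(out, sp)
}
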