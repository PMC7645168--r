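#' Voxel grid geometry
#'
#' A `voxel_grid` describes the sampling lattice every volume in a
#' reconstruction shares: the array dimensions, the physical voxel size in mm
#' (anisotropic voxels are handled by per-axis frequency scaling, never by
#' resampling), and the unit vector of the main field B0 in image coordinates.
#'
#' @param shape integer vector of length 3, array dimensions (each >= 8).
#' @param voxel_size numeric vector of length 3, voxel edge lengths in mm.
#' @param b0_direction unit 3-vector giving the B0 direction; default (0,0,1).
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(shape, voxel_size = c(1, 1, 1),
                       b0_direction = c(0, 0, 1)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 8L))
    stop("invalid grid: 'shape' must be 3 integers, each >= 8")
  voxel_size <- as.numeric(voxel_size)
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("'voxel_size' must be 3 positive lengths (mm)")
  b0_direction <- as.numeric(b0_direction)
  nb <- sqrt(sum(b0_direction^2))
  if (length(b0_direction) != 3L || abs(nb - 1) > 1e-9)
    stop("'b0_direction' must be a unit 3-vector")
  structure(list(shape = shape, voxel_size = voxel_size,
                 b0_direction = b0_direction),
            class = "voxel_grid")
}

#' @export
print.voxel_grid <- function(x, ...) {
  cat(sprintf("voxel grid %dx%dx%d, voxel %.3gx%.3gx%.3g mm, B0 = (%.3g, %.3g, %.3g)\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$voxel_size[1], x$voxel_size[2], x$voxel_size[3],
              x$b0_direction[1], x$b0_direction[2], x$b0_direction[3]))
  invisible(x)
}

same_grid <- function(a, b) {
  identical(a$shape, b$shape) &&
    isTRUE(all.equal(a$voxel_size, b$voxel_size))
}

check_volume <- function(values, grid, what = "volume") {
  if (!identical(dim(values), NULL) && !identical(as.integer(dim(values)), grid$shape))
    stop(sprintf("%s shape does not match grid", what))
  invisible(values)
}

# gyromagnetic ratio of 1H, rad / s / T
GAMMA_H <- 2.675e8

## ---- FFT helpers -----------------------------------------------------------

fftn <- function(x) stats::fft(x)

ifftn <- function(x) stats::fft(x, inverse = TRUE) / length(x)

# DFT sample frequencies (cycles / mm) along one axis
fft_freq <- function(n, d = 1) {
  k <- c(seq.int(0L, floor((n - 1) / 2)), seq.int(-ceiling((n - 1) / 2), -1L))
  k / (n * d)
}

# 3D arrays of k-components, recycled from per-axis frequency vectors
k_component <- function(grid, axis) {
  sh <- grid$shape
  f <- fft_freq(sh[axis], grid$voxel_size[axis])
  switch(axis,
         array(rep(f, times = sh[2] * sh[3]), dim = sh),
         array(rep(rep(f, each = sh[1]), times = sh[3]), dim = sh),
         array(rep(f, each = sh[1] * sh[2]), dim = sh))
}

## ---- dipole kernel ---------------------------------------------------------

#' k-space dipole kernel
#'
#' The Fourier-domain response of a unit magnetic dipole,
#' `D(k) = 1/3 - (k . b)^2 / |k|^2` with `b` the B0 unit vector.  `D` vanishes
#' on the magic-angle cone, which is what makes single-orientation dipole
#' inversion ill-posed.  The undefined DC value is set to 0, the usual QSM
#' convention: each reconstruction is mean-free and must be re-referenced
#' (e.g. to CSF) before comparing absolute values.
#'
#' @param grid a [voxel_grid].
#' @return Object of class `dipole_kernel`: list with `values` (real 3D array,
#'   DC at `[1,1,1]` following the unshifted FFT layout) and `grid`.
#' @export
make_dipole_kernel <- function(grid) {
  if (!inherits(grid, "voxel_grid")) grid <- do.call(voxel_grid, grid)
  b <- grid$b0_direction
  kx <- k_component(grid, 1L); ky <- k_component(grid, 2L); kz <- k_component(grid, 3L)
  k2 <- kx^2 + ky^2 + kz^2
  kb <- kx * b[1] + ky * b[2] + kz * b[3]
  d <- 1 / 3 - kb^2 / k2
  d[1, 1, 1] <- 0   # k = 0: 0/0 above; DC convention
  # enforce D(k) = D(-k) on the discrete lattice: for oblique b0 the
  # (k.b)^2 cross terms break evenness on the Nyquist planes of even-sized
  # grids, which would make the real-to-real convolution leak imaginary
  # parts; averaging with the index-reversed kernel restores symmetry
  sh <- grid$shape
  rev_idx <- lapply(sh, function(n) c(1L, seq.int(n, 2L)))
  d <- (d + d[rev_idx[[1]], rev_idx[[2]], rev_idx[[3]]]) / 2
  structure(list(values = d, grid = grid), class = "dipole_kernel")
}

#' Forward dipole field of a susceptibility distribution
#'
#' Computes the B0-relative field shift `dB = F^-1{ D(k) F{chi} }` (in ppm)
#' generated by a susceptibility volume (in ppb).  Linear in `chi`; a
#' spatially constant `chi` produces zero field because of the DC convention.
#'
#' @param chi real 3D array of susceptibility in ppb.
#' @param kernel a `dipole_kernel` on the same grid.
#' @return Real 3D array: field shift in ppm.
#' @export
forward_field <- function(chi, kernel) {
  check_volume(chi, kernel$grid, "chi")
  Re(ifftn(kernel$values * fftn(chi))) / 1000
}

#' Convert a field map to GRE phase and back
#'
#' `phi = gamma * B0 * TE * dB` with `dB` in ppm (the 1e-6 scale factor is
#' applied internally) and gamma = 2.675e8 rad/s/T.
#'
#' @param field real 3D array, field shift in ppm.
#' @param te_s echo time in seconds.
#' @param b0_T main field strength in tesla.
#' @return Phase volume in radians (unwrapped).
#' @export
field_to_phase <- function(field, te_s, b0_T) {
  stopifnot(te_s > 0, b0_T > 0)
  GAMMA_H * b0_T * te_s * field * 1e-6
}

#' @rdname field_to_phase
#' @param phase phase volume in radians.
#' @export
phase_to_field <- function(phase, te_s, b0_T) {
  stopifnot(te_s > 0, b0_T > 0)
  phase / (GAMMA_H * b0_T * te_s) * 1e6
}

## ---- finite differences ----------------------------------------------------

#' Forward-difference gradient and its negative adjoint
#'
#' `gradient_op` applies forward differences along one axis, scaled by
#' 1/voxel_size (units 1/mm), with replicate boundary handling (the gradient
#' on the last slice is 0).  `divergence_op` is minus its adjoint, so that
#' `sum(gradient_op(x) * y) == sum(x * -divergence_op(y))` exactly.
#'
#' @param volume real 3D array.
#' @param axis 1, 2 or 3.
#' @param voxel_size per-axis voxel lengths in mm (only `voxel_size[axis]`
#'   is used).
#' @return Real 3D array of the same shape.
#' @export
gradient_op <- function(volume, axis, voxel_size = c(1, 1, 1)) {
  n <- dim(volume)[axis]
  d <- array(0, dim(volume))
  if (axis == 1L) {
    d[-n, , ] <- volume[-1, , ] - volume[-n, , ]
  } else if (axis == 2L) {
    d[, -n, ] <- volume[, -1, ] - volume[, -n, ]
  } else {
    d[, , -n] <- volume[, , -1] - volume[, , -n]
  }
  d / voxel_size[axis]
}

#' @rdname gradient_op
#' @export
divergence_op <- function(volume, axis, voxel_size = c(1, 1, 1)) {
  # div = -G^T: backward difference with the boundary rows that make
  # <G x, y> = <x, -div y> hold exactly
  n <- dim(volume)[axis]
  d <- array(0, dim(volume))
  if (axis == 1L) {
    d[1, , ] <- volume[1, , ]
    d[2:(n - 1), , ] <- volume[2:(n - 1), , ] - volume[1:(n - 2), , ]
    d[n, , ] <- -volume[n - 1, , ]
  } else if (axis == 2L) {
    d[, 1, ] <- volume[, 1, ]
    d[, 2:(n - 1), ] <- volume[, 2:(n - 1), ] - volume[, 1:(n - 2), ]
    d[, n, ] <- -volume[, n - 1, ]
  } else {
    d[, , 1] <- volume[, , 1]
    d[, , 2:(n - 1)] <- volume[, , 2:(n - 1)] - volume[, , 1:(n - 2)]
    d[, , n] <- -volume[, , n - 1]
  }
  d / voxel_size[axis]
}
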