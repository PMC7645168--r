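## Phase preprocessing: unwrapping, SHARP background removal, fidelity weight.

# even (mirror) extension along every axis; makes FFT-periodic operators
# behave like Neumann-boundary ones
mirror_pad <- function(x) {
  n <- dim(x)
  x <- x[c(seq_len(n[1]), rev(seq_len(n[1]))), , ]
  x <- x[, c(seq_len(n[2]), rev(seq_len(n[2]))), ]
  x[, , c(seq_len(n[3]), rev(seq_len(n[3])))]
}

mirror_crop <- function(x, n) x[seq_len(n[1]), seq_len(n[2]), seq_len(n[3])]

# -(2 pi |k|)^2 multiplier of the FFT-domain Laplacian on the padded grid
laplace_multiplier <- function(shape, voxel_size) {
  f2 <- lapply(1:3, function(a) (2 * pi * fft_freq(shape[a], voxel_size[a]))^2)
  sh <- shape
  array(rep(f2[[1]], times = sh[2] * sh[3]), sh) +
    array(rep(rep(f2[[2]], each = sh[1]), times = sh[3]), sh) +
    array(rep(f2[[3]], each = sh[1] * sh[2]), sh)
}

#' Laplacian phase unwrapping
#'
#' Recovers unwrapped phase from wrapped phase by solving a Poisson equation:
#' the true phase Laplacian is estimated from the wrapped phase as
#' `cos(phi) L[sin(phi)] - sin(phi) L[cos(phi)]` and inverted spectrally
#' (mirror-padded FFT, i.e. Neumann boundaries).  Optionally the smooth
#' solution is made congruent with the input: the returned phase differs from
#' the wrapped input by exact multiples of 2*pi voxelwise.
#'
#' The method is deterministic and exact for smooth fields; like all Laplacian
#' unwrappers it can absorb a harmonic component of the true phase.
#' Pre-unwrapped phase can bypass this step entirely in the pipeline.
#'
#' @param phase wrapped phase volume in radians, values in (-pi, pi].
#' @param voxel_size per-axis voxel size in mm.
#' @param mask optional logical volume restricting the congruence region; an
#'   all-`FALSE` mask is an error.
#' @param congruent if `TRUE` (default), snap the smooth solution back onto
#'   the wrapped input modulo 2*pi.
#' @return Unwrapped phase volume (radians).
#' @export
unwrap_phase <- function(phase, voxel_size = c(1, 1, 1), mask = NULL,
                         congruent = TRUE) {
  if (!is.null(mask) && !any(mask)) stop("empty mask")
  n <- dim(phase)
  pw <- mirror_pad(phase)
  L <- laplace_multiplier(dim(pw), voxel_size)
  lap <- function(x) Re(ifftn(-L * fftn(x)))
  s <- sin(pw); cph <- cos(pw)
  rhs <- cph * lap(s) - s * lap(cph)
  Linv <- ifelse(L > 0, -1 / L, 0)
  sol <- Re(ifftn(Linv * fftn(rhs)))
  sol <- mirror_crop(sol, n)
  # the spectral solve loses the DC term; recover the global offset as the
  # circular mean of the residual so the congruence rounding is centered
  # (otherwise an offset near an odd multiple of pi puts every voxel on the
  # rounding knife edge)
  sel <- if (is.null(mask)) TRUE else mask
  sol <- sol + Arg(mean(exp(1i * (phase - sol))[sel]))
  if (congruent)
    sol <- phase + 2 * pi * round((sol - phase) / (2 * pi))
  sol
}

# spherical structuring element (voxel-index units), centered for FFT use
smv_kernel <- function(shape, radius_vox) {
  off <- lapply(shape, function(n) {
    i <- seq_len(n) - 1L
    pmin(i, n - i)                      # circular distance to index 0
  })
  q <- array(rep(off[[1]]^2, times = shape[2] * shape[3]), shape) +
    array(rep(rep(off[[2]]^2, each = shape[1]), times = shape[3]), shape) +
    array(rep(off[[3]]^2, each = shape[1] * shape[2]), shape)
  k <- (q <= radius_vox^2) * 1
  k / sum(k)
}

erode_mask <- function(mask, shape, radius_vox, kernel_fft) {
  m <- Re(ifftn(fftn(mask * 1) * kernel_fft))
  m > 1 - 1e-6
}

#' SHARP background-field removal
#'
#' Sophisticated Harmonic Artifact Reduction for Phase data: harmonic
#' (background) field components are annihilated by the spherical-mean-value
#' property -- convolving with `delta - sphere` kills any field harmonic over
#' the sphere's support -- and the remaining local field is recovered by a
#' truncated (thresholded) deconvolution.  Output is defined on the brain
#' mask eroded by the kernel radius.
#'
#' @param field total field volume (any linear unit, typically ppm).
#' @param mask logical brain mask.
#' @param radius_vox spherical kernel radius in voxels (default 6).
#' @param tsvd_threshold truncation threshold on the deconvolution filter
#'   (default 0.05).
#' @return List with `local` (background-free field, zero outside the eroded
#'   mask) and `mask` (the eroded mask).
#' @export
sharp_remove_background <- function(field, mask, radius_vox = 6,
                                    tsvd_threshold = 0.05) {
  stopifnot(radius_vox >= 1, tsvd_threshold > 0, tsvd_threshold < 0.5)
  if (!any(mask)) stop("empty mask")
  shape <- dim(field)
  if (any(2 * radius_vox + 1 > shape)) stop("SHARP kernel larger than grid")
  S <- fftn(smv_kernel(shape, radius_vox))
  C <- 1 - S                              # delta - sphere
  eroded <- erode_mask(mask, shape, radius_vox, S)
  if (!any(eroded)) stop("SHARP kernel too large: eroded mask is empty")
  tmp <- Re(ifftn(C * fftn(field * mask))) * eroded
  Cinv <- ifelse(Mod(C) > tsvd_threshold, 1 / C, 0)
  local <- Re(ifftn(Cinv * fftn(tmp))) * eroded
  list(local = local, mask = eroded)
}

#' Model-guided re-unwrapping
#'
#' Given a predicted (model) phase, the measured wrapped phase is re-unwrapped
#' as `model + wrap(measured - model)`: exact wherever the prediction is
#' within pi of the true phase, regardless of how steep the true phase is.
#' This recovers the rapidly varying dipole phase around strong focal sources
#' (microbleeds, calcifications) that spatial unwrapping must give up on.
#' The returned quality flag marks voxels whose wrapped residual approaches
#' pi, where the +-2*pi assignment is ambiguous.
#'
#' @param wrapped measured wrapped phase (radians).
#' @param model predicted unwrapped phase (radians), e.g. the forward phase
#'   of a first-pass reconstruction.
#' @param max_residual residual magnitude (radians) beyond which a voxel is
#'   flagged unreliable (default 0.8 * pi).
#' @return List with `phase` (re-unwrapped) and `quality` (logical volume).
#' @export
refine_unwrap <- function(wrapped, model, max_residual = 0.8 * pi) {
  resid <- wrap_phase(wrapped - model)
  list(phase = model + resid, quality = abs(resid) < max_residual)
}

#' Phase-quality mask
#'
#' Voxels where the unwrapped phase changes by more than `max_step` radians
#' per voxel along any axis are spatially aliased (e.g. the steep dipole
#' field just outside a strong microbleed or calcification, or pure-noise
#' phase where the magnitude has decayed away): their field value cannot be
#' trusted and they are excluded from the data-fidelity weight.  The
#' shorter-echo reconstructions repopulate these voxels through the
#' R2*-weighted fusion.
#'
#' @param phase_unwrapped unwrapped phase volume (radians).
#' @param max_step aliasing threshold in radians per voxel (default pi).
#' @return Logical volume, `TRUE` where the phase is reliable.
#' @export
phase_quality_mask <- function(phase_unwrapped, max_step = pi) {
  ok <- array(TRUE, dim(phase_unwrapped))
  for (a in 1:3)
    ok <- ok & abs(gradient_op(phase_unwrapped, a)) < max_step
  ok
}

#' Data-fidelity weight from the magnitude image
#'
#' The fidelity term of the constrained inversion is weighted by the image
#' magnitude (voxels with more signal carry more reliable phase).  W is the
#' magnitude normalized to unit mean over the mask and zero outside it.
#'
#' @param magnitude magnitude volume (>= 0).
#' @param mask logical brain mask.
#' @return Weight volume W, mean 1 over the mask.
#' @export
build_fidelity_weight <- function(magnitude, mask) {
  if (any(magnitude < 0)) stop("magnitude must be non-negative")
  m <- mean(magnitude[mask])
  if (!is.finite(m) || m <= 0) stop("magnitude is zero over the mask")
  w <- magnitude / m
  w[!mask] <- 0
  w
}
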