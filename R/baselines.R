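## Baseline dipole inversions: TKD, iSWIM, COSMOS.

#' Thresholded k-space division (TKD)
#'
#' Direct dipole inversion `chi_k = dB_k / D(k)` with the kernel clipped near
#' its zero cone: where `|D| < threshold` the division uses
#' `threshold * sign(D)` (with `sign(0) := +1`) instead of `D`.  Fast and
#' unbiased in the well-conditioned region, but it underestimates
#' susceptibility and streaks around the cone.
#'
#' @param field field map in ppm.
#' @param kernel a `dipole_kernel`.
#' @param threshold clip level, in (0, 1/3]; default 0.1.
#' @return Susceptibility volume in ppb.
#' @export
tkd_inversion <- function(field, kernel, threshold = 0.1) {
  stopifnot(threshold > 0, threshold <= 1 / 3)
  check_volume(field, kernel$grid, "field")
  d <- kernel$values
  sgn <- ifelse(d >= 0, 1, -1)          # sign(0) := +1
  dsafe <- ifelse(abs(d) >= threshold, d, threshold * sgn)
  Re(ifftn(fftn(field) / dsafe)) * 1000
}

# separable Hanning low-pass window (width w samples, centered at DC) on the
# unshifted FFT lattice
hanning_lowpass <- function(shape, width = 32) {
  half <- width / 2
  win <- lapply(shape, function(n) {
    i <- seq_len(n) - 1L
    m <- pmin(i, n - i)                  # distance to DC in samples
    ifelse(m <= half, cos(pi * m / width)^2, 0)
  })
  array(rep(win[[1]], times = shape[2] * shape[3]), shape) *
    array(rep(rep(win[[2]], each = shape[1]), times = shape[3]), shape) *
    array(rep(win[[3]], each = shape[1] * shape[2]), shape)
}

#' High-pass filter used for high-susceptibility detection
#'
#' k-space multiplication by the complement of a centered separable Hanning
#' low-pass window (default width 32 samples), the homodyne-style filter used
#' to isolate veins, basal ganglia and other localized high-susceptibility
#' content before thresholding.
#'
#' @param volume real 3D array.
#' @param width window width in k-space samples.
#' @return Filtered (high-pass) volume.
#' @export
highpass_filter <- function(volume, width = 32) {
  H <- hanning_lowpass(dim(volume), width)
  Re(ifftn((1 - H) * fftn(volume)))
}

#' Iterative SWIM (iSWIM) inversion
#'
#' TKD followed by iterative refilling of the ill-conditioned cone
#' `{|D| < threshold}`: at each iteration, high-susceptibility voxels are
#' detected by thresholding the high-pass-filtered map, a constraint map
#' equal to the current map on those voxels (zero elsewhere) is built, and
#' its spectrum replaces the cone region of k-space.  Samples in the
#' well-conditioned region are never modified, so `n_iter = 0` is exactly
#' TKD.
#'
#' @inheritParams tkd_inversion
#' @param n_iter number of refilling iterations (default 4).
#' @param chi_clip_threshold detection threshold on the high-pass-filtered
#'   map, in ppb (default 250).
#' @param hp_width Hanning window width for the high-pass filter.
#' @return Susceptibility volume in ppb.
#' @export
iswim_inversion <- function(field, kernel, threshold = 0.1, n_iter = 4,
                            chi_clip_threshold = 250, hp_width = 32) {
  stopifnot(n_iter >= 0)
  chi <- tkd_inversion(field, kernel, threshold)
  if (n_iter == 0) return(chi)
  ill <- abs(kernel$values) < threshold
  for (it in seq_len(n_iter)) {
    hp <- highpass_filter(chi, hp_width)
    chi_c <- chi * (abs(hp) > chi_clip_threshold)
    X <- fftn(chi)
    X[ill] <- fftn(chi_c)[ill]
    chi <- Re(ifftn(X))
  }
  chi
}

#' COSMOS multi-orientation inversion
#'
#' Calculation of susceptibility through multiple orientation sampling:
#' voxelwise-in-k weighted least squares over several head (here: B0-vector)
#' orientations, `chi_k = sum_i w_i D_i dB_i,k / sum_i w_i D_i^2`.  With three
#' or more well-separated orientations the zero cones do not intersect and
#' the inversion is well-posed.
#'
#' @param fields list of field maps (ppm), one per orientation.
#' @param kernels list of `dipole_kernel`s, one per orientation (same spatial
#'   grid, different `b0_direction`).
#' @param weights per-orientation non-negative weights (default equal).
#' @param eps denominator regularization; k-samples with
#'   `sum w_i D_i^2 < eps` are zeroed (for consistent multi-orientation data
#'   the ratio stays exact down to tiny denominators, so the default is
#'   small).
#' @return Susceptibility volume in ppb.
#' @export
cosmos_inversion <- function(fields, kernels, weights = NULL, eps = 1e-9) {
  if (length(fields) < 2) stop("COSMOS needs at least 2 orientations")
  if (length(fields) != length(kernels)) stop("fields/kernels length mismatch")
  if (is.null(weights)) weights <- rep(1, length(fields))
  num <- array(0i, dim(fields[[1]]))
  den <- array(0, dim(fields[[1]]))
  for (i in seq_along(fields)) {
    d <- kernels[[i]]$values
    num <- num + weights[i] * d * fftn(fields[[i]])
    den <- den + weights[i] * d^2
  }
  X <- ifelse(den >= eps, 1, 0) * num / pmax(den, eps)
  Re(ifftn(X)) * 1000
}
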