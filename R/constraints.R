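## Structural priors of the constrained inversion: edge-exclusion mask P and
## protection mask R.

# robust noise level of a derivative volume: 1.4826 * MAD within the mask
robust_sigma <- function(x, mask = NULL) {
  v <- if (is.null(mask)) as.vector(x) else x[mask]
  stats::mad(v)
}

#' Edge-exclusion mask P
#'
#' Per axis, `P_i = 1` where neither the structural image nor the initial
#' susceptibility map has a significant derivative, and 0 on edges:
#' `P_i = [|G_i rho| < mu1] * [|G_i chi_hat| < mu2]`, with each threshold
#' `noise_mult` times the robust noise level (1.4826 x MAD over the brain
#' mask) of the corresponding derivative volume.  P gates the
#' gradient-sparsity penalty so genuine tissue edges are not smoothed.
#' Constant inputs give `P == 1` everywhere.
#'
#' @param structural high-contrast structural volume (T1WE-like).
#' @param chi_init initial susceptibility map (ppb).
#' @param voxel_size per-axis voxel size in mm.
#' @param brain_mask logical mask for the noise estimate (default: all).
#' @param noise_mult threshold multiplier (default 2.5).
#' @return List of three binary volumes `P_x`, `P_y`, `P_z` (stored 0/1).
#' @export
edge_mask <- function(structural, chi_init, voxel_size = c(1, 1, 1),
                      brain_mask = NULL, noise_mult = 2.5) {
  stopifnot(identical(dim(structural), dim(chi_init)))
  out <- vector("list", 3)
  for (a in 1:3) {
    g1 <- gradient_op(structural, a, voxel_size)
    g2 <- gradient_op(chi_init, a, voxel_size)
    mu1 <- noise_mult * robust_sigma(g1, brain_mask)
    mu2 <- noise_mult * robust_sigma(g2, brain_mask)
    # a zero noise floor (e.g. piecewise-constant input) falls back to
    # exact-zero-gradient detection so true edges are still excluded
    p1 <- if (mu1 > 0) abs(g1) < mu1 else g1 == 0
    p2 <- if (mu2 > 0) abs(g2) < mu2 else g2 == 0
    p <- p1 & p2
    out[[a]] <- array(as.numeric(p), dim(structural))
  }
  names(out) <- c("P_x", "P_y", "P_z")
  out
}

#' Structural protection mask R
#'
#' The amplitude (L2) penalty is weighted by `R`, built from the normalized
#' structural image with hard zeros over everything that must not be smoothed
#' toward zero: deep-gray-matter labels, and voxels where the
#' high-pass-filtered initial susceptibility exceeds `chi_clip_threshold`
#' (veins, microbleeds, calcifications).  Zero outside the brain mask.
#'
#' @param structural structural volume (>= 0).
#' @param chi_init initial susceptibility map (ppb).
#' @param dgm_mask logical volume of deep-gray-matter voxels (may be all
#'   `FALSE` if no segmentation is available).
#' @param brain_mask logical brain mask.
#' @param chi_clip_threshold detection threshold (ppb) on the
#'   high-pass-filtered `chi_init`; default 250.
#' @param binary if `TRUE`, return a 0/1 mask instead of the normalized
#'   intensity (ablation option).
#' @param outside value of R outside the brain mask (default 1: the signal-
#'   free exterior is pinned to zero susceptibility, keeping the inversion
#'   well-posed; set 0 to leave the exterior unconstrained).
#' @param hp_width Hanning width of the high-pass filter.
#' @return Volume R in `[0, 1]`.
#' @export
structural_R_mask <- function(structural, chi_init, dgm_mask, brain_mask,
                              chi_clip_threshold = 250, binary = FALSE,
                              outside = 1, hp_width = 32) {
  if (any(structural < 0)) stop("structural image must be non-negative")
  mx <- max(structural[brain_mask])
  R <- if (binary) (structural > 0) * 1 else structural / mx
  hp <- highpass_filter(chi_init, hp_width)
  R[dgm_mask] <- 0
  R[abs(hp) > chi_clip_threshold] <- 0
  R[!brain_mask] <- outside
  R
}

#' Ideal constraint masks from the ground-truth phantom
#'
#' For simulation studies the exact edge and structure maps are known:
#' `P_i = 1` exactly where the ground-truth susceptibility has no derivative
#' along axis i, and `R` is the normalized structural reference with zeros on
#' every deep-gray structure, vein and sphere insert (and outside the brain).
#'
#' @param dataset a `stage_dataset` from [simulate_stage()].
#' @return List with `P` (list `P_x`, `P_y`, `P_z`), `R`, `brain_mask`.
#' @export
ideal_masks <- function(dataset) {
  chi <- dataset$chi_gt
  vs <- dataset$grid$voxel_size
  P <- lapply(1:3, function(a)
    array(as.numeric(gradient_op(chi, a, vs) == 0), dim(chi)))
  names(P) <- c("P_x", "P_y", "P_z")
  tis <- dataset$spec$tissues
  protected_codes <- tis$code[tis$is_dgm | tis$is_sphere | tis$name == "V"]
  prot <- array(dataset$labels %in% protected_codes, dim(chi))
  R <- dataset$structural / max(dataset$structural[dataset$brain_mask])
  R[prot] <- 0
  # outside the head there is no signal and no source: the amplitude penalty
  # pins the exterior to zero, which also keeps the inversion well-posed
  R[!dataset$brain_mask] <- 1
  list(P = P, R = R, brain_mask = dataset$brain_mask)
}
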