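## Quantitative evaluation: RMSE, 3D SSIM, ROI statistics, zero-referenced
## regression against reference values.

#' Root-mean-square error between two susceptibility maps
#'
#' @param chi,chi_ref volumes on the same grid (ppb).
#' @param mask logical volume; the error is averaged over it (default: all).
#' @return RMSE in ppb.
#' @export
rmse <- function(chi, chi_ref, mask = NULL) {
  stopifnot(identical(dim(chi), dim(chi_ref)))
  d <- chi - chi_ref
  if (!is.null(mask)) {
    if (!any(mask)) stop("empty mask")
    d <- d[mask]
  }
  sqrt(mean(d^2))
}

# separable Gaussian smoothing via FFT (circular boundary; evaluation masks
# stay away from the volume edge so wrap-around is immaterial)
gauss_smooth <- function(x, sigma) {
  sh <- dim(x)
  g <- lapply(sh, function(n) {
    i <- seq_len(n) - 1L
    m <- pmin(i, n - i)
    k <- exp(-m^2 / (2 * sigma^2))
    k / sum(k)
  })
  K <- array(rep(g[[1]], times = sh[2] * sh[3]), sh) *
    array(rep(rep(g[[2]], each = sh[1]), times = sh[3]), sh) *
    array(rep(g[[3]], each = sh[1] * sh[2]), sh)
  Re(ifftn(fftn(x) * fftn(K)))
}

#' Mean 3D structural similarity index
#'
#' Local SSIM with a 3D Gaussian window (sigma = 1.5 voxels) and the standard
#' stabilizers `C1 = (K1 L)^2`, `C2 = (K2 L)^2` (K1 = 0.01, K2 = 0.03), with
#' the data range `L` taken from `chi_ref` within the mask; the SSIM map is
#' averaged over the mask.
#'
#' @param chi test volume.
#' @param chi_ref reference volume (defines the data range).
#' @param mask logical volume to average over (default: all).
#' @param sigma Gaussian window sigma in voxels.
#' @param K1,K2 stabilizer constants.
#' @return Scalar in `[-1, 1]`.
#' @export
ssim_index <- function(chi, chi_ref, mask = NULL, sigma = 1.5,
                       K1 = 0.01, K2 = 0.03) {
  stopifnot(identical(dim(chi), dim(chi_ref)))
  if (is.null(mask)) mask <- array(TRUE, dim(chi))
  L <- diff(range(chi_ref[mask]))
  if (L == 0) L <- max(abs(chi_ref[mask]), 1)
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  mu1 <- gauss_smooth(chi, sigma); mu2 <- gauss_smooth(chi_ref, sigma)
  s11 <- gauss_smooth(chi^2, sigma) - mu1^2
  s22 <- gauss_smooth(chi_ref^2, sigma) - mu2^2
  s12 <- gauss_smooth(chi * chi_ref, sigma) - mu1 * mu2
  ssim_map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  mean(ssim_map[mask])
}

#' ROI statistics over a label volume
#'
#' Mean, standard deviation and voxel count of the susceptibility over the
#' entire 3D extent of each label.  Manually drawn ROI volumes are accepted
#' in exactly the same form (integer codes).
#'
#' @param chi susceptibility volume (ppb).
#' @param labels integer label volume (0 = unlabeled).
#' @param tissues optional table mapping `code` to `name`.
#' @return data.frame with columns `code`, `name`, `mean`, `sd`, `n`.
#' @export
roi_stats <- function(chi, labels, tissues = NULL) {
  codes <- sort(unique(labels[labels > 0L]))
  out <- data.frame(code = codes,
                    name = if (!is.null(tissues))
                      tissues$name[match(codes, tissues$code)]
                    else as.character(codes),
                    mean = NA_real_, sd = NA_real_, n = NA_integer_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(codes)) {
    v <- chi[labels == codes[i]]
    out$mean[i] <- mean(v)
    out$sd[i] <- stats::sd(v)
    out$n[i] <- length(v)
  }
  out$sd[out$n == 1L] <- 0
  out
}

# average the -L/-R pair of every bilateral structure name
bilateral_average <- function(report) {
  base <- sub("-[LR]$", "", report$name)
  agg <- stats::aggregate(report$mean, list(name = base), mean)
  names(agg)[2] <- "mean"
  agg
}

#' Zero-referenced regression against reference susceptibilities
#'
#' Both the measured and the reference ROI means are zero-referenced by
#' subtracting their own CSF mean; bilateral structures (`-L`/`-R` suffixes)
#' are averaged; ordinary least squares of measured on reference gives the
#' accuracy slope (1 = unbiased).
#'
#' @param report ROI report of the reconstruction ([roi_stats()] output).
#' @param reference data.frame with `name` and `mean` of the reference
#'   (model values or a reference reconstruction).
#' @param structures structure base names entering the fit (default: the
#'   deep-gray set CN, GP, PT, THA, RN, SN, CC).
#' @param csf_name CSF label name used for referencing.
#' @return List with `slope`, `intercept`, `r`, and the fitted `data`.
#' @export
reference_regression <- function(report, reference,
                                 structures = c("CN", "GP", "PT", "THA",
                                                "RN", "SN", "CC"),
                                 csf_name = "CSF") {
  m <- bilateral_average(report)
  r <- bilateral_average(reference)
  if (!(csf_name %in% m$name) || !(csf_name %in% r$name))
    stop("CSF must be present on both sides for zero-referencing")
  m$mean <- m$mean - m$mean[m$name == csf_name]
  r$mean <- r$mean - r$mean[r$name == csf_name]
  keep <- intersect(structures, intersect(m$name, r$name))
  if (length(keep) < 3) stop("need at least 3 structures for the regression")
  x <- r$mean[match(keep, r$name)]
  y <- m$mean[match(keep, m$name)]
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y),
       data = data.frame(name = keep, reference = x, measured = y))
}
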