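## Simulated STAGE brain phantom
##
## A deterministic parametric stand-in for a labeled human-brain
## susceptibility model: ellipsoidal cortex/white matter, paired ellipsoidal
## deep-gray structures, medial ventricles, capsule-primitive veins, and
## spherical microbleed / calcification / pineal-gland inserts.  Tissue
## susceptibility, T1 and relative proton density follow the standard
## literature values used for QSM simulation studies.

#' Acquisition parameters for a STAGE protocol
#'
#' STAGE acquires two double-echo gradient-echo scans at a low and a high flip
#' angle.  Echo times may differ slightly between the two flip-angle scans;
#' they are therefore stored per scan.
#'
#' @param b0_T field strength in tesla.
#' @param tr_s repetition time in seconds.
#' @param flip_deg flip angles in degrees, `c(low, high)`.
#' @param te_low_s the two echo times (s) of the low-flip scan.
#' @param te_high_s the two echo times (s) of the high-flip scan.
#' @param b0_direction unit vector of B0 in image coordinates.
#' @return An object of class `acq_params`.
#' @export
acq_params <- function(b0_T = 3, tr_s = 25e-3, flip_deg = c(6, 24),
                       te_low_s = c(7.5e-3, 17.5e-3),
                       te_high_s = c(8.75e-3, 18.75e-3),
                       b0_direction = c(0, 0, 1)) {
  stopifnot(b0_T > 0, tr_s > 0, length(flip_deg) == 2,
            length(te_low_s) == 2, length(te_high_s) == 2)
  structure(list(b0_T = b0_T, tr_s = tr_s, flip_deg = flip_deg,
                 te_low_s = te_low_s, te_high_s = te_high_s,
                 b0_direction = b0_direction),
            class = "acq_params")
}

#' Tissue property table of the simulated brain model
#'
#' Susceptibility (ppb), T1 (ms) and relative proton density for each label.
#' Sphere inserts (CMB, CaD, PG) carry zero proton density, so their magnitude
#' signal vanishes, and a fixed R2* of 40/s.
#'
#' @return data.frame with columns `code`, `name`, `chi_ppb`, `T1_ms`, `pd`,
#'   `is_sphere`, `is_dgm`.
#' @export
tissue_table <- function() {
  tb <- data.frame(
    name    = c("WM", "GM", "GP-L", "GP-R", "PT-L", "PT-R", "THA-L", "THA-R",
                "CN-L", "CN-R", "SN-L", "SN-R", "RN-L", "RN-R", "CC-L", "CC-R",
                "V", "CSF", "CMB1", "CMB2", "CaD1", "CaD2", "PG"),
    chi_ppb = c(0, 20, 180, 180, 90, 90, 10, 10, 60, 60, 160, 160, 130, 130,
                -30, -30, 450, -14, 3000, 1000, -1000, -3000, -3000),
    T1_ms   = c(837, 1607, 888, 888, 1140, 1140, 1218, 1218, 1226, 1226,
                1147, 1147, 833, 833, 780, 780, 1932, 4163,
                1000, 1000, 1000, 1000, 1000),
    pd      = c(0.73, 0.80, 0.72, 0.72, 0.82, 0.82, 0.79, 0.79, 0.82, 0.82,
                0.79, 0.79, 0.80, 0.80, 0.79, 0.79, 0.85, 1.00,
                0, 0, 0, 0, 0),
    stringsAsFactors = FALSE)
  tb$code <- seq_len(nrow(tb))
  tb$is_sphere <- tb$name %in% c("CMB1", "CMB2", "CaD1", "CaD2", "PG")
  tb$is_dgm <- tb$name %in% c("GP-L", "GP-R", "PT-L", "PT-R", "THA-L", "THA-R",
                              "CN-L", "CN-R", "SN-L", "SN-R", "RN-L", "RN-R",
                              "CC-L", "CC-R")
  tb[, c("code", "name", "chi_ppb", "T1_ms", "pd", "is_sphere", "is_dgm")]
}

#' Default sphere inserts
#'
#' Two microbleed-like paramagnetic spheres in frontal white matter
#' (+3000 ppb r = 3 mm, +1000 ppb r = 5 mm), two calcification-like
#' diamagnetic spheres in posterior white matter (-1000 ppb r = 5 mm,
#' -3000 ppb r = 3 mm), and one pineal-gland-like midline sphere
#' (-3000 ppb r = 3 mm).  Centers are in mm, relative to the grid center.
#'
#' @return data.frame with columns `name`, `cx`, `cy`, `cz`, `radius_mm`,
#'   `chi_ppb`.
#' @export
default_spheres <- function() {
  data.frame(
    name      = c("CMB1", "CMB2", "CaD1", "CaD2", "PG"),
    cx        = c(14, -14, -16, 16, 0),
    cy        = c(26, 26, -26, -26, -24),
    cz        = c(0, 0, 2, 2, 9),
    radius_mm = c(3, 5, 5, 3, 3),
    chi_ppb   = c(3000, 1000, -1000, -3000, -3000),
    stringsAsFactors = FALSE)
}

#' Phantom specification
#'
#' @param grid a [voxel_grid]; the default 96x96x64 at 1x1x1.5 mm is the
#'   desk-scale preset; `preset = "paper"` selects 160x160x96.
#' @param spheres sphere insert table as in [default_spheres()]; may be `NULL`
#'   for a sphere-free model.
#' @param tissues tissue property table, defaults to [tissue_table()].
#' @param preset `"desk"` or `"paper"` grid preset (ignored when `grid` is
#'   given).
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = NULL, spheres = default_spheres(),
                         tissues = tissue_table(), preset = "desk") {
  if (is.null(grid)) {
    grid <- switch(match.arg(preset, c("desk", "paper")),
                   desk  = voxel_grid(c(96, 96, 64), c(1, 1, 1.5)),
                   paper = voxel_grid(c(160, 160, 96), c(1, 1, 1.5)))
  }
  if (!is.null(spheres) && nrow(spheres) > 0 &&
      !all(spheres$name %in% tissues$name))
    stop("every sphere label needs a tissue-table entry")
  structure(list(grid = grid, spheres = spheres, tissues = tissues),
            class = "phantom_spec")
}

# world coordinates (mm) of voxel centers relative to the grid center
world_coords <- function(grid) {
  sh <- grid$shape; vs <- grid$voxel_size
  lapply(1:3, function(a) (seq_len(sh[a]) - (sh[a] + 1) / 2) * vs[a])
}

# squared normalized ellipsoid radius on the voxel lattice
ellipsoid_q <- function(coords, center, semi) {
  x <- (coords[[1]] - center[1]) / semi[1]
  y <- (coords[[2]] - center[2]) / semi[2]
  z <- (coords[[3]] - center[3]) / semi[3]
  sh <- c(length(x), length(y), length(z))
  array(rep(x^2, times = sh[2] * sh[3]), sh) +
    array(rep(rep(y^2, each = sh[1]), times = sh[3]), sh) +
    array(rep(z^2, each = sh[1] * sh[2]), sh)
}

# squared distance from each voxel center to a segment (capsule axis)
capsule_d2 <- function(coords, p0, p1) {
  sh <- c(length(coords[[1]]), length(coords[[2]]), length(coords[[3]]))
  X <- array(rep(coords[[1]], times = sh[2] * sh[3]), sh)
  Y <- array(rep(rep(coords[[2]], each = sh[1]), times = sh[3]), sh)
  Z <- array(rep(coords[[3]], each = sh[1] * sh[2]), sh)
  v <- p1 - p0; L2 <- sum(v^2)
  t <- ((X - p0[1]) * v[1] + (Y - p0[2]) * v[2] + (Z - p0[3]) * v[3]) / L2
  t <- pmin(pmax(t, 0), 1)
  (X - (p0[1] + t * v[1]))^2 + (Y - (p0[2] + t * v[2]))^2 +
    (Z - (p0[3] + t * v[3]))^2
}

# reference anatomy (mm) for a brain of semi-axes (40, 44, 38); per-axis
# linearly rescaled to the brain that fits the requested grid
phantom_anatomy <- function() {
  list(
    ref_semi = c(40, 44, 38),
    inner_scale = 0.82,                      # WM/GM shell boundary
    bilateral = list(
      # name, center (right side; left mirrors x), semi-axes
      "CN"  = list(center = c(12, 14, 6),   semi = c(3.5, 7, 5)),
      "PT"  = list(center = c(20, 6, 2),    semi = c(4.5, 8, 5)),
      "GP"  = list(center = c(13, 3, 0),    semi = c(3.5, 5.5, 4)),
      "THA" = list(center = c(8, -8, 0),    semi = c(5.5, 7.5, 5.5)),
      "RN"  = list(center = c(4, -15, -6),  semi = c(2.5, 2.5, 2.5)),
      "SN"  = list(center = c(8, -17, -9),  semi = c(2.5, 4.5, 2.5)),
      "CC"  = list(center = c(12, -14, -9), semi = c(2.5, 5, 3.5))),
    csf = list(list(center = c(7, 4, 6),  semi = c(5, 13, 6)),
               list(center = c(-7, 4, 6), semi = c(5, 13, 6))),
    veins = list(list(p0 = c(0, -20, 2), p1 = c(0, -36, -4), radius = 2.5),
                 list(p0 = c(0, -4, 6),  p1 = c(0, -18, 4),  radius = 1.8)))
}

#' Build the labeled susceptibility phantom
#'
#' Rasterizes the parametric anatomy onto the voxel grid
#' (voxel-center-inside-surface), assigns each label its tissue-table
#' susceptibility, and adds the sphere inserts.  Deterministic given the spec.
#'
#' @param spec a [phantom_spec].
#' @return List with `chi` (ppb, 3D array), `labels` (integer codes, 0 =
#'   background), `brain_mask` (logical array), `grid`, `spec`.
#' @export
build_phantom <- function(spec = phantom_spec()) {
  grid <- spec$grid
  tis <- spec$tissues
  code_of <- function(nm) tis$code[match(nm, tis$name)]
  anat <- phantom_anatomy()
  co <- world_coords(grid)
  fov <- grid$shape * grid$voxel_size
  brain_semi <- 0.42 * fov
  s <- brain_semi / anat$ref_semi       # per-axis anatomy scale

  labels <- array(0L, grid$shape)
  brain <- ellipsoid_q(co, c(0, 0, 0), brain_semi) < 1
  labels[brain] <- code_of("GM")
  inner <- ellipsoid_q(co, c(0, 0, 0), anat$inner_scale * brain_semi) < 1
  labels[inner] <- code_of("WM")

  for (v in anat$csf) {
    q <- ellipsoid_q(co, v$center * s, v$semi * s)
    labels[q < 1 & brain] <- code_of("CSF")
  }
  for (nm in names(anat$bilateral)) {
    st <- anat$bilateral[[nm]]
    for (side in c("R", "L")) {
      ctr <- st$center * s
      if (side == "L") ctr[1] <- -ctr[1]
      q <- ellipsoid_q(co, ctr, st$semi * s)
      labels[q < 1 & brain] <- code_of(paste0(nm, "-", side))
    }
  }
  for (v in anat$veins) {
    d2 <- capsule_d2(co, v$p0 * s, v$p1 * s)
    labels[d2 < v$radius^2 & brain] <- code_of("V")
  }

  if (!is.null(spec$spheres) && nrow(spec$spheres) > 0) {
    sp <- spec$spheres
    for (i in seq_len(nrow(sp))) for (j in seq_len(nrow(sp))) if (i < j) {
      d <- sqrt(sum((c(sp$cx[i], sp$cy[i], sp$cz[i]) * s -
                     c(sp$cx[j], sp$cy[j], sp$cz[j]) * s)^2))
      if (d < sp$radius_mm[i] + sp$radius_mm[j])
        stop(sprintf("overlapping spheres: %s and %s", sp$name[i], sp$name[j]))
    }
    for (i in seq_len(nrow(sp))) {
      q <- ellipsoid_q(co, c(sp$cx[i], sp$cy[i], sp$cz[i]) * s,
                       rep(sp$radius_mm[i], 3))
      inside <- q < 1
      if (!all(brain[inside]))
        stop(sprintf("sphere %s extends outside the brain", sp$name[i]))
      labels[inside] <- code_of(sp$name[i])
    }
  }

  chi <- array(0, grid$shape)
  idx <- labels > 0L
  chi[idx] <- tis$chi_ppb[labels[idx]]
  list(chi = chi, labels = labels, brain_mask = labels > 0L,
       grid = grid, spec = spec)
}

#' R2* map from the susceptibility model
#'
#' `R2* = 20/s + 0.125 * chi` (chi in ppb), except sphere inserts
#' (CMB/CaD/PG), which are fixed at 40/s; clamped at >= 0.
#'
#' @param chi susceptibility volume in ppb.
#' @param labels integer label volume.
#' @param tissues tissue table (for the sphere codes).
#' @return R2* volume in 1/s.
#' @export
chi_to_r2star <- function(chi, labels, tissues = tissue_table()) {
  r2s <- pmax(20 + 0.125 * chi, 0)
  sphere_codes <- tissues$code[tissues$is_sphere]
  r2s[labels %in% sphere_codes] <- 40
  array(r2s, dim(chi))
}

#' Steady-state gradient-echo magnitude (Ernst equation)
#'
#' `S = pd * sin(a) * (1 - E1) / (1 - cos(a) E1) * exp(-TE * R2*)` with
#' `E1 = exp(-TR/T1)`.
#'
#' @param pd relative proton density volume (0 for signal-free inserts).
#' @param T1_ms T1 volume in ms (> 0).
#' @param r2star R2* volume in 1/s.
#' @param tr_s repetition time (s).
#' @param flip_deg flip angle in degrees.
#' @param te_s echo time (s).
#' @return Magnitude volume (arbitrary units, >= 0).
#' @export
ernst_magnitude <- function(pd, T1_ms, r2star, tr_s, flip_deg, te_s) {
  stopifnot(tr_s > 0, flip_deg > 0, flip_deg < 180)
  if (any(T1_ms <= 0)) stop("T1 must be positive")
  a <- flip_deg * pi / 180
  e1 <- exp(-tr_s / (T1_ms * 1e-3))
  pd * sin(a) * (1 - e1) / (1 - cos(a) * e1) * exp(-te_s * r2star)
}

wrap_phase <- function(phi) {
  # wrap to (-pi, pi]
  w <- phi - 2 * pi * round(phi / (2 * pi))
  w[w <= -pi] <- w[w <= -pi] + 2 * pi
  w
}

#' Simulate a noisy multi-echo dual-flip-angle STAGE dataset
#'
#' Forward-simulates the four GRE echoes (low/high flip angle, short/long TE)
#' from the phantom: phase from the dipole forward model, magnitude from the
#' Ernst equation with the chi-derived R2* map, then complex Gaussian noise at
#' the requested magnitude SNR (sigma = mean noise-free in-brain magnitude /
#' snr, added independently to the real and imaginary channels).
#'
#' @param spec a [phantom_spec].
#' @param params an [acq_params].
#' @param snr magnitude signal-to-noise ratio (Inf for noise-free).
#' @param seed RNG seed (integer) for reproducibility.
#' @return Object of class `stage_dataset`: list with `echoes` (named list
#'   `FAL_TE1`, `FAH_TE1`, `FAL_TE2`, `FAH_TE2`, each with `magnitude`,
#'   `phase`, `te_s`, `flip_deg`), `params`, `chi_gt`, `labels`,
#'   `brain_mask`, `structural` (noise-free high-flip short-TE magnitude,
#'   the T1-weighted-enhanced analogue), `r2star_gt`, `grid`.
#' @export
simulate_stage <- function(spec = phantom_spec(), params = acq_params(),
                           snr = 10, seed = 1L) {
  stopifnot(snr > 0)
  ph <- build_phantom(spec)
  grid <- ph$grid
  grid$b0_direction <- params$b0_direction
  tis <- spec$tissues

  pd <- array(0, grid$shape); T1 <- array(1000, grid$shape)
  idx <- ph$labels > 0L
  pd[idx] <- tis$pd[ph$labels[idx]]
  T1[idx] <- tis$T1_ms[ph$labels[idx]]
  r2s <- chi_to_r2star(ph$chi, ph$labels, tis)

  kernel <- make_dipole_kernel(grid)
  dB <- forward_field(ph$chi, kernel)     # ppm

  echo_defs <- list(
    FAL_TE1 = list(flip = params$flip_deg[1], te = params$te_low_s[1]),
    FAH_TE1 = list(flip = params$flip_deg[2], te = params$te_high_s[1]),
    FAL_TE2 = list(flip = params$flip_deg[1], te = params$te_low_s[2]),
    FAH_TE2 = list(flip = params$flip_deg[2], te = params$te_high_s[2]))

  wm <- ph$labels == tis$code[tis$name == "WM"]
  if (!any(wm)) wm <- ph$brain_mask
  set.seed(as.integer(seed))
  echoes <- lapply(echo_defs, function(e) {
    mag <- ernst_magnitude(pd, T1, r2s, params$tr_s, e$flip, e$te)
    phi <- field_to_phase(dB, e$te, params$b0_T)
    sig <- mag * exp(1i * phi)
    if (is.finite(snr)) {
      # SNR is referenced to the white-matter signal level
      sigma <- mean(mag[wm]) / snr
      n <- length(sig)
      sig <- sig + complex(real = stats::rnorm(n, 0, sigma),
                           imaginary = stats::rnorm(n, 0, sigma))
    }
    list(magnitude = array(Mod(sig), grid$shape),
         phase = array(wrap_phase(Arg(sig)), grid$shape),
         te_s = e$te, flip_deg = e$flip)
  })

  structural <- ernst_magnitude(pd, T1, r2s, params$tr_s,
                                params$flip_deg[2], params$te_high_s[1])
  structure(list(echoes = echoes, params = params, chi_gt = ph$chi,
                 labels = ph$labels, brain_mask = ph$brain_mask,
                 structural = structural, r2star_gt = r2s, grid = grid,
                 spec = spec, snr = snr, seed = as.integer(seed)),
            class = "stage_dataset")
}

#' @export
print.stage_dataset <- function(x, ...) {
  cat(sprintf("STAGE dataset: %dx%dx%d voxels, %d echoes, SNR %s, seed %d\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              length(x$echoes),
              if (is.finite(x$snr)) format(x$snr) else "Inf", x$seed))
  for (nm in names(x$echoes))
    cat(sprintf("  %s: flip %g deg, TE %.2f ms\n", nm,
                x$echoes[[nm]]$flip_deg, 1000 * x$echoes[[nm]]$te_s))
  invisible(x)
}
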