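## L-curve selection of the regularization weight lambda2 (lambda1 tied at a
## fixed ratio).

#' L-curve scan over lambda2
#'
#' Solves the constrained inversion for each value of a log-spaced lambda2
#' grid, records the data-fidelity residual and the regularization value at
#' each solution, and selects the grid value of maximum curvature of the
#' log-log residual-vs-regularization curve (the L-curve corner).  The
#' curvature is computed by 3-point finite differences after monotone (PCHIP)
#' interpolation of the curve onto a dense log-lambda grid.
#'
#' @param field local field map (ppm).
#' @param kernel a `dipole_kernel`.
#' @param masks mask list as in [scswim()].
#' @param lambda2_grid increasing vector of >= 5 lambda2 values (log-spaced).
#' @param chi_init optional initial susceptibility (ppb); computed once
#'   (iSWIM) and shared across the scan if missing.
#' @param params base [scswim_params]; `lambda2` is overridden per grid point.
#' @param chi_ref optional ground-truth volume (ppb); when given, the scan
#'   table also records the RMSE of each solution (the second selection
#'   criterion used on simulated data).
#' @return Object of class `lcurve_scan`: list with `table` (data.frame:
#'   lambda2, residual, regularization, curvature, and rmse when `chi_ref`
#'   is given) and `lambda2_opt` (max-curvature grid element).
#' @export
lcurve_scan <- function(field, kernel, masks = list(), lambda2_grid,
                        chi_init = NULL, params = scswim_params(),
                        chi_ref = NULL) {
  if (length(lambda2_grid) < 5) stop("need a grid of at least 5 lambda values")
  lambda2_grid <- sort(lambda2_grid)
  if (is.null(chi_init)) chi_init <- iswim_inversion(field, kernel)

  sh <- dim(field)
  ones <- array(1, sh)
  if (is.null(masks$W)) masks$W <- ones
  if (is.null(masks$P)) masks$P <- list(ones, ones, ones)
  if (is.null(masks$R)) masks$R <- ones
  vs <- kernel$grid$voxel_size

  res <- reg <- rmse_v <- numeric(length(lambda2_grid))
  for (j in seq_along(lambda2_grid)) {
    p <- params
    p$lambda2 <- lambda2_grid[j]
    p$lambda1 <- p$lambda1_ratio * p$lambda2
    fit <- scswim(field, kernel, masks, p, chi_init)
    chi <- fit$chi * 1e-9                      # dimensionless, solver scale
    r <- Re(ifftn(kernel$values * fftn(chi))) - field * 1e-6
    res[j] <- sqrt(sum((masks$W * r)^2))
    l1 <- 0
    for (a in 1:3) l1 <- l1 + sum(abs(masks$P[[a]] * gradient_op(chi, a, vs)))
    reg[j] <- p$lambda1_ratio * l1 + 0.5 * sum((masks$R * chi)^2)
    if (!is.null(chi_ref))
      rmse_v[j] <- sqrt(mean((fit$chi - chi_ref)^2))
  }

  if (any(diff(res) < 0))
    warning("fidelity residual not monotone over the lambda grid")

  curv <- lcurve_curvature(log(lambda2_grid), log(res), log(reg))
  tab <- data.frame(lambda2 = lambda2_grid, residual = res,
                    regularization = reg, curvature = curv)
  if (!is.null(chi_ref)) tab$rmse <- rmse_v
  structure(list(table = tab,
                 lambda2_opt = lambda2_grid[which.max(curv)]),
            class = "lcurve_scan")
}

# curvature of the parametric log-log curve (x(t), y(t)), t = log(lambda),
# evaluated at the grid points: PCHIP-interpolate onto a dense t grid,
# finite-difference the derivatives, read the curvature back at the nodes
lcurve_curvature <- function(t, x, y, n_dense = 200) {
  td <- seq(min(t), max(t), length.out = n_dense)
  xd <- pracma::pchip(t, x, td)
  yd <- pracma::pchip(t, y, td)
  h <- td[2] - td[1]
  grad <- function(v) {
    g <- v
    n <- length(v)
    g[1] <- (v[2] - v[1]) / h
    g[n] <- (v[n] - v[n - 1]) / h
    g[2:(n - 1)] <- (v[3:n] - v[1:(n - 2)]) / (2 * h)
    g
  }
  xp <- grad(xd); yp <- grad(yd)
  xpp <- grad(xp); ypp <- grad(yp)
  kd <- (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
  kd[!is.finite(kd)] <- 0
  # curvature at the original nodes
  vapply(t, function(ti) kd[which.min(abs(td - ti))], numeric(1))
}

#' Default lambda2 scan grid
#'
#' Eight log-spaced points per decade over `[1e-5, 1e-1]`.
#'
#' @return Numeric vector of lambda2 values.
#' @export
default_lambda2_grid <- function() {
  10^seq(-5, -1, by = 1 / 8)
}

#' @export
print.lcurve_scan <- function(x, ...) {
  cat(sprintf("L-curve scan over %d lambda2 values; corner at lambda2 = %.3g\n",
              nrow(x$table), x$lambda2_opt))
  print(x$table, row.names = FALSE, digits = 4)
  invisible(x)
}
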