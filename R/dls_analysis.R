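# Dynamic light scattering: Stokes-Einstein conversion of translational
# diffusion to hydrodynamic diameter, and log-normal summaries of
# intensity-weighted size distributions (geometric mean mu_g, dimensionless
# geometric SD sigma_g, range = mu_g multiplied/divided by sigma_g).

#' DLS measurement configuration
#'
#' Defaults correspond to measurements at 25 degrees C in phosphate-buffered
#' saline, approximating the buffer viscosity by that of water at 25 C
#' (0.8872 mPa s). The Boltzmann constant is fixed at its SI value.
#'
#' @param temperature Absolute temperature, K. Default 298.15.
#' @param viscosity Solvent viscosity, Pa s. Default 0.8872e-3.
#' @return An object of class `dls_config`.
#' @export
dls_config <- function(temperature = 298.15, viscosity = 0.8872e-3) {
  check_number(temperature, "temperature", lower = 0, strict_lower = TRUE)
  check_number(viscosity, "viscosity", lower = 0, strict_lower = TRUE)
  structure(list(temperature = temperature, viscosity = viscosity,
                 boltzmann = 1.380649e-23),
            class = "dls_config")
}

#' Stokes-Einstein hydrodynamic diameter
#'
#' `D_H = k_B T / (3 pi eta D_t)`, returned in nm.
#'
#' @param dt Translational diffusion coefficient, m^2/s (> 0).
#' @param cfg A [dls_config()].
#' @return Hydrodynamic diameter in nm.
#' @examples
#' stokes_einstein_dh(1e-10)  # 4.92 nm at 25 C in water
#' @export
stokes_einstein_dh <- function(dt, cfg = dls_config()) {
  if (any(dt <= 0)) stop_validation("dt must be positive")
  cfg$boltzmann * cfg$temperature / (3 * pi * cfg$viscosity * dt) * 1e9
}

#' @rdname stokes_einstein_dh
#' @param dh Hydrodynamic diameter, nm (> 0); the inverse conversion.
#' @export
stokes_einstein_dt <- function(dh, cfg = dls_config()) {
  if (any(dh <= 0)) stop_validation("dh must be positive")
  cfg$boltzmann * cfg$temperature / (3 * pi * cfg$viscosity * dh * 1e-9)
}

#' Assemble an intensity-weighted size distribution
#'
#' @param dh_grid Hydrodynamic diameters, nm, strictly increasing.
#' @param weights Relative intensities, non-negative, not all zero.
#' @return An object of class `size_distribution`.
#' @export
size_distribution <- function(dh_grid, weights) {
  if (length(dh_grid) != length(weights)) {
    stop_validation("dh_grid and weights must have equal length")
  }
  if (any(diff(dh_grid) <= 0)) stop_validation("dh_grid must be strictly increasing")
  if (any(weights < 0)) stop_validation("weights must be non-negative")
  if (sum(weights) <= 0) stop_validation("weights must not all be zero")
  structure(list(dh_grid = dh_grid, weights = weights), class = "size_distribution")
}

#' Read / write a size-distribution CSV
#'
#' Columns `dh_nm`, `intensity`.
#'
#' @param dist A `size_distribution` (writer).
#' @param path File path.
#' @return A `size_distribution` (reader); `path` invisibly (writer).
#' @export
read_dls_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("dh_nm", "intensity") %in% names(df))) {
    stop_validation("DLS CSV must have columns dh_nm, intensity")
  }
  size_distribution(df$dh_nm, df$intensity)
}

#' @rdname read_dls_csv
#' @export
write_dls_csv <- function(dist, path) {
  utils::write.csv(data.frame(dh_nm = dist$dh_grid, intensity = dist$weights),
                   path, row.names = FALSE)
  invisible(path)
}

#' Fit a log-normal to an intensity-weighted size distribution
#'
#' Least-squares fit of `A * dlnorm(D_H; log mu_g, log sigma_g)` (a log-normal
#' density in ln-diameter space scaled by a free amplitude) by
#' Levenberg-Marquardt. Because the amplitude is free, the fit is invariant to
#' uniform rescaling of the weights. Standard errors come from the linearized
#' covariance; the reported diameter range is `mu_g / sigma_g` to
#' `mu_g * sigma_g`.
#'
#' @param dist A [size_distribution()] with at least 5 positive-weight points.
#' @return An object of class `lognormal_fit` with `mu_g` (nm), `sigma_g`
#'   (dimensionless, >= 1), `se_mu`, `se_sigma`, `amplitude`, `range_low`,
#'   `range_high`, `rss`, `df`.
#' @export
fit_lognormal <- function(dist) {
  if (!inherits(dist, "size_distribution")) {
    stop_validation("dist must be a size_distribution")
  }
  pos <- dist$weights > 0
  if (sum(pos) < 5) {
    stop(errorCondition(
      "at least 5 positive-weight grid points are required for a log-normal fit",
      class = c("etsdyn_fit_error", "error")))
  }
  d <- dist$dh_grid
  w <- dist$weights
  # moment start values in ln-diameter space
  wp <- w / sum(w)
  m0 <- sum(wp * log(d))
  s0 <- sqrt(max(sum(wp * (log(d) - m0)^2), 1e-6))
  df_fit <- data.frame(d = d, w = w)
  start <- list(lmu = m0, lsig = log(max(exp(s0), 1 + 1e-4)),
                A = max(w) / stats::dlnorm(exp(m0), m0, s0))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      w ~ A * stats::dlnorm(d, lmu, exp(lsig)),
      data = df_fit, start = start,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12, ptol = 1e-12)
    ),
    error = function(e) {
      stop(errorCondition(
        paste0("log-normal fit failed: ", conditionMessage(e)),
        class = c("etsdyn_fit_error", "error")))
    }
  )
  est <- stats::coef(fit)
  mu_g <- exp(est[["lmu"]])
  sigma_g <- exp(exp(est[["lsig"]]))
  if (sigma_g < 1 + 1e-9) {
    stop(errorCondition(
      "degenerate distribution: fitted geometric SD collapses to 1",
      class = c("etsdyn_fit_error", "error")))
  }
  nm <- c("lmu", "lsig", "A")
  covm <- tryCatch(stats::vcov(fit), error = function(e) {
    matrix(NA_real_, 3, 3, dimnames = list(nm, nm))
  })
  se_lmu <- sqrt(covm["lmu", "lmu"])
  se_lsig <- sqrt(covm["lsig", "lsig"])
  structure(
    list(mu_g = mu_g, sigma_g = sigma_g,
         se_mu = mu_g * se_lmu,                       # delta method on exp()
         se_sigma = sigma_g * log(sigma_g) * se_lsig, # chain through exp(exp())
         amplitude = est[["A"]],
         range_low = mu_g / sigma_g, range_high = mu_g * sigma_g,
         rss = sum(stats::resid(fit)^2), df = length(d) - 3L),
    class = "lognormal_fit"
  )
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("<lognormal_fit> mu_g = %.2f nm (SE %.3g), sigma_g = %.3f (SE %.3g)\n",
              x$mu_g, x$se_mu, x$sigma_g, x$se_sigma))
  cat(sprintf("  D_H range (mu_g */ sigma_g): %.2f - %.2f nm\n",
              x$range_low, x$range_high))
  invisible(x)
}

#' Compare two fitted size distributions
#'
#' Reports the shift in median hydrodynamic diameter (`mu_g(b) - mu_g(a)`),
#' the broadening ratio (`sigma_g(b) / sigma_g(a)`; < 1 is a tightening of
#' the distribution), and z-scores from the propagated standard errors.
#'
#' @param a Reference fit (e.g. unbound protein).
#' @param b Comparison fit (e.g. DNA-bound).
#' @return An object of class `dls_shift` with `delta_median`,
#'   `broadening_ratio`, `z_median`, `z_sigma`.
#' @export
compare_distributions <- function(a, b) {
  if (!inherits(a, "lognormal_fit") || !inherits(b, "lognormal_fit")) {
    stop_validation("a and b must be lognormal_fit objects")
  }
  delta <- b$mu_g - a$mu_g
  ratio <- b$sigma_g / a$sigma_g
  z_med <- delta / sqrt(a$se_mu^2 + b$se_mu^2)
  # z for the sigma ratio on the log scale
  se_log_a <- a$se_sigma / a$sigma_g
  se_log_b <- b$se_sigma / b$sigma_g
  z_sig <- log(ratio) / sqrt(se_log_a^2 + se_log_b^2)
  structure(
    list(delta_median = delta, broadening_ratio = ratio,
         z_median = z_med, z_sigma = z_sig,
         mu_g_a = a$mu_g, mu_g_b = b$mu_g,
         sigma_g_a = a$sigma_g, sigma_g_b = b$sigma_g),
    class = "dls_shift"
  )
}

#' @export
print.dls_shift <- function(x, ...) {
  dir_med <- if (x$delta_median < 0) "downward" else "upward"
  dir_sig <- if (x$broadening_ratio < 1) "tightening" else "broadening"
  cat(sprintf("<dls_shift> median %.2f -> %.2f nm (%s shift, z = %.2f)\n",
              x$mu_g_a, x$mu_g_b, dir_med, x$z_median))
  cat(sprintf("  sigma_g %.3f -> %.3f (%s, ratio %.3f, z = %.2f)\n",
              x$sigma_g_a, x$sigma_g_b, dir_sig, x$broadening_ratio, x$z_sigma))
  invisible(x)
}
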