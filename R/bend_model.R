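# Point-kink reptation model of circular-permutation electrophoresis.
#
# A protein bound at fractional position x along a gel-resolved DNA fragment
# introduces a fixed kink of angle theta (deflection from linearity). Under
# reptation, mobility tracks the squared end-to-end distance of the migrating
# chain; for a unit rod kinked at x the normalized value is
#     1 - 2 x (1 - x) (1 - cos theta),
# quadratic in x, minimized at x = 0.5 and equal to 1 at both ends. The
# dimensionless prefactor K collects every non-bend contribution (effective
# charge and frictional coupling with the matrix), so that
#     R_f(x) = K * [1 - 2 x (1 - x) (1 - cos theta)]
# and R_f(0) = R_f(1) = K regardless of the bend angle. Theta is reported in
# degrees as the deflection from linearity (180 deg minus the included angle).

#' Predicted relative mobility of a kinked fragment
#'
#' @param x Flexure displacement(s), fractions in \[0, 1\].
#' @param K Non-bend mobility factor (> 0); the mobility at x = 0 and x = 1.
#' @param theta Bend angle in degrees, in \[0, 180).
#' @return Relative mobility, same length as `x`.
#' @examples
#' predict_rf(c(0, 0.5, 1), K = 0.9, theta = 60)
#' @export
predict_rf <- function(x, K, theta) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_validation("x must lie in [0, 1]")
  }
  check_number(K, "K", lower = 0, strict_lower = TRUE)
  check_number(theta, "theta", lower = 0)
  if (theta >= 180) stop_validation("theta must be < 180 degrees")
  K * (1 - 2 * x * (1 - x) * (1 - cospi(theta / 180)))
}

#' Assemble a mobility profile
#'
#' Relative mobilities (bound-band migration over unbound-band migration) of a
#' permuted series, one mean +/- SE per flexure displacement.
#'
#' @param x Flexure displacements in \[0, 1\].
#' @param rf_mean Mean relative mobilities, in (0, 1.5\].
#' @param rf_se Standard errors of the means (>= 0). Default 0 (noise-free).
#' @param n_rep Replicate counts (>= 1). Default 1.
#' @param label Complex identity (protein construct + site).
#' @return An object of class `mobility_profile` with a `points` data frame.
#' @export
mobility_profile <- function(x, rf_mean, rf_se = 0, n_rep = 1L, label = "") {
  n <- length(x)
  rf_se <- rep_len(rf_se, n)
  n_rep <- rep_len(n_rep, n)
  if (length(rf_mean) != n) stop_validation("x and rf_mean lengths differ")
  if (any(x < 0 | x > 1)) stop_validation("x must lie in [0, 1]")
  if (any(rf_mean <= 0 | rf_mean > 1.5)) {
    stop_validation("rf_mean must lie in (0, 1.5]")
  }
  if (any(rf_se < 0)) stop_validation("rf_se must be >= 0")
  if (any(n_rep < 1)) stop_validation("n_rep must be >= 1")
  pts <- data.frame(x = x, rf_mean = rf_mean, rf_se = rf_se, n_rep = as.integer(n_rep))
  pts <- pts[order(pts$x), , drop = FALSE]
  rownames(pts) <- NULL
  structure(list(points = pts, label = label), class = "mobility_profile")
}

#' @export
print.mobility_profile <- function(x, ...) {
  cat(sprintf("<mobility_profile> %s: %d positions, x in [%.3f, %.3f]\n",
              x$label, nrow(x$points), min(x$points$x), max(x$points$x)))
  invisible(x)
}

#' Read / write mobility tables
#'
#' TSV with columns label, x, rf_mean, rf_se, n_rep. A file may hold several
#' labels; `read_mobility_tsv` returns a named list of profiles.
#'
#' @param profile A `mobility_profile` (or list of them) to write.
#' @param path File path.
#' @return A named list of `mobility_profile` objects (reader); `path`
#'   invisibly (writer).
#' @export
read_mobility_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("label", "x", "rf_mean", "rf_se", "n_rep")
  if (!all(need %in% names(df))) {
    stop_validation("mobility TSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- lapply(split(df, df$label), function(d) {
    mobility_profile(d$x, d$rf_mean, d$rf_se, d$n_rep, label = d$label[1])
  })
  out[unique(df$label)]
}

#' @rdname read_mobility_tsv
#' @export
write_mobility_tsv <- function(profile, path) {
  profiles <- if (inherits(profile, "mobility_profile")) list(profile) else profile
  df <- do.call(rbind, lapply(profiles, function(p) {
    cbind(label = p$label, p$points)
  }))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Deterministic initialization: K0 from the mobilities at the two most extreme
# placements, theta0 by inverting the midpoint value, clamped to [0, 179].
bend_start <- function(pts) {
  ext <- order(abs(pts$x - 0.5), decreasing = TRUE)[1:2]
  K0 <- mean(pts$rf_mean[ext])
  mid <- which.min(abs(pts$x - 0.5))
  c0 <- max(-1, min(1, 2 * pts$rf_mean[mid] / K0 - 1))
  theta0 <- max(0, min(179, acos(c0) * 180 / pi))
  # keep the start strictly off the theta = 0 boundary, where the Jacobian
  # column for theta vanishes and damped least squares cannot take a step
  c(K = K0, theta = max(theta0, 0.5))
}

#' Fit the bend model to a mobility profile
#'
#' Weighted (1/SE^2) Levenberg-Marquardt least squares of
#' `R_f = K * [1 - 2 x (1 - x) (1 - cos theta)]`. If any SE is zero the fit
#' is unweighted. Initialization is deterministic: K0 is the mean mobility at
#' the two most extreme placements and theta0 inverts the near-midpoint value.
#' Confidence limits are linearized (delta-method) 95% intervals.
#'
#' A profile should span both near-central (|x - 0.5| < 0.15) and near-terminal
#' (|x - 0.5| > 0.3) placements for (K, theta) to be well identified; a profile
#' failing this raises a warning and the fit is still attempted.
#'
#' @param profile A [mobility_profile()].
#' @return An object of class `bend_fit` with elements `K`, `theta` (degrees),
#'   `covariance` (2x2), `rss` (weighted if the fit is weighted), `df`
#'   (n - 2), `ci95` (2x2 matrix), `weighted`, `label`.
#' @examples
#' x <- seq(0.05, 0.95, length.out = 11)
#' p <- mobility_profile(x, predict_rf(x, 0.95, 50), label = "noise-free")
#' fit_profile(p)
#' @export
fit_profile <- function(profile) {
  if (!inherits(profile, "mobility_profile")) {
    stop_validation("profile must be a mobility_profile")
  }
  pts <- profile$points
  if (nrow(pts) < 4) stop_validation("at least 4 points are required")
  if (!any(abs(pts$x - 0.5) < 0.15) || !any(abs(pts$x - 0.5) > 0.3)) {
    warning("profile spans a narrow x range; (K, theta) may be poorly identified")
  }
  weighted <- all(pts$rf_se > 0)
  w <- if (weighted) 1 / pts$rf_se^2 else rep(1, nrow(pts))
  sw <- sqrt(w)
  resid_fn <- function(par) {
    sw * (pts$rf_mean -
            par[1] * (1 - 2 * pts$x * (1 - pts$x) * (1 - cospi(par[2] / 180))))
  }
  jac_fn <- function(par) -sw * rf_gradient(pts$x, par[1], par[2])
  start <- bend_start(pts)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      par = start, fn = resid_fn, jac = jac_fn,
      lower = c(K = 1e-8, theta = 0), upper = c(K = Inf, theta = 179.999),
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-15,
                                           ptol = 1e-15)
    ),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$info %in% 1:4) {
    stop(errorCondition(
      paste0("bend-model fit failed for '", profile$label, "': ",
             if (is.null(fit)) "optimizer error" else fit$message,
             " (start K=", signif(start[1], 4),
             ", theta=", signif(start[2], 4), ")"),
      class = c("etsdyn_fit_error", "error")
    ))
  }
  est <- fit$par
  res <- pts$rf_mean - predict_rf(pts$x, est["K"], est["theta"])
  rss <- sum(w * res^2)
  dof <- nrow(pts) - 2L
  # linearized covariance sigma^2 (J' J)^-1 with sigma^2 = weighted RSS / df;
  # singular at the theta = 0 boundary, reported as NA there
  J <- jac_fn(est)
  covm <- tryCatch(solve(crossprod(J)) * rss / dof, error = function(e) {
    matrix(NA_real_, 2, 2)
  })
  dimnames(covm) <- list(c("K", "theta"), c("K", "theta"))
  se <- sqrt(diag(covm))
  tq <- stats::qt(0.975, dof)
  ci95 <- cbind(lower = est - tq * se, upper = est + tq * se)
  structure(
    list(K = unname(est["K"]), theta = unname(est["theta"]),
         covariance = covm, rss = rss, df = dof, ci95 = ci95,
         weighted = weighted, label = profile$label, n_points = nrow(pts)),
    class = "bend_fit"
  )
}

#' @export
print.bend_fit <- function(x, ...) {
  cat(sprintf("<bend_fit> %s\n", x$label))
  cat(sprintf("  K     = %.4f [%.4f, %.4f]\n", x$K, x$ci95["K", 1], x$ci95["K", 2]))
  cat(sprintf("  theta = %.2f deg (deflection from linearity) [%.2f, %.2f]\n",
              x$theta, x$ci95["theta", 1], x$ci95["theta", 2]))
  cat(sprintf("  RSS %.4g on %d df (%s)\n", x$rss, x$df,
              if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

#' Non-bend factor read off the fragment ends
#'
#' The model forces `R_f(0) = R_f(1) = K` for any bend angle, so the fitted
#' end value is a direct assessment of non-bend-related (charge/friction)
#' effects, uncontaminated by theta. This accessor makes that reading explicit;
#' algebraically it equals the fitted `K`.
#'
#' @param fit A `bend_fit`.
#' @return The end-point mobility (equals `fit$K`).
#' @export
k_from_ends <- function(fit) {
  if (!inherits(fit, "bend_fit")) stop_validation("fit must be a bend_fit")
  predict_rf(0, fit$K, fit$theta)
}

# Gradient of predict_rf wrt (K, theta in degrees) at fixed x.
rf_gradient <- function(x, K, theta) {
  th <- theta * pi / 180
  cbind(
    K = 1 - 2 * x * (1 - x) * (1 - cos(th)),
    theta = -K * 2 * x * (1 - x) * sin(th) * pi / 180
  )
}

#' Delta-method 95% confidence band for a fitted bend model
#'
#' Pointwise band `predict_rf +/- t(0.975, df) * sqrt(g' C g)` where `g` is the
#' parameter gradient and `C` the fit covariance. At x = 0 and x = 1 the theta
#' gradient vanishes, so the band width there reflects var(K) alone.
#'
#' @param fit A `bend_fit` with finite covariance.
#' @param x_grid Flexure displacements at which to evaluate the band.
#' @return Data frame with columns `x`, `fit`, `lower`, `upper`.
#' @export
confidence_band <- function(fit, x_grid = seq(0, 1, by = 0.01)) {
  if (!inherits(fit, "bend_fit")) stop_validation("fit must be a bend_fit")
  C <- fit$covariance
  if (any(!is.finite(C))) {
    stop(errorCondition("fit covariance is singular or undefined; no band available",
                        class = c("etsdyn_fit_error", "error")))
  }
  g <- rf_gradient(x_grid, fit$K, fit$theta)
  v <- rowSums((g %*% C) * g)
  v[v < 0] <- 0
  half <- stats::qt(0.975, fit$df) * sqrt(v)
  pred <- predict_rf(x_grid, fit$K, fit$theta)
  data.frame(x = x_grid, fit = pred, lower = pred - half, upper = pred + half)
}

#' Nested-model F test: do two complexes share one (K, theta)?
#'
#' Fits the two profiles separately (4 parameters) and globally with a shared
#' (K, theta) pair (2 parameters), and compares residual sums of squares with
#' Fisher's F test:
#' `F = [(RSS_global - RSS_separate)/2] / [RSS_separate/df_separate]`,
#' `p` from the upper tail of F(2, df_separate). The two x grids need not
#' match.
#'
#' By default the RSS values entering the F ratio come from unweighted fits:
#' the assay's measurement error is homoscedastic (replicate SEs are ±0.005 or
#' better at every position), and per-point weights estimated from
#' quadruplicates carry only 3 degrees of freedom each, which inflates the
#' size of an RSS-ratio test well above its nominal level. Set
#' `weighted = TRUE` to weight by 1/SE^2 when the per-point variances are
#' well determined.
#'
#' @param a,b [mobility_profile()] objects.
#' @param alpha Significance level for the verdict. Default 0.05.
#' @param weighted Use 1/SE^2 weights in the compared fits. Default `FALSE`.
#' @return An object of class `bend_comparison` with the two separate fits,
#'   the global fit, `rss_global`, `rss_separate`, `df_separate`, `f_stat`,
#'   `p_value` and `verdict` (`"distinguishable"` / `"indistinguishable"`).
#' @export
compare_profiles <- function(a, b, alpha = 0.05, weighted = FALSE) {
  if (!inherits(a, "mobility_profile") || !inherits(b, "mobility_profile")) {
    stop_validation("a and b must be mobility_profile objects")
  }
  if (nrow(a$points) == 0 || nrow(b$points) == 0) {
    stop_validation("profiles must be non-empty")
  }
  check_number(alpha, "alpha", lower = 0, upper = 1, strict_lower = TRUE)
  if (!weighted) {
    unweight <- function(p) {
      mobility_profile(p$points$x, p$points$rf_mean, 0, p$points$n_rep, p$label)
    }
    a <- unweight(a)
    b <- unweight(b)
  }
  fit_a <- fit_profile(a)
  fit_b <- fit_profile(b)
  pooled <- mobility_profile(
    c(a$points$x, b$points$x),
    c(a$points$rf_mean, b$points$rf_mean),
    c(a$points$rf_se, b$points$rf_se),
    c(a$points$n_rep, b$points$n_rep),
    label = paste0(a$label, " + ", b$label, " (global)")
  )
  fit_g <- suppressWarnings(fit_profile(pooled))
  rss_sep <- fit_a$rss + fit_b$rss
  df_sep <- fit_a$df + fit_b$df
  rss_glob <- fit_g$rss
  f_stat <- max(0, ((rss_glob - rss_sep) / 2) / (rss_sep / df_sep))
  p <- stats::pf(f_stat, 2, df_sep, lower.tail = FALSE)
  structure(
    list(fit_a = fit_a, fit_b = fit_b, fit_global = fit_g,
         rss_global = rss_glob, rss_separate = rss_sep,
         df_global = fit_g$df, df_separate = df_sep,
         f_stat = f_stat, p_value = p, alpha = alpha,
         verdict = if (p < alpha) "distinguishable" else "indistinguishable"),
    class = "bend_comparison"
  )
}

#' @export
print.bend_comparison <- function(x, ...) {
  cat(sprintf("<bend_comparison> %s vs %s\n", x$fit_a$label, x$fit_b$label))
  cat(sprintf("  F(2, %d) = %.4g, P = %s -> %s at alpha = %g\n",
              x$df_separate, x$f_stat, format_pvalue(x$p_value),
              x$verdict, x$alpha))
  invisible(x)
}

#' Plot a mobility profile with its fitted bend model
#'
#' Base-graphics plot of the data (mean +/- SE), the fitted curve and its 95%
#' delta-method band.
#'
#' @param x A `bend_fit`.
#' @param profile The [mobility_profile()] that was fitted.
#' @param ... Passed to [plot()].
#' @return Invisibly, the confidence-band data frame.
#' @export
plot.bend_fit <- function(x, profile = NULL, ...) {
  band <- tryCatch(confidence_band(x), error = function(e) NULL)
  grid <- seq(0, 1, by = 0.01)
  pred <- predict_rf(grid, x$K, x$theta)
  ylim <- range(pred, if (!is.null(profile)) profile$points$rf_mean)
  plot(grid, pred, type = "l", xlab = "Flexure displacement, x",
       ylab = expression(italic(R)[f]), ylim = ylim, main = x$label, ...)
  if (!is.null(band)) {
    graphics::lines(band$x, band$lower, lty = 3)
    graphics::lines(band$x, band$upper, lty = 3)
  }
  if (!is.null(profile)) {
    pts <- profile$points
    graphics::points(pts$x, pts$rf_mean, pch = 16)
    graphics::arrows(pts$x, pts$rf_mean - pts$rf_se, pts$x, pts$rf_mean + pts$rf_se,
                     angle = 90, code = 3, length = 0.02)
  }
  invisible(band)
}
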