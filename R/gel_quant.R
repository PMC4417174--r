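# Lane-trace quantitation and replicate statistics for circular-permutation
# gels: band detection by intensity-weighted centroids, relative mobility as a
# bound/unbound migration ratio, and per-position Welch t tests with
# Benjamini-Hochberg FDR control.

#' Assemble a gel lane intensity trace
#'
#' @param positions Migration coordinate, arbitrary units, strictly increasing.
#' @param intensities Non-negative signal, same length.
#' @param label Fragment label.
#' @param role `"bound"` or `"unbound"`.
#' @return An object of class `lane_trace`.
#' @export
lane_trace <- function(positions, intensities, label = "", role = c("bound", "unbound")) {
  role <- match.arg(role)
  if (length(positions) != length(intensities)) {
    stop_validation("positions and intensities must have equal length")
  }
  if (any(diff(positions) <= 0)) stop_validation("positions must be strictly increasing")
  if (any(intensities < 0)) stop_validation("intensities must be non-negative")
  structure(list(positions = positions, intensities = intensities,
                 label = label, role = role),
            class = "lane_trace")
}

#' Locate bands in a lane trace
#'
#' Detects local maxima above a noise floor (default: baseline + 3 x the
#' median absolute deviation, baseline = trace median), splits the trace into
#' band regions at the local minima between qualifying maxima, and returns the
#' intensity-weighted centroid and area of each region (baseline-subtracted).
#'
#' @param trace A [lane_trace()].
#' @param mad_mult Multiplier on the MAD for the noise floor. Default 3.
#' @return Data frame with columns `center`, `area`, `lo`, `hi` (region
#'   bounds), ordered by migration position.
#' @export
locate_bands <- function(trace, mad_mult = 3) {
  pos <- trace$positions
  int <- trace$intensities
  baseline <- stats::median(int)
  floor_ <- baseline + mad_mult * stats::mad(int)
  n <- length(int)
  is_max <- int > floor_ &
    int >= c(-Inf, int[-n]) & int >= c(int[-1], -Inf)
  peaks <- which(is_max)
  # collapse plateaus
  if (length(peaks) > 1) peaks <- peaks[c(TRUE, diff(peaks) > 1)]
  if (length(peaks) == 0) {
    stop(errorCondition("no band detected above the noise floor",
                        class = c("etsdyn_detection_error", "error")))
  }
  # region boundaries: local minimum between adjacent peaks, trace ends outside
  cuts <- integer(0)
  if (length(peaks) > 1) {
    cuts <- vapply(seq_len(length(peaks) - 1), function(i) {
      seg <- peaks[i]:peaks[i + 1]
      seg[which.min(int[seg])]
    }, integer(1))
  }
  bounds <- c(1L, cuts, n)
  sub <- pmax(int - baseline, 0)
  out <- do.call(rbind, lapply(seq_along(peaks), function(i) {
    idx <- bounds[i]:bounds[i + 1]
    w <- sub[idx]
    data.frame(center = sum(pos[idx] * w) / sum(w),
               area = pracma::trapz(pos[idx], w),
               lo = pos[bounds[i]], hi = pos[bounds[i + 1]])
  }))
  out[order(out$center), , drop = FALSE]
}

#' Relative mobility from a bound/unbound lane pair
#'
#' The primary (largest-area) band is located in each lane;
#' `rf = migration(bound) / migration(unbound)`. Larger rf means the complex
#' migrates faster. rf is invariant to uniform intensity rescaling of either
#' lane and to common shifts of the migration axis applied to both.
#'
#' @param bound,unbound [lane_trace()] objects.
#' @param mad_mult Passed to [locate_bands()].
#' @return An object of class `rel_mobility` with elements `rf`,
#'   `bound_center`, `unbound_center`.
#' @export
relative_mobility <- function(bound, unbound, mad_mult = 3) {
  bb <- locate_bands(bound, mad_mult)
  ub <- locate_bands(unbound, mad_mult)
  bc <- bb$center[which.max(bb$area)]
  uc <- ub$center[which.max(ub$area)]
  structure(list(rf = bc / uc, bound_center = bc, unbound_center = uc,
                 label = bound$label),
            class = "rel_mobility")
}

#' Welch's t test from summary statistics
#'
#' Unequal-variance t test assembled from means, standard errors of the means,
#' and replicate counts (the form in which quadruplicate gel mobilities are
#' reported): `t = (m1 - m2) / sqrt(se1^2 + se2^2)` with Welch-Satterthwaite
#' degrees of freedom and a two-sided p-value.
#'
#' Degenerate inputs: if both SEs are zero and the means are equal, `t = 0`
#' and `p = 1`; if both SEs are zero and the means differ, `p = 0` with a
#' warning (the difference is exact).
#'
#' @param mean1,mean2 Group means.
#' @param se1,se2 Standard errors of the means (>= 0).
#' @param n1,n2 Replicate counts (>= 2).
#' @return List with `t`, `df`, `p`.
#' @examples
#' welch_t(0.80, 0.005, 4, 0.75, 0.005, 4)  # t = 7.071, df = 6
#' @export
welch_t <- function(mean1, se1, n1, mean2, se2, n2) {
  check_number(se1, "se1", lower = 0); check_number(se2, "se2", lower = 0)
  check_number(n1, "n1", lower = 2); check_number(n2, "n2", lower = 2)
  if (se1 == 0 && se2 == 0) {
    if (mean1 == mean2) return(list(t = 0, df = Inf, p = 1))
    warning("both SEs are zero with unequal means; reporting p = 0")
    return(list(t = sign(mean1 - mean2) * Inf, df = Inf, p = 0))
  }
  v <- se1^2 + se2^2
  t_stat <- (mean1 - mean2) / sqrt(v)
  df <- v^2 / (se1^4 / (n1 - 1) + se2^4 / (n2 - 1))
  p <- 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE)
  list(t = t_stat, df = df, p = p)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p-values, clipped at 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
adjust_fdr <- function(p_values) {
  if (length(p_values) == 0) return(numeric(0))
  if (any(!is.finite(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop_validation("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Per-position comparison of high- and low-affinity mobilities
#'
#' One Welch t test per flexure displacement between two profiles measured on
#' the same fragment series, with BH adjustment across positions. A position
#' is flagged significant when its adjusted p-value falls below `alpha`.
#'
#' @param high,low [mobility_profile()] objects on matching x grids.
#' @param alpha FDR level. Default 0.05.
#' @param tol Tolerance for matching x values. Default 1e-8.
#' @return A data frame of class `position_test_table` with columns `x`,
#'   `mean_high`, `mean_low`, `se_high`, `se_low`, `t_stat`, `df`, `p_raw`,
#'   `p_adjusted`, `significant`.
#' @export
position_tests <- function(high, low, alpha = 0.05, tol = 1e-8) {
  if (!inherits(high, "mobility_profile") || !inherits(low, "mobility_profile")) {
    stop_validation("high and low must be mobility_profile objects")
  }
  h <- high$points; l <- low$points
  if (nrow(h) != nrow(l) || any(abs(h$x - l$x) > tol)) {
    missing_h <- setdiff(round(l$x, 8), round(h$x, 8))
    missing_l <- setdiff(round(h$x, 8), round(l$x, 8))
    stop_validation(
      "x grids do not match; missing in high: {",
      paste(missing_h, collapse = ", "), "}, missing in low: {",
      paste(missing_l, collapse = ", "), "}")
  }
  tests <- Map(function(i) {
    welch_t(h$rf_mean[i], h$rf_se[i], h$n_rep[i],
            l$rf_mean[i], l$rf_se[i], l$n_rep[i])
  }, seq_len(nrow(h)))
  p_raw <- vapply(tests, `[[`, numeric(1), "p")
  p_adj <- adjust_fdr(p_raw)
  out <- data.frame(
    x = h$x, mean_high = h$rf_mean, mean_low = l$rf_mean,
    se_high = h$rf_se, se_low = l$rf_se,
    t_stat = vapply(tests, `[[`, numeric(1), "t"),
    df = vapply(tests, `[[`, numeric(1), "df"),
    p_raw = p_raw, p_adjusted = p_adj,
    significant = p_adj < alpha
  )
  class(out) <- c("position_test_table", "data.frame")
  attr(out, "alpha") <- alpha
  out
}

#' @export
print.position_test_table <- function(x, ...) {
  df <- as.data.frame(x)
  df$p_raw <- format_pvalue(df$p_raw)
  df$p_adjusted <- format_pvalue(df$p_adjusted)
  cat(sprintf("<position_test_table> %d positions, %d significant at FDR %g\n",
              nrow(df), sum(x$significant), attr(x, "alpha")))
  print(df, row.names = FALSE, digits = 4)
  invisible(x)
}
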