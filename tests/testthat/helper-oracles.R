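# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Squared end-to-end distance of a unit rod kinked by `theta_deg` at
# fractional position x, by explicit 2-D vector geometry.
kink_endtoend_sq <- function(x, theta_deg) {
  th <- theta_deg * pi / 180
  e <- x * c(1, 0) + (1 - x) * c(cos(th), sin(th))
  sum(e^2)
}

# Brute-force Benjamini-Hochberg: adjusted p_i = min over the tail (ranks >= i
# after sorting) of p * m / rank, clipped at 1, original order restored.
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  adj <- vapply(seq_len(m), function(i) {
    min(1, min(ps[i:m] * m / (i:m)))
  }, numeric(1))
  out <- numeric(m)
  out[ord] <- adj
  out
}

# Brute-force weighted RSS minimization of the kink model using the geometry
# oracle and stats::optim (independent of minpack.lm and of predict_rf).
oracle_rss <- function(par, x, y, w) {
  mu <- par[1] * vapply(x, kink_endtoend_sq, numeric(1), theta_deg = par[2])
  sum(w * (y - mu)^2)
}

oracle_fit <- function(x, y, w = rep(1, length(x)), start = c(0.9, 60)) {
  o1 <- stats::optim(start, oracle_rss, x = x, y = y, w = w,
                     method = "Nelder-Mead",
                     control = list(reltol = 1e-14, maxit = 5000))
  o2 <- stats::optim(o1$par, oracle_rss, x = x, y = y, w = w,
                     method = "BFGS", control = list(reltol = 1e-14))
  if (o2$value < o1$value) o2 else o1
}

# Analytic entropy route to positional information content.
brute_force_ic <- function(p) {
  h <- -sum(ifelse(p > 0, p * log2(p), 0))
  2 - h
}

# Make a noise-free mobility profile straight from the geometry oracle.
oracle_profile <- function(x, K, theta, label = "oracle") {
  y <- K * vapply(x, kink_endtoend_sq, numeric(1), theta_deg = theta)
  mobility_profile(x, y, 0, 1, label = label)
}
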