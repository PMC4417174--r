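# Seeded generators emulating every input the analyses consume: quadruplicate
# mobility profiles (Gaussian replicate noise, SE 0.005), gel lane traces,
# intensity-weighted log-normal size distributions, guanine-ladder
# electropherograms with core protection, and multinomial motif counts.
# Every generator is a pure function of (arguments, seed): the caller's RNG
# state is saved and restored.

#' Scenario specification for synthetic data generation
#'
#' Bundles every parameter the generators need. Defaults reproduce the study
#' conditions of a quadruplicate circular-permutation experiment: replicate
#' SE 0.005 on relative mobility, n = 4 replicates, an 11-fragment series of
#' 143-bp fragments carrying a 10-bp site.
#'
#' @param name Scenario name.
#' @param bend Named list `high`/`low`, each `c(K = , theta = )`.
#' @param rf_se Standard error of mean relative mobility. Default 0.005.
#' @param n_rep Replicates per fragment. Default 4.
#' @param dls Named list of `c(mu_g = , sigma_g = )` per species (e.g.
#'   `unbound`, `high`, `low`), plus `noise_cv` (multiplicative noise CV,
#'   default 0.05).
#' @param suppression Named numeric: core-guanine amplitude multipliers in the
#'   bound state, per affinity class.
#' @param pwm Optional [motif_matrix()] used for motif-count generation.
#' @param kd Named list `c(sp = , ns = )` dissociation constants (M) per
#'   protein for discrimination energetics.
#' @param sites Named list of [binding_site()] objects (`high`, `low`).
#' @param seed Integer seed; mandatory for any stochastic generation.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(name,
                          bend = list(high = c(K = 0.92, theta = 63),
                                      low = c(K = 0.85, theta = 55)),
                          rf_se = 0.005, n_rep = 4L,
                          dls = list(unbound = c(mu_g = 4.2, sigma_g = 1.40),
                                     high = c(mu_g = 4.0, sigma_g = 1.25),
                                     low = c(mu_g = 4.6, sigma_g = 1.50),
                                     noise_cv = 0.05),
                          suppression = c(high = 0.1, low = 0.5),
                          pwm = NULL, kd = NULL,
                          sites = list(high = binding_site("AGCGGAAGTG", "high site", "high"),
                                       low = binding_site("AAAGGAATGG", "low site", "low")),
                          seed = 1L) {
  check_number(rf_se, "rf_se", lower = 0)
  check_number(n_rep, "n_rep", lower = 1)
  check_number(seed, "seed")
  for (cx in names(bend)) {
    predict_rf(0.5, bend[[cx]]["K"], bend[[cx]]["theta"])  # range validation
  }
  structure(
    list(name = name, bend = bend, rf_se = rf_se, n_rep = as.integer(n_rep),
         dls = dls, suppression = suppression, pwm = pwm, kd = kd,
         sites = sites, seed = as.integer(seed)),
    class = "scenario_spec"
  )
}

#' Built-in scenarios
#'
#' Three qualitative scenarios mirroring the contrast between the ETS domains:
#'
#' * `scenario_pu1_like()`: high- and low-affinity complexes differ in both K
#'   and theta. The defaults (K 0.92 vs 0.85; theta 63 deg vs ~55 deg) are
#'   chosen so the two mobility curves coincide at x = 0.5: differences are
#'   maximal for terminal sites and vanish for centered sites. Nonspecific
#'   binding is weak (Kd_ns = 1e-5 M).
#' * `scenario_ets1_minimal_like()`: a minimal ETS domain; high and low
#'   complexes share one (K, theta), tight size distribution, stronger
#'   nonspecific binding (Kd_ns = 1e-7 M).
#' * `scenario_ets1_autoinhibited_like()`: as the minimal domain but with a
#'   larger hydrodynamic diameter (autoinhibitory flanking helices) and
#'   right-shifted, broadened distributions upon DNA binding.
#'
#' Parameter values are qualitative stand-ins that reproduce the observed
#' patterns, not measured estimates.
#'
#' @param seed Integer seed.
#' @return A [scenario_spec()].
#' @export
scenario_pu1_like <- function(seed = 1L) {
  K_h <- 0.92; th_h <- 63; K_l <- 0.85
  # theta_low chosen so both curves coincide exactly at x = 0.5
  th_l <- acos(K_h * (1 + cospi(th_h / 180)) / K_l - 1) * 180 / pi
  scenario_spec(
    name = "PU.1-like",
    bend = list(high = c(K = K_h, theta = th_h), low = c(K = K_l, theta = th_l)),
    dls = list(unbound = c(mu_g = 4.2, sigma_g = 1.40),
               high = c(mu_g = 4.0, sigma_g = 1.25),
               low = c(mu_g = 4.6, sigma_g = 1.50),
               noise_cv = 0.05),
    suppression = c(high = 0.1, low = 0.5),
    kd = list(A = c(sp = 1e-10, ns = 1e-5), B = c(sp = 1e-10, ns = 1e-7)),
    seed = seed
  )
}

#' @rdname scenario_pu1_like
#' @export
scenario_ets1_minimal_like <- function(seed = 1L) {
  scenario_spec(
    name = "Ets-1-minimal-like",
    bend = list(high = c(K = 0.90, theta = 60), low = c(K = 0.90, theta = 60)),
    dls = list(unbound = c(mu_g = 4.2, sigma_g = 1.15),
               high = c(mu_g = 4.1, sigma_g = 1.14),
               low = c(mu_g = 4.4, sigma_g = 1.18),
               noise_cv = 0.05),
    suppression = c(high = 0.1, low = 0.35),
    kd = list(A = c(sp = 1e-10, ns = 1e-7), B = c(sp = 1e-10, ns = 1e-7)),
    sites = list(high = binding_site("GCCGGAAGTG", "SC1", "high"),
                 low = binding_site("TCCGGAAACC", "SC12", "low")),
    seed = seed
  )
}

#' @rdname scenario_pu1_like
#' @export
scenario_ets1_autoinhibited_like <- function(seed = 1L) {
  scenario_spec(
    name = "Ets-1-autoinhibited-like",
    bend = list(high = c(K = 0.88, theta = 55), low = c(K = 0.88, theta = 55)),
    dls = list(unbound = c(mu_g = 4.8, sigma_g = 1.15),
               high = c(mu_g = 5.2, sigma_g = 1.30),
               low = c(mu_g = 5.3, sigma_g = 1.32),
               noise_cv = 0.05),
    suppression = c(high = 0.25, low = 0.4),
    kd = list(A = c(sp = 1e-10, ns = 1e-7), B = c(sp = 1e-10, ns = 1e-7)),
    sites = list(high = binding_site("GCCGGAAGTG", "SC1", "high"),
                 low = binding_site("TCCGGAAACC", "SC12", "low")),
    seed = seed
  )
}

#' Generate high/low mobility profiles for a scenario
#'
#' For each complex, relative mobilities at the series' flexure displacements
#' are drawn as `n_rep` replicates around the bend-model prediction with
#' per-replicate Gaussian SD `rf_se * sqrt(n_rep)` (so the mean has SD
#' `rf_se`); profile means and SEs are computed from the replicates.
#'
#' @param spec A [scenario_spec()].
#' @param series A [make_series()] result. Default: 11 x 143 bp, 10-bp site.
#' @param seed Seed; defaults to `spec$seed`.
#' @return Named list of [mobility_profile()] objects (`high`, `low`).
#' @export
gen_mobility_profiles <- function(spec, series = make_series(), seed = spec$seed) {
  x <- flexure_displacement(series)
  with_local_seed(seed, {
    out <- lapply(names(spec$bend), function(cx) {
      par <- spec$bend[[cx]]
      mu <- predict_rf(x, par[["K"]], par[["theta"]])
      reps <- matrix(
        stats::rnorm(length(x) * spec$n_rep, mean = rep(mu, each = spec$n_rep),
                     sd = spec$rf_se * sqrt(spec$n_rep)),
        nrow = spec$n_rep
      )
      if (spec$rf_se > 0) {
        se <- apply(reps, 2, stats::sd) / sqrt(spec$n_rep)
        m <- colMeans(reps)
      } else {
        se <- rep(0, length(x)); m <- mu
      }
      mobility_profile(x, m, se, spec$n_rep,
                       label = paste0(spec$name, " ", cx, "-affinity"))
    })
    names(out) <- names(spec$bend)
    out
  })
}

#' Generate a bound/unbound gel lane pair per fragment
#'
#' Gaussian bands on a migration grid: the unbound band at a fixed position,
#' the bound band at `unbound_pos * rf`. Band amplitude and width are
#' configurable; amplitudes do not affect recovered mobilities.
#'
#' @param profile A [mobility_profile()].
#' @param unbound_pos Migration position of the unbound band. Default 50.
#' @param band_sd Band SD in migration units. Default 1.2.
#' @param amplitude Peak amplitude. Default 100.
#' @param grid_step Migration grid spacing. Default 0.05.
#' @param noise_sd Additive Gaussian noise SD. Default 0.
#' @param seed Seed used when `noise_sd > 0`.
#' @return List (one element per fragment) of lists with `bound` and
#'   `unbound` [lane_trace()] objects.
#' @export
gen_gel_lanes <- function(profile, unbound_pos = 50, band_sd = 1.2,
                          amplitude = 100, grid_step = 0.05, noise_sd = 0,
                          seed = 1L) {
  grid <- seq(0, unbound_pos * 1.4, by = grid_step)
  with_local_seed(seed, {
    lapply(seq_len(nrow(profile$points)), function(i) {
      rf <- profile$points$rf_mean[i]
      mk <- function(center, role) {
        sig <- amplitude * exp(-(grid - center)^2 / (2 * band_sd^2))
        if (noise_sd > 0) sig <- pmax(sig + stats::rnorm(length(grid), 0, noise_sd), 0)
        lane_trace(grid, sig, label = sprintf("x=%.3f", profile$points$x[i]),
                   role = role)
      }
      list(bound = mk(unbound_pos * rf, "bound"),
           unbound = mk(unbound_pos, "unbound"))
    })
  })
}

#' Generate an intensity-weighted size distribution
#'
#' A log-normal curve `A * dlnorm(D_H; log mu_g, log sigma_g)` on a log-spaced
#' diameter grid, with multiplicative log-normal noise of coefficient of
#' variation `noise_cv`. Zero noise round-trips exactly through
#' [fit_lognormal()].
#'
#' @param mu_g Geometric mean diameter, nm (> 0).
#' @param sigma_g Geometric SD (>= 1).
#' @param noise_cv Multiplicative noise CV. Default 0.05.
#' @param n_grid Grid points. Default 80.
#' @param amplitude Scale factor. Default 100.
#' @param seed Seed.
#' @return A [size_distribution()].
#' @export
gen_dls <- function(mu_g, sigma_g, noise_cv = 0.05, n_grid = 80,
                    amplitude = 100, seed = 1L) {
  check_number(mu_g, "mu_g", lower = 0, strict_lower = TRUE)
  check_number(sigma_g, "sigma_g", lower = 1)
  span <- max(sigma_g, 1.0001)^4
  grid <- exp(seq(log(mu_g / span), log(mu_g * span), length.out = n_grid))
  w <- amplitude * stats::dlnorm(grid, log(mu_g), log(max(sigma_g, 1.0001)))
  with_local_seed(seed, {
    if (noise_cv > 0) w <- w * exp(stats::rnorm(n_grid, 0, noise_cv))
    size_distribution(grid, w)
  })
}

#' Generate a guanine-ladder electropherogram with an index map
#'
#' One Gaussian peak per guanine of the supplied 5'-GGAA-3'-strand sequence
#' window (DMS mode), or one peak per base (DNase mode). In the bound state
#' the two core-consensus guanines are multiplied by `suppression`
#' (protection); in DNase mode, bases of the 5'-TTCC-3' complement window are
#' multiplied by `enhancement` (hypersensitivity). The control peak is the
#' guanine farthest from the site. Peaks sit 20 scan points apart with SD 3;
#' integration windows of +/- 8 scans are disjoint.
#'
#' @param sequence_window DNA sequence (sense strand) containing the 10-bp
#'   site; must contain a GGAA or GGAT core and at least one guanine outside
#'   the site.
#' @param site_start 1-based start of the 10-bp site within the window.
#' @param bound Logical: is the protein bound?
#' @param mode `"dms"` (guanine peaks) or `"dnase"` (all-base peaks).
#' @param suppression Core-guanine amplitude multiplier when bound. Default 0.1.
#' @param enhancement DNase amplitude multiplier over the TTCC window when
#'   bound. Default 3.
#' @param amplitude Base peak amplitude. Default 100.
#' @param noise_sd Additive Gaussian noise SD. Default 0.
#' @param seed Seed.
#' @return List with `trace` (an [electropherogram()]), `index_map` (data
#'   frame), and `core_indices` (window positions of the two core guanines).
#' @export
gen_electropherogram <- function(sequence_window, site_start, bound = FALSE,
                                 mode = c("dms", "dnase"), suppression = 0.1,
                                 enhancement = 3, amplitude = 100,
                                 noise_sd = 0, seed = 1L) {
  mode <- match.arg(mode)
  seq_up <- toupper(sequence_window)
  bases <- strsplit(seq_up, "")[[1]]
  site_end <- site_start + 9
  if (site_start < 1 || site_end > length(bases)) {
    stop_validation("10-bp site must lie within the sequence window")
  }
  site_seq <- substr(seq_up, site_start, site_end)
  core_rel <- regexpr("GGAA|GGAT", site_seq)
  if (core_rel < 0) stop_validation("site lacks a GGA(A/T) core")
  core_abs <- site_start + core_rel - 1
  core_indices <- c(core_abs, core_abs + 1)            # the two core guanines
  ttcc_window <- (core_abs):(core_abs + 3)             # TTCC on the other strand
  peak_bases <- if (mode == "dms") which(bases == "G") else seq_along(bases)
  if (!any(peak_bases < site_start | peak_bases > site_end)) {
    stop_validation("no peak outside the site available as a control")
  }
  outside <- peak_bases[peak_bases < site_start | peak_bases > site_end]
  site_center <- (site_start + site_end) / 2
  control <- outside[which.max(abs(outside - site_center))]
  centers <- 20 * peak_bases
  amps <- rep(amplitude, length(peak_bases))
  if (bound) {
    if (mode == "dms") {
      amps[peak_bases %in% core_indices] <- amplitude * suppression
    } else {
      amps[peak_bases %in% ttcc_window] <- amplitude * enhancement
    }
  }
  scan <- seq(0, 20 * (length(bases) + 1), by = 1)
  signal <- rep(0, length(scan))
  for (i in seq_along(centers)) {
    signal <- signal + amps[i] * exp(-(scan - centers[i])^2 / (2 * 3^2))
  }
  with_local_seed(seed, {
    if (noise_sd > 0) signal <- pmax(signal + stats::rnorm(length(scan), 0, noise_sd), 0)
    trace <- electropherogram(scan, signal,
                              sample = if (bound) "bound" else "unbound")
    index_map <- data.frame(base_index = peak_bases,
                            window_start = centers - 8, window_end = centers + 8,
                            is_control = peak_bases == control)
    list(trace = trace, index_map = index_map, core_indices = core_indices)
  })
}

#' Sample motif counts from a probability matrix
#'
#' Draws `n_sites` aligned sites per position by a multinomial on the column
#' probabilities; counts normalize back toward the generating matrix as
#' `n_sites` grows.
#'
#' @param pwm A [motif_matrix()].
#' @param n_sites Number of sites (>= 1).
#' @param seed Seed.
#' @return A [motif_matrix()] carrying counts.
#' @export
gen_motif_counts <- function(pwm, n_sites, seed = 1L) {
  check_number(n_sites, "n_sites", lower = 1)
  with_local_seed(seed, {
    counts <- apply(pwm$probs, 2, function(p) stats::rmultinom(1, n_sites, p))
    motif_matrix(counts = counts,
                 source = sprintf("sampled n=%d from %s", n_sites, pwm$source))
  })
}
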