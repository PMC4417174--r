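# Orchestration: write a scenario's input files to a directory, run each
# analysis over them, and emit machine-readable reports. Report files have a
# deterministic `payload` (byte-identical across runs at a fixed seed) and a
# separate `meta` field carrying provenance (package version, seed, input
# hashes, timestamp).

report_meta <- function(inputs, seed) {
  hashes <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(package = "etsdyn",
       version = as.character(utils::packageVersion("etsdyn")),
       seed = seed,
       input_md5 = hashes,
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
}

write_report_json <- function(payload, meta, path) {
  jsonlite::write_json(list(payload = payload, meta = meta), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

bend_fit_payload <- function(fit) {
  list(label = fit$label, K = fit$K, theta_deg = fit$theta,
       theta_convention = "deflection from linearity (180 deg - included angle)",
       ci95 = list(K = unname(fit$ci95["K", ]), theta = unname(fit$ci95["theta", ])),
       rss = fit$rss, df = fit$df, weighted = fit$weighted)
}

#' Write all synthetic input files for a scenario
#'
#' Emits, under `dir`: mobility tables (`mobility.tsv`), the series definition
#' (`series.tsv`), size-distribution CSVs (`dls_<species>.csv`), DMS
#' electropherograms for unbound/high/low plus a DNase pair
#' (`fp_*.csv`, `fp_index_map.tsv`, `fp_core.txt`), motif count files
#' (`motif_a.jaspar`, `motif_b.jaspar`), binding constants
#' (`binding_constants.csv`), and the scenario parameters (`scenario.json`).
#'
#' @param spec A [scenario_spec()].
#' @param dir Output directory (created if needed).
#' @param series Fragment series. Default [make_series()].
#' @return `dir`, invisibly.
#' @export
generate_scenario <- function(spec, dir, series = make_series()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_series_tsv(series, p("series.tsv"))
  prof <- gen_mobility_profiles(spec, series)
  write_mobility_tsv(prof, p("mobility.tsv"))
  dls_species <- setdiff(names(spec$dls), "noise_cv")
  for (i in seq_along(dls_species)) {
    sp <- dls_species[i]
    par <- spec$dls[[sp]]
    write_dls_csv(
      gen_dls(par[["mu_g"]], par[["sigma_g"]], spec$dls$noise_cv,
              seed = spec$seed + i),
      p(sprintf("dls_%s.csv", sp)))
  }
  # footprints on the high-affinity site in a window with flanking guanines
  window <- paste0("ATTGACGTCA", spec$sites$high$sequence, "CATGACGTCA")
  site_start <- 11
  fp_un <- gen_electropherogram(window, site_start, bound = FALSE, seed = spec$seed)
  write_trace_csv(fp_un$trace, p("fp_dms_unbound.csv"))
  for (cx in names(spec$suppression)) {
    fp_b <- gen_electropherogram(window, site_start, bound = TRUE,
                                 suppression = spec$suppression[[cx]],
                                 seed = spec$seed + match(cx, names(spec$suppression)))
    write_trace_csv(fp_b$trace, p(sprintf("fp_dms_bound_%s.csv", cx)))
  }
  write_index_map(fp_un$index_map, p("fp_index_map.tsv"))
  writeLines(as.character(fp_un$core_indices), p("fp_core.txt"))
  dn_un <- gen_electropherogram(window, site_start, bound = FALSE, mode = "dnase",
                                seed = spec$seed)
  dn_b <- gen_electropherogram(window, site_start, bound = TRUE, mode = "dnase",
                               seed = spec$seed + 1)
  write_trace_csv(dn_un$trace, p("fp_dnase_unbound.csv"))
  write_trace_csv(dn_b$trace, p("fp_dnase_bound.csv"))
  write_index_map(dn_un$index_map, p("fp_dnase_index_map.tsv"))
  if (is.null(spec$pwm)) {
    # sharp vs degenerate stand-in motifs around the shared GGAA core
    sharp <- diag(4)[, c(1, 1, 3, 3, 1, 1, 2, 4, 2, 3)]
    soft <- 0.7 * sharp + 0.3 * 0.25
    pwm_a <- motif_matrix(sharp, source = "synthetic A")
    pwm_b <- motif_matrix(soft, source = "synthetic B")
  } else {
    pwm_a <- pwm_b <- spec$pwm
  }
  write_motif(gen_motif_counts(pwm_a, 1000, seed = spec$seed), p("motif_a.jaspar"))
  write_motif(gen_motif_counts(pwm_b, 1000, seed = spec$seed + 1), p("motif_b.jaspar"))
  if (!is.null(spec$kd)) {
    utils::write.csv(
      data.frame(protein = names(spec$kd),
                 kd_specific_M = vapply(spec$kd, `[[`, numeric(1), "sp"),
                 kd_nonspecific_M = vapply(spec$kd, `[[`, numeric(1), "ns")),
      p("binding_constants.csv"), row.names = FALSE)
  }
  jsonlite::write_json(
    list(name = spec$name, seed = spec$seed, rf_se = spec$rf_se,
         n_rep = spec$n_rep, bend = spec$bend,
         suppression = as.list(spec$suppression)),
    p("scenario.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

require_inputs <- function(dir, files) {
  paths <- file.path(dir, files)
  missing <- files[!file.exists(paths)]
  if (length(missing)) {
    stop_validation("missing input file(s) in ", dir, ": ",
                    paste(missing, collapse = ", "))
  }
  paths
}

#' Run the bend-model analysis over a scenario directory
#'
#' Reads `mobility.tsv`, fits each profile, compares the first two (high vs
#' low), runs per-position Welch/FDR tests, and writes `bend_report.json`
#' plus `position_tests.tsv` under `out_dir`.
#'
#' @param dir Input directory (see [generate_scenario()]).
#' @param out_dir Output directory. Default `dir`.
#' @param alpha Significance level. Default 0.05.
#' @param seed Seed recorded in provenance. Default `NA`.
#' @return List with `fits`, `comparison`, `position_tests`, invisibly.
#' @export
run_bend <- function(dir, out_dir = dir, alpha = 0.05, seed = NA) {
  paths <- require_inputs(dir, "mobility.tsv")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  profiles <- read_mobility_tsv(paths[1])
  if (length(profiles) < 2) stop_validation("mobility.tsv must contain two profiles")
  fits <- lapply(profiles, fit_profile)
  cmp <- compare_profiles(profiles[[1]], profiles[[2]], alpha = alpha)
  pt <- position_tests(profiles[[1]], profiles[[2]], alpha = alpha)
  payload <- list(
    fits = lapply(fits, bend_fit_payload),
    comparison = list(
      f_stat = cmp$f_stat, df = c(2, cmp$df_separate),
      p_value = cmp$p_value, p_printed = format_pvalue(cmp$p_value),
      rss_global = cmp$rss_global, rss_separate = cmp$rss_separate,
      alpha = alpha, verdict = cmp$verdict),
    n_significant_positions = sum(pt$significant)
  )
  write_report_json(payload, report_meta(paths, seed),
                    file.path(out_dir, "bend_report.json"))
  df <- as.data.frame(pt)
  df$p_printed <- format_pvalue(df$p_adjusted)
  utils::write.table(df, file.path(out_dir, "position_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(fits = fits, comparison = cmp, position_tests = pt))
}

#' Run the DLS analysis over a scenario directory
#'
#' Fits every `dls_*.csv`, compares each bound species against `dls_unbound`
#' when present, and writes `dls_report.json`.
#'
#' @inheritParams run_bend
#' @return List with `fits` and `shifts`, invisibly.
#' @export
run_dls <- function(dir, out_dir = dir, seed = NA) {
  files <- list.files(dir, pattern = "^dls_.*\\.csv$", full.names = TRUE)
  if (length(files) == 0) stop_validation("no dls_*.csv inputs in ", dir)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  species <- sub("^dls_(.*)\\.csv$", "\\1", basename(files))
  fits <- lapply(files, function(f) fit_lognormal(read_dls_csv(f)))
  names(fits) <- species
  shifts <- NULL
  if ("unbound" %in% species) {
    others <- setdiff(species, "unbound")
    shifts <- lapply(fits[others], function(f) {
      compare_distributions(fits$unbound, f)
    })
  }
  payload <- list(
    fits = lapply(fits, function(f) {
      list(mu_g_nm = f$mu_g, sigma_g = f$sigma_g, se_mu = f$se_mu,
           se_sigma = f$se_sigma, range_nm = c(f$range_low, f$range_high))
    }),
    shifts = lapply(shifts, function(s) {
      list(delta_median_nm = s$delta_median, broadening_ratio = s$broadening_ratio,
           z_median = s$z_median, z_sigma = s$z_sigma)
    })
  )
  write_report_json(payload, report_meta(files, seed),
                    file.path(out_dir, "dls_report.json"))
  invisible(list(fits = fits, shifts = shifts))
}

#' Run the footprint analysis over a scenario directory
#'
#' Integrates and normalizes the DMS traces, computes protection of the core
#' guanines for each bound sample, flags >20% changes, checks DNase
#' hypersensitivity when DNase traces are present, and writes
#' `footprint_report.json`.
#'
#' @inheritParams run_bend
#' @return List with `protection` reports and `dnase` verdict, invisibly.
#' @export
run_footprint <- function(dir, out_dir = dir, seed = NA) {
  paths <- require_inputs(dir, c("fp_dms_unbound.csv", "fp_index_map.tsv", "fp_core.txt"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  imap <- read_index_map(paths[2])
  core <- as.numeric(readLines(paths[3]))
  tab_un <- normalize_to_control(integrate_peaks(read_trace_csv(paths[1]), imap))
  bound_files <- list.files(dir, pattern = "^fp_dms_bound_.*\\.csv$", full.names = TRUE)
  if (length(bound_files) == 0) stop_validation("no fp_dms_bound_*.csv inputs in ", dir)
  cls <- sub("^fp_dms_bound_(.*)\\.csv$", "\\1", basename(bound_files))
  prot <- lapply(bound_files, function(f) {
    tab_b <- normalize_to_control(integrate_peaks(read_trace_csv(f, sample = "bound"), imap))
    protection(tab_b, tab_un, core)
  })
  names(prot) <- cls
  dnase <- NULL
  dn_files <- file.path(dir, c("fp_dnase_unbound.csv", "fp_dnase_bound.csv",
                               "fp_dnase_index_map.tsv"))
  if (all(file.exists(dn_files))) {
    dn_map <- read_index_map(dn_files[3])
    dn_un <- normalize_to_control(integrate_peaks(read_trace_csv(dn_files[1]), dn_map))
    dn_b <- normalize_to_control(integrate_peaks(
      read_trace_csv(dn_files[2], sample = "bound"), dn_map))
    dnase <- hypersensitivity_check(dn_b, dn_un, window = core[1]:(core[1] + 3))
  }
  payload <- list(
    protection = lapply(prot, function(pr) {
      list(core_fraction_bound = pr$core_fraction_bound,
           core_fraction_unbound = pr$core_fraction_unbound,
           protection_percent = pr$protection_percent,
           delta_flags = pr$delta_flags)
    }),
    dnase_site_specific = if (is.null(dnase)) NULL else dnase$site_specific
  )
  write_report_json(payload, report_meta(paths, seed),
                    file.path(out_dir, "footprint_report.json"))
  invisible(list(protection = prot, dnase = dnase))
}

#' Run the motif-information analysis over a scenario directory
#'
#' Computes positional and total information content for `motif_a.jaspar` and
#' `motif_b.jaspar`, their difference, and (when `binding_constants.csv` is
#' present) the discrimination-energetics bound on the extractable-information
#' difference. Writes `motif_report.json`.
#'
#' @inheritParams run_bend
#' @return List with `ic_a`, `ic_b`, `ic_difference`, `discrimination`,
#'   invisibly.
#' @export
run_motif <- function(dir, out_dir = dir, seed = NA) {
  paths <- require_inputs(dir, c("motif_a.jaspar", "motif_b.jaspar"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  a <- read_motif(paths[1], "jaspar")
  b <- read_motif(paths[2], "jaspar")
  ic_a <- total_ic(a); ic_b <- total_ic(b)
  disc <- NULL
  kd_file <- file.path(dir, "binding_constants.csv")
  if (file.exists(kd_file)) {
    kd <- utils::read.csv(kd_file)
    if (nrow(kd) >= 2) {
      disc <- delta_total_ic(kd$kd_specific_M[1], kd$kd_nonspecific_M[1],
                             kd$kd_specific_M[2], kd$kd_nonspecific_M[2])
    }
  }
  payload <- list(
    motif_a = list(positional_ic = ic_a$positional_ic, total_ic = ic_a$total_ic),
    motif_b = list(positional_ic = ic_b$positional_ic, total_ic = ic_b$total_ic),
    ic_difference_bits = ic_a$total_ic - ic_b$total_ic,
    discrimination = if (is.null(disc)) NULL else list(
      delta_total_ic_bits = disc$delta_total_ic,
      bits_a = disc$bits_a, bits_b = disc$bits_b, epsilon_r = disc$epsilon_r,
      kd_convention = "dissociation constants; Ksp/Kns = Kd_ns/Kd_sp")
  )
  write_report_json(payload, report_meta(paths, seed),
                    file.path(out_dir, "motif_report.json"))
  invisible(list(ic_a = ic_a, ic_b = ic_b,
                 ic_difference = ic_a$total_ic - ic_b$total_ic,
                 discrimination = disc))
}

#' Generate a scenario and run every analysis
#'
#' @param spec A [scenario_spec()].
#' @param dir Working directory for inputs and reports.
#' @param alpha Significance level for the bend comparison. Default 0.05.
#' @return Named list of the four module results, invisibly.
#' @export
run_all <- function(spec, dir, alpha = 0.05) {
  generate_scenario(spec, dir)
  invisible(list(
    bend = run_bend(dir, alpha = alpha, seed = spec$seed),
    dls = run_dls(dir, seed = spec$seed),
    footprint = run_footprint(dir, seed = spec$seed),
    motif = run_motif(dir, seed = spec$seed)
  ))
}
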