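# Circularly permuted construct series: equal-length DNA fragments carrying a
# single binding site at positions ranging from one end to the other. The
# fractional position of the site center ("flexure displacement", x) is the
# abscissa of the bend-model analysis.

#' Define an ETS binding site
#'
#' A 10-bp double-stranded binding site given by its sense (5'-GGAA-3') strand.
#' ETS domains recognize a 5'-GGA(A/T)-3' core; a site lacking that core is
#' accepted with a warning so degenerate control sequences remain usable.
#'
#' @param sequence 10-base DNA string (sense strand, characters ACGT).
#' @param name Label for the site (e.g. `"PU.1 high-affinity"`).
#' @param affinity_class `"high"` or `"low"`.
#' @return An object of class `binding_site`.
#' @examples
#' binding_site("AGCGGAAGTG", "PU.1 high", "high")
#' @export
binding_site <- function(sequence, name = "site", affinity_class = c("high", "low")) {
  affinity_class <- match.arg(affinity_class)
  if (!is.character(sequence) || length(sequence) != 1L) {
    stop_validation("sequence must be a single character string")
  }
  sequence <- toupper(sequence)
  if (nchar(sequence) != 10L) {
    stop_validation("binding site must be exactly 10 bases, got ", nchar(sequence))
  }
  if (grepl("[^ACGT]", sequence)) {
    stop_validation("sequence contains non-ACGT characters: ", sequence)
  }
  if (!grepl("GGAA|GGAT", sequence)) {
    warning("site '", sequence, "' lacks the 5'-GGA(A/T)-3' ETS core consensus")
  }
  structure(
    list(name = name, sequence = sequence, affinity_class = affinity_class),
    class = "binding_site"
  )
}

#' @export
print.binding_site <- function(x, ...) {
  cat(sprintf("<binding_site> %s: 5'-%s-3' (%s affinity)\n",
              x$name, x$sequence, x$affinity_class))
  invisible(x)
}

#' Define one circularly permuted fragment
#'
#' Coordinates are 1-based and fully closed: base i occupies the continuous
#' interval \[i-1, i\], so a fragment of length L spans \[0, L\]. `site_start`
#' may be fractional; series built by [make_series()] space site centers
#' exactly evenly, which for typical geometries (e.g. a 10-bp site in a 143-bp
#' fragment) requires off-grid placement of the central fragment.
#'
#' @param fragment_length Fragment length in bp (positive).
#' @param site_start 1-based position of the first site base (may be fractional).
#' @param site_length Site length in bp (>= 0).
#' @param label Unique fragment label.
#' @return An object of class `permuted_fragment`.
#' @export
permuted_fragment <- function(fragment_length, site_start, site_length, label = "fragment") {
  check_number(fragment_length, "fragment_length", lower = 0, strict_lower = TRUE)
  check_number(site_start, "site_start", lower = 1)
  check_number(site_length, "site_length", lower = 0)
  if (site_start + site_length - 1 > fragment_length) {
    stop_validation("site [", site_start, ", ", site_start + site_length - 1,
                    "] extends beyond fragment of length ", fragment_length)
  }
  structure(
    list(fragment_length = fragment_length, site_start = site_start,
         site_length = site_length, label = label),
    class = "permuted_fragment"
  )
}

#' Flexure displacement of a fragment
#'
#' The position of the center of the binding site relative to the length of
#' the entire fragment, as a fraction in (0, 1). Under the continuous
#' coordinate convention the site center sits at `site_start - 1 + site_length/2`,
#' so a centrally placed site gives exactly x = 0.5.
#'
#' @param fragment A `permuted_fragment`, or a `permuted_series` (in which case
#'   a vector of displacements, one per fragment, is returned).
#' @return Fraction(s) in (0, 1).
#' @examples
#' f <- permuted_fragment(143, 70.4, 10)
#' flexure_displacement(f)  # 0.52 to two decimals
#' @export
flexure_displacement <- function(fragment) UseMethod("flexure_displacement")

#' @export
flexure_displacement.permuted_fragment <- function(fragment) {
  (fragment$site_start - 1 + fragment$site_length / 2) / fragment$fragment_length
}

#' @export
flexure_displacement.permuted_series <- function(fragment) {
  vapply(fragment$fragments, flexure_displacement, numeric(1))
}

#' Site fraction of a fragment
#'
#' Percentage of the fragment length occupied by the binding site. The
#' point-kink approximation of the bend model is appropriate when this is
#' small (a 10-bp site in a 143-bp fragment spans only 7%).
#'
#' @param fragment A `permuted_fragment`.
#' @return Percent in \[0, 100\].
#' @export
site_fraction <- function(fragment) {
  if (fragment$fragment_length <= 0) stop_validation("fragment_length must be positive")
  100 * fragment$site_length / fragment$fragment_length
}

#' Build a circularly permuted fragment series
#'
#' Generates `n_fragments` fragments of identical length whose site placements
#' run from one extreme (site flush with the left end) to the other, with site
#' centers exactly evenly spaced. For odd `n_fragments` the series is mirror
#' symmetric about x = 0.5 (x_i + x_{n+1-i} = 1) and includes a centered
#' fragment.
#'
#' @param fragment_length Common fragment length, bp. Default 143.
#' @param site_length Site length, bp. Default 10 (or the length of `site`).
#' @param n_fragments Number of fragments (>= 2). Default 11.
#' @param site Optional [binding_site()] shared by the series.
#' @param labels Optional character vector of unique labels.
#' @return An object of class `permuted_series`.
#' @examples
#' s <- make_series(143, 10, 11)
#' round(flexure_displacement(s), 3)
#' @export
make_series <- function(fragment_length = 143, site_length = 10, n_fragments = 11,
                        site = NULL, labels = NULL) {
  if (!is.null(site)) {
    if (!inherits(site, "binding_site")) stop_validation("site must be a binding_site")
    site_length <- nchar(site$sequence)
  }
  check_number(n_fragments, "n_fragments", lower = 2)
  if (site_length > fragment_length) {
    stop_validation("site_length (", site_length, ") exceeds fragment_length (",
                    fragment_length, ")")
  }
  starts <- 1 + (seq_len(n_fragments) - 1) *
    (fragment_length - site_length) / (n_fragments - 1)
  if (is.null(labels)) labels <- sprintf("F%02d", seq_len(n_fragments))
  if (anyDuplicated(labels)) stop_validation("fragment labels must be unique")
  fragments <- Map(function(s, lab) {
    permuted_fragment(fragment_length, s, site_length, lab)
  }, starts, labels)
  out <- structure(list(fragments = fragments, site = site), class = "permuted_series")
  x <- flexure_displacement(out)
  if (any(diff(x) <= 0)) stop_validation("flexure displacements must be strictly increasing")
  out
}

#' @export
print.permuted_series <- function(x, ...) {
  df <- as.data.frame(x)
  cat(sprintf("<permuted_series> %d fragments of %g bp, site %g bp\n",
              nrow(df), df$fragment_length[1], df$site_length[1]))
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.permuted_series <- function(x, ...) {
  data.frame(
    label = vapply(x$fragments, `[[`, character(1), "label"),
    fragment_length = vapply(x$fragments, `[[`, numeric(1), "fragment_length"),
    site_start = vapply(x$fragments, `[[`, numeric(1), "site_start"),
    site_length = vapply(x$fragments, `[[`, numeric(1), "site_length"),
    x = flexure_displacement(x)
  )
}

#' Write / read a series definition TSV
#'
#' Columns: label, fragment_length, site_start, site_length, x (computed).
#'
#' @param series A `permuted_series`.
#' @param path File path.
#' @return `write_series_tsv` returns `path` invisibly; `read_series_tsv`
#'   returns a `permuted_series`.
#' @export
write_series_tsv <- function(series, path) {
  utils::write.table(as.data.frame(series), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_series_tsv
#' @export
read_series_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("label", "fragment_length", "site_start", "site_length")
  if (!all(need %in% names(df))) {
    stop_validation("series TSV must have columns: ", paste(need, collapse = ", "))
  }
  fragments <- Map(function(L, s, l, lab) permuted_fragment(L, s, l, lab),
                   df$fragment_length, df$site_start, df$site_length, df$label)
  structure(list(fragments = fragments, site = NULL), class = "permuted_series")
}
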