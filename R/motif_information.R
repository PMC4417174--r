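# Binding-motif information content and discrimination energetics.
#
# Under an equiprobable-base background, the information content of a motif
# position is IC = 2 + sum_b p_b log2 p_b bits (0 for a uniform column, 2 for
# an absolutely preferred base); the total IC of a site sums its positions.
# The difference in total IC between two optimized DNA discriminators A and B
# is bounded by their binding energetics:
#   Delta(total IC)_{A-B} = eps_r * (log2(Ksp_A/Kns_A) - log2(Ksp_B/Kns_B)),
# where Ksp and Kns are the specific and nonspecific association constants and
# eps_r <= ln 2 (~0.7) is the conversion efficiency under isothermal
# conditions. Constants are accepted as dissociation constants (the form in
# which affinities are quoted, e.g. 1e-10 M) and inverted internally, so
# Ksp/Kns = Kd_ns/Kd_sp.

BASES <- c("A", "C", "G", "T")

#' Assemble a motif matrix
#'
#' @param probs 4 x L base-probability matrix (rows A, C, G, T); each column
#'   must sum to 1 within 1e-9. May be omitted if `counts` is given.
#' @param counts Optional 4 x L non-negative integer count matrix; converted
#'   to probabilities with `pseudocount` added per cell.
#' @param source Provenance label (e.g. `"in vitro selection"`, `"ChIP-seq"`).
#' @param pseudocount Added to every count before normalization. Default 0.
#' @return An object of class `motif_matrix`.
#' @export
motif_matrix <- function(probs = NULL, counts = NULL, source = "", pseudocount = 0) {
  if (is.null(probs) && is.null(counts)) {
    stop_validation("either probs or counts must be supplied")
  }
  if (!is.null(counts)) {
    counts <- as.matrix(counts)
    if (nrow(counts) != 4) stop_validation("counts must have 4 rows (A, C, G, T)")
    if (any(counts < 0)) stop_validation("counts must be non-negative")
    sums <- colSums(counts + pseudocount)
    if (any(sums <= 0)) {
      stop_validation("column(s) with zero total count: ",
                      paste(which(sums <= 0), collapse = ", "))
    }
    if (is.null(probs)) probs <- sweep(counts + pseudocount, 2, sums, "/")
  }
  probs <- as.matrix(probs)
  if (nrow(probs) != 4) stop_validation("probs must have 4 rows (A, C, G, T)")
  if (ncol(probs) < 1) stop_validation("motif must have at least one position")
  if (any(probs < 0 | probs > 1)) stop_validation("probabilities must lie in [0, 1]")
  bad <- abs(colSums(probs) - 1) > 1e-9
  if (any(bad)) {
    stop_validation("column(s) not summing to 1: ", paste(which(bad), collapse = ", "))
  }
  rownames(probs) <- BASES
  if (!is.null(counts)) rownames(counts) <- BASES
  structure(list(probs = probs, counts = counts, source = source),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  prof <- total_ic(x)
  cat(sprintf("<motif_matrix> %d positions%s, total IC %.2f bits\n",
              ncol(x$probs),
              if (nzchar(x$source)) paste0(" (", x$source, ")") else "",
              prof$total_ic))
  print(round(x$probs, 3))
  invisible(x)
}

#' Positional information content
#'
#' `IC = 2 + sum_b p_b log2 p_b` bits under an equiprobable background, with
#' the convention 0 log 0 = 0. Ranges from 0 (uniform column) to 2 (single
#' absolutely preferred base).
#'
#' @param column Base-probability 4-vector (A, C, G, T) summing to 1.
#' @return Information content in bits.
#' @examples
#' positional_ic(c(1, 0, 0, 0))           # 2 bits
#' positional_ic(rep(0.25, 4))            # 0 bits
#' @export
positional_ic <- function(column) {
  if (length(column) != 4) stop_validation("column must have 4 entries (A, C, G, T)")
  if (any(column < 0)) stop_validation("probabilities must be non-negative")
  if (abs(sum(column) - 1) > 1e-9) stop_validation("column must sum to 1")
  nz <- column > 0
  2 + sum(column[nz] * log2(column[nz]))
}

#' Total information content and logo stack heights
#'
#' @param motif A [motif_matrix()].
#' @return An object of class `ic_profile` with `positional_ic` (bits per
#'   position), `total_ic` (bits), and `stack_heights` (4 x L matrix of
#'   IC x base probability; each column sums to its positional IC).
#' @export
total_ic <- function(motif) {
  if (!inherits(motif, "motif_matrix")) stop_validation("motif must be a motif_matrix")
  pic <- apply(motif$probs, 2, positional_ic)
  structure(
    list(positional_ic = pic, total_ic = sum(pic),
         stack_heights = sweep(motif$probs, 2, pic, "*")),
    class = "ic_profile"
  )
}

#' @export
print.ic_profile <- function(x, ...) {
  cat(sprintf("<ic_profile> total IC %.3f bits over %d positions\n",
              x$total_ic, length(x$positional_ic)))
  print(round(x$positional_ic, 3))
  invisible(x)
}

#' Total-IC difference between two motifs
#'
#' @param motif_a,motif_b [motif_matrix()] objects of equal length.
#' @return `total_ic(motif_a) - total_ic(motif_b)` in bits.
#' @export
ic_difference <- function(motif_a, motif_b) {
  if (ncol(motif_a$probs) != ncol(motif_b$probs)) {
    stop_validation("motifs differ in length (", ncol(motif_a$probs), " vs ",
                    ncol(motif_b$probs), "); align or trim them explicitly")
  }
  total_ic(motif_a)$total_ic - total_ic(motif_b)$total_ic
}

#' Discrimination energetics: extractable-information difference
#'
#' Converts specific/nonspecific binding of two proteins into the difference
#' in sequence information (bits) each can extract on transitioning from
#' nonspecific to specific binding:
#' `Delta = eps_r * (log2(Kd_ns,A/Kd_sp,A) - log2(Kd_ns,B/Kd_sp,B))`.
#' Constants are dissociation constants in molar units; the association-form
#' ratio Ksp/Kns equals Kd_ns/Kd_sp.
#'
#' @param kd_sp_a,kd_ns_a Specific and nonspecific Kd of protein A, M.
#' @param kd_sp_b,kd_ns_b Same for protein B.
#' @param epsilon_r Conversion efficiency in (0, 1\]; default `ln 2` (~0.7),
#'   the isothermal maximum.
#' @return An object of class `discrimination_result` with `delta_total_ic`
#'   (bits, A minus B; antisymmetric under swapping the proteins), the
#'   per-protein log-ratio terms `bits_a`, `bits_b`, and `epsilon_r`.
#' @examples
#' delta_total_ic(1e-10, 1e-5, 1e-10, 1e-7)  # 4.6 bits
#' @export
delta_total_ic <- function(kd_sp_a, kd_ns_a, kd_sp_b, kd_ns_b,
                           epsilon_r = log(2)) {
  for (v in c(kd_sp_a = kd_sp_a, kd_ns_a = kd_ns_a,
              kd_sp_b = kd_sp_b, kd_ns_b = kd_ns_b)) {
    if (!is.finite(v) || v <= 0) stop_validation("binding constants must be positive")
  }
  check_number(epsilon_r, "epsilon_r", lower = 0, upper = 1, strict_lower = TRUE)
  bits_a <- epsilon_r * log2(kd_ns_a / kd_sp_a)
  bits_b <- epsilon_r * log2(kd_ns_b / kd_sp_b)
  structure(
    list(delta_total_ic = bits_a - bits_b, bits_a = bits_a, bits_b = bits_b,
         epsilon_r = epsilon_r),
    class = "discrimination_result"
  )
}

#' @export
print.discrimination_result <- function(x, ...) {
  cat(sprintf(
    "<discrimination_result> Delta(total IC)_{A-B} = %.3f bits (eps_r = %.3f)\n",
    x$delta_total_ic, x$epsilon_r))
  cat(sprintf("  A: %.3f bits, B: %.3f bits (Kd convention: Ksp/Kns = Kd_ns/Kd_sp)\n",
              x$bits_a, x$bits_b))
  invisible(x)
}

#' Read a motif matrix from standard text formats
#'
#' Supported formats: `jaspar` (header line `>ID name`, rows like
#' `A [ 12 3 0 ... ]`), `meme_minimal` (a `MOTIF` block with a
#' `letter-probability matrix` section), and `counts_tsv` (TSV with header
#' A C G T, one row per motif position).
#'
#' @param path File path.
#' @param format One of `"jaspar"`, `"meme_minimal"`, `"counts_tsv"`.
#' @param pseudocount Added to counts before normalization. Default 0.
#' @return A [motif_matrix()].
#' @export
read_motif <- function(path, format = c("jaspar", "meme_minimal", "counts_tsv"),
                       pseudocount = 0) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  parse_fail <- function(i, why) {
    stop(errorCondition(sprintf("%s:%d: %s", path, i, why),
                        class = c("etsdyn_parse_error", "error")))
  }
  switch(format,
    jaspar = {
      src <- ""
      rows <- list()
      for (i in seq_along(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln)) next
        if (startsWith(ln, ">")) { src <- sub("^>\\s*", "", ln); next }
        m <- regmatches(ln, regexec("^([ACGT])\\s*\\[?\\s*([-0-9. eE+]+?)\\s*\\]?$", ln))[[1]]
        if (length(m) != 3) parse_fail(i, "expected 'BASE [ counts ]'")
        vals <- suppressWarnings(as.numeric(strsplit(trimws(m[3]), "\\s+")[[1]]))
        if (any(is.na(vals))) parse_fail(i, "non-numeric count")
        rows[[m[2]]] <- vals
      }
      if (!setequal(names(rows), BASES)) {
        parse_fail(length(lines), "need one row each for A, C, G, T")
      }
      counts <- do.call(rbind, rows[BASES])
      motif_matrix(counts = counts, source = src, pseudocount = pseudocount)
    },
    meme_minimal = {
      mstart <- grep("^letter-probability matrix", lines)
      if (length(mstart) == 0) parse_fail(1, "no 'letter-probability matrix' line")
      mstart <- mstart[1]
      w <- suppressWarnings(as.integer(
        sub(".*w=\\s*(\\d+).*", "\\1", lines[mstart])))
      name_line <- grep("^MOTIF", lines, value = TRUE)
      src <- if (length(name_line)) trimws(sub("^MOTIF", "", name_line[1])) else ""
      rows <- list()
      i <- mstart + 1
      while (i <= length(lines) && length(rows) < (if (is.na(w)) Inf else w)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln)) break
        vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
        if (length(vals) != 4 || any(is.na(vals))) {
          parse_fail(i, "expected 4 numeric probabilities")
        }
        rows[[length(rows) + 1]] <- vals
        i <- i + 1
      }
      if (length(rows) == 0) parse_fail(mstart, "empty probability matrix")
      if (!is.na(w) && length(rows) != w) {
        parse_fail(i - 1, sprintf("expected w=%d rows, got %d", w, length(rows)))
      }
      probs <- t(do.call(rbind, rows))
      probs <- sweep(probs, 2, colSums(probs), "/")  # absorb rounding in the file
      motif_matrix(probs = probs, source = src)
    },
    counts_tsv = {
      df <- utils::read.delim(path, check.names = FALSE)
      if (!all(BASES %in% names(df))) parse_fail(1, "header must contain A, C, G, T")
      motif_matrix(counts = t(as.matrix(df[, BASES])), pseudocount = pseudocount)
    }
  )
}

#' Write a motif matrix
#'
#' @param motif A [motif_matrix()].
#' @param path File path.
#' @param format `"jaspar"` (counts if present, else probabilities) or
#'   `"counts_tsv"`.
#' @return `path`, invisibly.
#' @export
write_motif <- function(motif, path, format = c("jaspar", "counts_tsv")) {
  format <- match.arg(format)
  m <- if (!is.null(motif$counts)) motif$counts else motif$probs
  if (format == "jaspar") {
    lines <- c(
      paste0(">", if (nzchar(motif$source)) motif$source else "motif"),
      vapply(BASES, function(b) {
        sprintf("%s [ %s ]", b,
                paste(format(m[b, ], trim = TRUE, digits = 17), collapse = " "))
      }, character(1))
    )
    writeLines(lines, path)
  } else {
    utils::write.table(as.data.frame(t(m)), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
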