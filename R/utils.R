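# Internal helpers shared across modules.

# Run expr with a locally seeded RNG, restoring the caller's RNG state on exit,
# so generators are pure functions of (arguments, seed).
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had_seed) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        },
        add = TRUE
      )
    }
    set.seed(seed)
  }
  force(expr)
}

stop_validation <- function(...) {
  stop(errorCondition(paste0(...), class = c("etsdyn_validation_error", "error")))
}

check_number <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_validation(name, " must be a single finite number")
  }
  if (strict_lower && x <= lower) stop_validation(name, " must be > ", lower)
  if (!strict_lower && x < lower) stop_validation(name, " must be >= ", lower)
  if (x > upper) stop_validation(name, " must be <= ", upper)
  invisible(x)
}

#' Format a p-value the way gel-shift reports print it
#'
#' p-values below 1e-5 are printed as `"<0.00001"`; larger values are printed
#' with up to five significant digits. The numeric value is never altered,
#' only its display.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector.
#' @export
format_pvalue <- function(p) {
  ifelse(p < 1e-5, "<0.00001", formatC(p, digits = 5, format = "g"))
}
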