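#' Round half away from zero
#'
#' Commercial rounding: exact halves move away from zero, so 0.09955 rounded
#' to four decimals is 0.0996 (base [round()] would give the even neighbour).
#' Used everywhere a value is *reported*; internal computation never rounds.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (>= 0).
#' @return `x` rounded to `digits` decimals, halves away from zero.
#' @export
#' @examples
#' round_half_up(c(0.09955, -0.09955), 4)
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), digits >= 0)
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# canonical DPSIR layer order
.layers <- c("D", "P", "S", "I", "R")

# "P_4" -> layer "P"; tolerant of codes without an underscore
code_layer <- function(code) sub("_.*$", "", code)

# numeric suffix of a code, for deterministic tie-breaking; NA-safe
code_index <- function(code) {
  idx <- suppressWarnings(as.numeric(sub("^[^_]*_", "", code)))
  ifelse(is.na(idx), Inf, idx)
}

# order codes by DPSIR layer then numeric index then alphabetically
order_codes <- function(codes) {
  order(match(code_layer(codes), .layers), code_index(codes), codes)
}

stop_ <- function(...) stop(sprintf(...), call. = FALSE)
warn_ <- function(...) warning(sprintf(...), call. = FALSE)

# sum-to-one check used by every weight constructor
check_weights <- function(w, tol = 1e-10, what = "weights") {
  if (any(!is.finite(w)) || any(w < 0))
    stop_("%s must be finite and nonnegative", what)
  if (abs(sum(w) - 1) > tol)
    stop_("%s must sum to 1 (got %.12f)", what, sum(w))
  invisible(w)
}
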