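#' Round half away from zero at a fixed number of decimals
#'
#' Decimal rounding as done on printed tables: exact halves round away from
#' zero (`0.2625 -> 0.263`), unlike [base::round()]'s round-half-even. A small
#' guard absorbs binary representation error so that values that are exact
#' halves in decimal round up even when their double representation falls a
#' few ulp short.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (non-negative integer).
#' @return `x` rounded half-up (away from zero) to `digits` decimals.
#' @examples
#' round_half_up(0.2625, 3) # 0.263
#' round_half_up(0.7125, 3) # 0.713
#' @export
round_half_up <- function(x, digits = 0) {
  stopifnot(is.numeric(x), length(digits) == 1L, digits >= 0)
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# internal: stop with a condition class so callers/tests can match error kinds
pr_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "promethee2_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
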