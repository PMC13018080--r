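# Internal numeric/formatting helpers.

#' Round half away from zero
#'
#' Commercial ("half-up") rounding used for all displayed dollar amounts;
#' `base::round()` rounds half to even, which does not match how the model's
#' reported tables are printed.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.5)    # 1
#' round_half_up(-0.5)   # -1
#' round_half_up(2.345, 2)
round_half_up <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}

#' Format a dollar amount for display
#'
#' @param x numeric vector of dollar amounts.
#' @param digits decimals to keep (0 for whole dollars, 2 for cents).
#' @return character vector like `"$13,777,940"`.
#' @export
format_dollar <- function(x, digits = 0) {
  neg <- x < 0
  v <- formatC(round_half_up(abs(x), digits),
               format = "f", digits = digits, big.mark = ",")
  paste0(ifelse(neg, "-$", "$"), v)
}

# stop() with a consistent prefix for user input errors
fail <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
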