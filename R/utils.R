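#' @keywords internal
"_PACKAGE"

#' @importFrom utils read.delim write.table
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed percentages in clinical tables
#' conventionally round half away from zero, so shares of 0.375 print as 37.5
#' and 0.5 as 1 (at 0 digits).
#'
#' @param x numeric vector.
#' @param digits number of decimal digits.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# format a fraction as a percentage at the stated printed precision
percent_printed <- function(frac, digits = 1) {
  round_half_away(100 * frac, digits = digits)
}

stop_lcrep <- function(..., call. = FALSE) {
  stop(..., call. = call.)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

rbind_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (length(rows) == 0L) return(NULL)
  do.call(rbind, c(rows, make.row.names = FALSE))
}

# deterministic child seed derived from a base seed and a stream index;
# kept below 2^31 so it is always a valid R integer seed
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 7919 + as.double(stream) * 104729) %% 2147483629)
}
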