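#' Decibel conversions
#'
#' Power quantities: `db_to_linear()` maps dB to linear power (`10^(x/10)`),
#' `linear_to_db()` is its inverse. All spectral averaging in the package is
#' done on the linear power scale; dB values appear only at interfaces.
#'
#' @param x numeric vector.
#' @return numeric vector of the same length.
#' @export
db_to_linear <- function(x) 10^(x / 10)

#' @rdname db_to_linear
#' @export
linear_to_db <- function(x) 10 * log10(x)

#' Mean of levels expressed in dB, taken in linear power
#'
#' @param x numeric vector of levels in dB.
#' @return single level in dB.
#' @export
db_power_mean <- function(x) linear_to_db(mean(db_to_linear(x)))

# internal: stop unless cond, sprintf-style message
.check <- function(cond, msg, ...) {
  if (!isTRUE(cond)) stop(sprintf(msg, ...), call. = FALSE)
}
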