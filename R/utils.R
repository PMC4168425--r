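# internal helpers shared across modules

#' @keywords internal
stop_odormix <- function(class, message, call = sys.call(-1)) {
  cond <- structure(
    class = c(class, "odormix_error", "error", "condition"),
    list(message = message, call = call)
  )
  stop(cond)
}

abort_invalid <- function(message) stop_odormix("odormix_invalid_input", message)
abort_missing <- function(message) stop_odormix("odormix_missing_data", message)
abort_degenerate <- function(message) stop_odormix("odormix_degenerate_design", message)
abort_domain <- function(message) stop_odormix("odormix_domain_error", message)
abort_subthreshold <- function(message) stop_odormix("odormix_subthreshold", message)
abort_fit <- function(message) stop_odormix("odormix_fit_failure", message)

#' Round half away from zero at a fixed number of decimals
#'
#' Conventional "schoolbook" rounding used for report output (0.05 -> 0.1),
#' unlike [base::round()]'s round-half-to-even. Internal computations always
#' keep full precision; this is applied only when matching printed tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(0.05, 1) # 0.1, where round(0.05, 1) gives 0
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
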