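#' @keywords internal
"_PACKAGE"

#' @importFrom stats qbeta runif sd setNames
#' @importFrom utils read.table write.table head tail
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; printed confidence scores follow
#' conventional half-up rounding (0.815 -> 0.82), so a dedicated helper is
#' used wherever a rounded value is part of the contract.
#'
#' @param x numeric vector
#' @param digits number of decimal places
#' @return rounded numeric vector
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

fs_log <- function(..., level = "INFO") {
  if (identical(Sys.getenv("FSINDEL_QUIET"), "1")) return(invisible(NULL))
  message(sprintf("[%s] %s", level, paste0(...)))
}

# Labels used throughout: positive class first.
DAMAGING <- "gene-damaging"
NEUTRAL <- "neutral"

fs_labels <- function() c(DAMAGING, NEUTRAL)

stopifnot_scalar_int <- function(x, name) {
  if (!(is.numeric(x) && length(x) == 1L && is.finite(x) && x == floor(x)))
    stop(sprintf("'%s' must be a single integer", name), call. = FALSE)
}
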