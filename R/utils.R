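# Shared internal helpers.

#' Format numbers in tabular scientific notation
#'
#' Rounds to a fixed number of significant figures (round-half-even, via
#' [signif()]) and renders as upper-case scientific notation, e.g. `"2.2E+00"`.
#' `NA` renders as the empty string so that missing measurements propagate to
#' blank cells in written tables.
#'
#' @param x Numeric vector.
#' @param digits Significant figures (default 2, the convention of the
#'   package's result tables).
#' @return Character vector.
#' @examples
#' format_sci(c(2.2168, 0.12048, NA))
#' @export
format_sci <- function(x, digits = 2) {
  out <- rep("", length(x))
  ok <- !is.na(x)
  out[ok] <- sprintf(paste0("%.", digits - 1, "E"), signif(x[ok], digits))
  out
}

# Null-safe scalar accessor for list- or data-frame-like rows.
.field <- function(row, name) {
  v <- row[[name]]
  if (is.null(v) || length(v) == 0) return(NA_real_)
  as.numeric(v[1])
}

# stopifnot-style validation with a custom message
.check <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}
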