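#' Round half away from zero
#'
#' Dollar and percentage figures in variation reports are rounded half away
#' from zero (commercial rounding), not to even as [base::round()] does.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# internal: stop with a classed condition so callers/tests can target errors
bv_abort <- function(msg, class) {
  stop(structure(
    class = c(class, "bundlevar_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

# internal: check required columns on a data frame
check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    bv_abort(
      sprintf("%s is missing required column(s): %s", what,
              paste(missing, collapse = ", ")),
      "bundlevar_schema_error"
    )
  }
  invisible(df)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
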