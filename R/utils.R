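# Round half away from zero (commercial rounding), unlike base round()'s
# round-half-even. Accuracies are nonnegative so only the positive branch
# matters, but keep it correct for negatives anyway.
round_half_up <- function(x, digits = 2) {
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}

# Internal field checker shared by the score functions and the cohort
# validator; `name` appears verbatim in the error so callers can identify the
# offending field.
check_numeric_field <- function(x, name, lower = -Inf, upper = Inf,
                                strict_lower = FALSE, strict = TRUE) {
  if (!is.numeric(x)) {
    stop(sprintf("field '%s' must be numeric", name), call. = FALSE)
  }
  bad_finite <- !is.finite(x)
  bad_range <- !bad_finite &
    (if (strict_lower) x <= lower else x < lower | x > upper)
  bad_range <- bad_range | (!bad_finite & x > upper)
  if (any(bad_finite)) {
    msg <- sprintf("field '%s' contains non-finite values (rows %s)",
                   name, paste(utils::head(which(bad_finite), 5), collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  if (any(bad_range, na.rm = TRUE)) {
    lim <- if (strict_lower) {
      sprintf("must be > %g", lower)
    } else {
      sprintf("must be in [%g, %g]", lower, upper)
    }
    msg <- sprintf("field '%s' out of range (%s; rows %s)",
                   name, lim, paste(utils::head(which(bad_range), 5), collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  invisible(x)
}
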