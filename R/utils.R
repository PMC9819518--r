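# Rounding that matches printed decision-analysis tables: halves go away
# from zero, unlike base round()'s round-half-even.
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Parse Saaty-scale judgments written as numbers or fraction strings ("1/3").
parse_saaty <- function(x) {
  if (is.numeric(x)) {
    return(as.numeric(x))
  }
  vapply(as.character(x), function(s) {
    s <- trimws(s)
    if (grepl("^[0-9.]+\\s*/\\s*[0-9.]+$", s)) {
      parts <- as.numeric(strsplit(s, "/")[[1]])
      parts[1] / parts[2]
    } else {
      v <- suppressWarnings(as.numeric(s))
      if (is.na(v)) abort(sprintf("cannot parse judgment value '%s'", s))
      v
    }
  }, numeric(1), USE.NAMES = FALSE)
}
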