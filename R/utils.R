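# Round half away from zero at `digits` decimals. base::round() rounds
# half-to-even, which would print a 0.15%-class distance of exactly 0.125
# as 0.12; report tables follow the conventional half-up rule instead.
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Render a proportion as a percentage string with fixed decimals (half-up).
format_percent <- function(d, digits = 1) {
  out <- rep(NA_character_, length(d))
  ok <- !is.na(d)
  out[ok] <- formatC(round_half_up(d[ok] * 100, digits),
                     format = "f", digits = digits)
  out
}

# First whitespace-separated token of a binomial.
genus_of <- function(species) {
  vapply(strsplit(species, "\\s+"), `[[`, character(1), 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
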