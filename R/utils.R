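# p-values to 3 decimals, "<.001" below 0.0005, no leading zero
.fmt_p <- function(p) {
  if (is.na(p)) return("-")
  if (p < 0.0005) return("<.001")
  sub("^0", "", sprintf("%.3f", p))
}

.fmt_or_ci <- function(or, lo, hi) {
  sprintf("%.2f (%.2f, %.2f)", or, lo, hi)
}
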