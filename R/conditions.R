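# Classed conditions so callers (and tests) can distinguish failure modes
# without string matching.

md_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "mirdose_error"), call = call))
}

md_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "mirdose_warning")))
}

# round-half-up: reported activities use commercial rounding, not the IEC
# round-half-even that base round() applies at .5 ties
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}
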