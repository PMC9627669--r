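## Classed error conditions so callers can distinguish failure modes
## (degenerate plates must be catchable, not just fatal).

screen_abort <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "rnaiscreen_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

screen_warn <- function(message, class) {
  warning(structure(
    class = c(class, "rnaiscreen_warning", "warning", "condition"),
    list(message = message, call = NULL)
  ))
}
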