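# Classed conditions so callers (and the CLI) can react to specific failures
# without matching on message text.

pdp_error <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "pdp_error")))
}

# Raised when a solver hits a user-supplied resource limit. `partial` carries
# the (incomplete) solution set accumulated so far.
pdp_limit_error <- function(msg, partial = NULL) {
  stop(errorCondition(msg, partial = partial,
                      class = c("pdp_limit_error", "pdp_error")))
}
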