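# Classed error conditions so callers can distinguish failure modes with
# tryCatch(..., NegativeProbability = ...) instead of grepping messages.
bc_stop <- function(class, msg, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "biocontinuum_error"),
                      call = call))
}

bc_warn <- function(class, msg) {
  warning(warningCondition(msg, class = c(class, "biocontinuum_warning")))
}
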