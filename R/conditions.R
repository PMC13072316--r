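# Classed conditions so callers can distinguish pipeline failure modes
# (screening rejection vs. empty signal vs. no spectral peak, ...).

rr_abort <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "rrvideo_error"), call = call))
}

rr_warn <- function(msg, class) {
  warning(warningCondition(msg, class = c(class, "rrvideo_warning")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
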