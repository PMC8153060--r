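# Condition helpers: I/O-class errors (missing/corrupt files, bad usage) are
# distinguished from domain-class errors (geometry, degenerate data) so the
# command-line layer can map them to distinct exit codes.

abort_io <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("claustrseg_io_error", "error")))
}

abort_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...), class = c("claustrseg_domain_error", "error")))
}
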