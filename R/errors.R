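# Error conditions. Three classes so callers (and the command-line driver)
# can map failures to distinct exit codes: usage (2), validation (3),
# format (3); anything else is an internal error (4).

abort_usage <- function(msg) {
  rlang::abort(msg, class = "magqc_usage_error")
}

abort_validation <- function(msg) {
  rlang::abort(msg, class = "magqc_validation_error")
}

abort_format <- function(msg) {
  rlang::abort(msg, class = c("magqc_format_error", "magqc_validation_error"))
}
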