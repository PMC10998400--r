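# Typed error conditions: every malformed input raises one of these, never a
# silent skip. Tests match on the condition class.

abort_parse <- function(message, ...) {
  abort(message, class = c("randelphi_parse_error", "randelphi_error"), ...)
}

abort_validation <- function(message, ...) {
  abort(message, class = c("randelphi_validation_error", "randelphi_error"), ...)
}

abort_domain <- function(message, ...) {
  abort(message, class = c("randelphi_domain_error", "randelphi_error"), ...)
}

abort_io <- function(message, ...) {
  abort(message, class = c("randelphi_io_error", "randelphi_error"), ...)
}

abort_empty_scores <- function(message = "no evaluable scores: item must be flagged, not scored") {
  abort(message, class = c("randelphi_empty_scores_error", "randelphi_error"))
}
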