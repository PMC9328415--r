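# Structured conditions: every user-facing failure carries a class that tests
# and the CLI can dispatch on, in addition to being a regular R error.

tk_stop <- function(msg, class, call = sys.call(-1)) {
  stop(errorCondition(msg, class = c(class, "treekit_error"), call = call))
}

stop_invalid_value <- function(msg) tk_stop(msg, "treekit_invalid_value")
stop_structure     <- function(msg) tk_stop(msg, "treekit_structure_error")
stop_lookup        <- function(msg) tk_stop(msg, "treekit_lookup_error")
stop_undefined     <- function(msg) tk_stop(msg, "treekit_undefined_statistic")
stop_topology      <- function(msg) tk_stop(msg, "treekit_unsupported_topology")
stop_io            <- function(msg) tk_stop(msg, "treekit_io_error")

stop_parse <- function(msg, offset = NULL) {
  if (!is.null(offset)) msg <- sprintf("%s (at character %d)", msg, offset)
  tk_stop(msg, "treekit_parse_error")
}
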