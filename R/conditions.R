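# Typed conditions: every recoverable failure carries a subclass so callers
# (and the meta-analysis layer) can distinguish degenerate inputs from bugs.

fg_stop <- function(msg, class, call = sys.call(-1)) {
  stop(structure(
    class = c(paste0("factorgeom_", class), "factorgeom_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

fg_warn <- function(msg, class) {
  warning(structure(
    class = c(paste0("factorgeom_", class), "factorgeom_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' @keywords internal
assert_that <- function(ok, msg, class = "domain_error") {
  if (!isTRUE(ok)) fg_stop(msg, class, call = sys.call(-2))
  invisible(TRUE)
}
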