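## Classed error conditions so callers (and the CLI) can react to failure
## modes programmatically instead of matching message strings.

chm_error <- function(class, message, ...) {
  stop(errorCondition(message, ..., class = c(paste0("chm_", class), "chm_error")))
}

#' @keywords internal
assert_that <- function(ok, class, message) {
  if (!isTRUE(ok)) chm_error(class, message)
  invisible(TRUE)
}
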