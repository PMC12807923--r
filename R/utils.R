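## Small internal helpers shared across modules.

stop2 <- function(..., class = "value_error") {
  stop(errorCondition(paste0(...), class = c(class, "ecoplateNet_error")))
}

warn2 <- function(...) warning(paste0(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_that <- function(cond, msg, class = "value_error") {
  if (!isTRUE(cond)) stop2(msg, class = class)
  invisible(TRUE)
}
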