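# shared internal helpers

# classed condition so callers can test errors by class rather than message
err <- function(class, msg) {
  stop(structure(
    class = c(class, "speechscca_error", "error", "condition"),
    list(message = msg, call = NULL)
  ))
}

warn <- function(class, msg) {
  warning(structure(
    class = c(class, "speechscca_warning", "warning", "condition"),
    list(message = msg, call = NULL)
  ))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample statistics quadruple used for sentence lengths and coherence series
stat_quad <- function(x, prefix) {
  s <- if (length(x) > 1) stats::sd(x) else 0
  out <- c(min(x), max(x), mean(x), s)
  names(out) <- paste0(prefix, c("_min", "_max", "_mean", "_sd"))
  out
}

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x == round(x) && x > 0

# derive independent sub-seeds from one master seed (kept below 2^31)
derive_seed <- function(seed, offset) {
  (as.integer(seed) + 1013904223L + offset * 7919L) %% 2147483647L
}
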