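# internal helpers shared across modules

# deterministic derivation of a child RNG seed from a base seed and a few
# small integer tags; stays within the 32-bit signed range
derive_seed <- function(base, ...) {
  tags <- c(...)
  x <- as.double(base) %% 2147483647
  for (t in tags) {
    x <- (x * 69069 + as.double(t) + 1) %% 2147483647
  }
  as.integer(x)
}

stop_param <- function(...) {
  stop(structure(class = c("unibic_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_format <- function(...) {
  stop(structure(class = c("unibic_format_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_validation <- function(...) {
  stop(structure(class = c("unibic_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# standard error of the mean
se_mean <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}
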