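# Internal helpers: seed management and logging.

# All randomness in multi-replicate drivers flows from one master seed via
# this splitter, so every replicate is individually reproducible. Linear
# congruential step keeps results in [0, 2^31 - 2] (R integers are 32-bit).
derive_seed <- function(master, stream, index = 0L) {
  m <- 2147483647
  x <- (as.double(master) %% m)
  x <- (x * 48271 + as.double(stream) * 7919 + as.double(index) + 1) %% m
  as.integer(x)
}

nse_log <- function(fmt, ..., verbose = getOption("netskeleton.verbose", FALSE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
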