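# internal helpers: seed derivation and small utilities

# Deterministically derive a child seed from a master seed and an index.
# Kept strictly below 2^31 so it is always a valid R/C++ integer seed.
derive_seed <- function(master, index) {
  master <- as.numeric(master) %% 2147483647
  (master * 48271 + as.numeric(index) * 16807 + 12345) %% 2147483647
}

`%||%` <- function(a, b) if (is.null(a)) b else a

fw_log <- function(..., verbose = getOption("fwinvade.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[fwinvade] ", ...)
  invisible(NULL)
}

stop_fw <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_fw(...)
  invisible(TRUE)
}
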