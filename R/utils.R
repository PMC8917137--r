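# Internal helpers shared across modules.

# Typed condition so callers can test specific failure modes with
# expect_error(..., class = "phospec_*").
ps_error <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "phospec_error")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `code` under a fixed RNG seed when one is given, leaving the caller's
# RNG stream untouched; run as-is when seed is NULL.
with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(seed, code)
}

# Per-stage seeds derived from one top-level seed so that pipeline stages are
# independently reproducible.  Kept well below .Machine$integer.max.
stage_seed <- function(seed, stage) {
  stages <- c(
    simulate = 1L, preprocess = 2L, quantify = 3L,
    train = 4L, predict = 5L, report = 6L
  )
  offset <- stages[[match.arg(stage, names(stages))]]
  (as.integer(seed) %% 1000000L) * 1000L + offset
}
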