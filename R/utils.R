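# Internal helpers: error signalling, argument checking, scoped RNG.

pc_stop <- function(..., class = "pulsecount_error") {
  stop(errorCondition(paste0(...),
                      class = c(class, "pulsecount_error", "error", "condition")))
}

pc_stop_validation <- function(...) {
  pc_stop(..., class = "pulsecount_validation_error")
}

# Scalar range check; bounds are closed unless open_* is set.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE,
                         integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    pc_stop_validation("`", name, "` must be a single finite number")
  if (integer && x != round(x))
    pc_stop_validation("`", name, "` must be a whole number")
  bad <- x < lower || x > upper ||
    (open_lower && x == lower) || (open_upper && x == upper)
  if (bad)
    pc_stop_validation("`", name, "` must lie in ",
                       if (open_lower) "(" else "[", lower, ", ", upper,
                       if (open_upper) ")" else "]", ", got ", format(x))
  invisible(as.numeric(x))
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    pc_stop_validation("`", name, "` must be TRUE or FALSE")
  invisible(x)
}

check_string <- function(x, name) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    pc_stop_validation("`", name, "` must be a single string")
  invisible(x)
}

# Evaluate `code` with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never perturbs user simulations.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) ||
      seed != round(seed))
    pc_stop_validation("`seed` must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old)
      assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Round half away from zero, as in hand-computed percentage tables.
round_half_up <- function(x) floor(x + 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
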