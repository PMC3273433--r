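# Classed conditions so callers (and the CLI) can map failures to exit codes:
# validation errors -> 1, configuration errors -> 2, domain errors -> 1.

abort_validation <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nullox_validation_error", "nullox_error")))
}

abort_config <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nullox_config_error", "nullox_error")))
}

abort_domain <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("nullox_domain_error", "nullox_error")))
}

warn_nullox <- function(msg, ...) {
  warning(warningCondition(sprintf(msg, ...), class = "nullox_warning"),
          call. = FALSE)
}

is_count <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x == trunc(x)
}

is_probability <- function(x) {
  length(x) == 1L && is.numeric(x) && is.finite(x) && x >= 0 && x <= 1
}

check_count <- function(x, name) {
  if (!is_count(x)) {
    abort_validation("'%s' must be a single non-negative integer, got %s",
                     name, paste(format(x), collapse = ", "))
  }
  as.integer(x)
}

check_probability <- function(x, name) {
  if (!is_probability(x)) {
    abort_domain("'%s' must be a single probability in [0, 1], got %s",
                 name, paste(format(x), collapse = ", "))
  }
  as.numeric(x)
}
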