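# Internal helpers: classed error conditions so callers can distinguish
# configuration mistakes from data/format problems and numerical failures.

rd_stop <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...),
                      class = c(class, "restdrift_error", "error", "condition")))
}

stop_config    <- function(fmt, ...) rd_stop("restdrift_config_error", fmt, ...)
stop_format    <- function(fmt, ...) rd_stop("restdrift_format_error", fmt, ...)
stop_domain    <- function(fmt, ...) rd_stop("restdrift_domain_error", fmt, ...)
stop_numeric   <- function(fmt, ...) rd_stop("restdrift_numerical_error", fmt, ...)
stop_analysis  <- function(fmt, ...) rd_stop("restdrift_analysis_error", fmt, ...)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Seed the RNG only when the caller supplies a seed; otherwise leave the
# global stream alone so callers can manage reproducibility themselves.
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop_config("rng seed must be a single number, got %s", deparse(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

is_session_image <- function(x) inherits(x, "session_image")
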