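# internal validation helpers

stop_if_not_scalar <- function(x, name, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  invisible(x)
}

stop_if_not_positive <- function(x, name) {
  stop_if_not_scalar(x, name)
  if (x <= 0) stop(sprintf("`%s` must be > 0", name), call. = FALSE)
  invisible(x)
}

stop_if_negative <- function(x, name) {
  stop_if_not_scalar(x, name)
  if (x < 0) stop(sprintf("`%s` must be >= 0", name), call. = FALSE)
  invisible(x)
}

# Seed the RNG for a sub-stream.  A freshly seeded Mersenne-Twister state
# is poorly scrambled for its first draws (across nearby streams the
# early normals are strongly biased), so a short burn-in is discarded.
seed_stream <- function(seed) {
  set.seed(as.integer(seed))
  invisible(stats::runif(64))
}

#' @keywords internal
"_PACKAGE"
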