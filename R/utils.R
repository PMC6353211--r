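# internal helpers shared across modules

#' @keywords internal
.check_number <- function(x, name, lower = -Inf, upper = Inf,
                          allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  }
  if (x < lower || x > upper) {
    stop(sprintf("'%s' must be in [%s, %s]", name,
                 format(lower), format(upper)), call. = FALSE)
  }
  invisible(x)
}

#' @keywords internal
.check_count <- function(x, name, lower = 0) {
  .check_number(x, name, lower = lower)
  if (x != round(x)) {
    stop(sprintf("'%s' must be an integer", name), call. = FALSE)
  }
  invisible(as.integer(x))
}

#' @keywords internal
.set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    .check_count(seed, "seed")
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

# Reflect an unbounded random walk into [0, L] (mirror boundaries).
#' @keywords internal
.reflect <- function(x, L) {
  y <- x %% (2 * L)
  ifelse(y > L, 2 * L - y, y)
}

#' @keywords internal
.geometric_mean <- function(x) exp(mean(log(x)))
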