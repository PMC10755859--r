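#' @keywords internal
"%||%" <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

#' Stop with a classed error
#' @noRd
sf_stop <- function(msg, class = "strainflow_error", ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

#' Validate a scalar probability / fraction
#' @noRd
check_fraction <- function(x, name, lo = 0, hi = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    sf_stop(sprintf("`%s` must be a single number in [%g, %g]", name, lo, hi),
            class = "strainflow_invalid_argument")
  }
  invisible(x)
}

#' Validate a positive integer-ish count
#' @noRd
check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != round(x)) {
    sf_stop(sprintf("`%s` must be an integer >= %d", name, min),
            class = "strainflow_invalid_argument")
  }
  invisible(as.integer(x))
}

#' Run code under a locally-set RNG seed, restoring the caller's RNG state
#' @noRd
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

#' Derive a stream-specific child seed from a master seed (stays < 2^31)
#' @noRd
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 69069 + stream * 104729) %% 2147483647
}

#' Dirichlet sampler via independent gammas
#' @noRd
rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x / rowSums(x)
}
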