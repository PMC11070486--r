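`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible child seed from a master seed
#'
#' Child seeds keep per-subject random streams independent of cohort size and
#' iteration order, so that adding or dropping a subject does not perturb the
#' draws of the others.
#'
#' @param master integer master seed (< 2^31).
#' @param k child index (>= 1).
#' @return an integer seed in \[1, 2^31 - 2\].
#' @keywords internal
child_seed <- function(master, k) {
  m <- 2147483647
  s <- (as.double(master %% m) * 69069 + as.double(k) * 1013904223) %% m
  as.integer(s %% (m - 2) + 1)
}

stopifnot_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x)))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}

## Gravitational conversion for the gram-force compliance window (400-600 g).
GRAM_FORCE_N <- 9.80665e-3
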