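# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a root seed and a stream name
#'
#' Every stage of the pipeline draws its randomness from a named substream of
#' a single root seed, so stages are independently reproducible. The derived
#' seed always fits in a 32-bit signed integer.
#'
#' @param root integer root seed.
#' @param name character stream name.
#' @return an integer seed.
#' @export
derive_seed <- function(root, name) {
  stopifnot(is.numeric(root), length(root) == 1L, is.character(name))
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((abs(root) + 104729 * h) %% .Machine$integer.max)
}

# lower-triangle off-diagonal values of a symmetric matrix
offdiag <- function(M) M[lower.tri(M, diag = FALSE)]

stop_gwherit <- function(...) stop(sprintf(...), call. = FALSE)

assert_prob <- function(x, name, open = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_gwherit("%s must be a single finite number", name)
  if (open && (x <= 0 || x >= 1))
    stop_gwherit("%s must lie strictly in (0, 1), got %g", name, x)
  if (!open && (x < 0 || x > 1))
    stop_gwherit("%s must lie in [0, 1], got %g", name, x)
  invisible(x)
}
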