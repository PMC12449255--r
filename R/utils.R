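## internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_input <- function(msg, ...) {
  stop(sprintf(msg, ...), call. = FALSE)
}

assert_that <- function(ok, msg, ...) {
  if (!isTRUE(ok)) abort_input(msg, ...)
  invisible(TRUE)
}

## coerce to a column-compressed sparse double matrix
as_dgc <- function(m) {
  Matrix::drop0(
    methods::as(methods::as(methods::as(m, "dMatrix"), "generalMatrix"),
                "CsparseMatrix"))
}

is_nonneg <- function(m) {
  if (inherits(m, "sparseMatrix")) all(m@x >= 0) else all(m >= 0)
}

## derive a stream of child seeds from one user seed, all < 2^31
derive_seeds <- function(seed, n) {
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

## half-open interval overlap: [s1, e1) vs [s2, e2)
intervals_overlap <- function(s1, e1, s2, e2) {
  s1 < e2 & e1 > s2
}
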