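#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the R random number generator, evaluates `expr`, and restores the
#' previous RNG state afterwards, so seeded operations do not perturb the
#' caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_fmt <- function(class, fmt, ...) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "erpsynth_error")))
}

assert_that <- function(ok, class, fmt, ...) {
  if (!isTRUE(ok)) stop_fmt(class, fmt, ...)
  invisible(TRUE)
}

# Derive a child seed from a base seed and a stream tag, kept within the
# 32-bit integer range R requires.
child_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L)
}
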