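# Internal helpers: seeding, validation.

# Derive a reproducible child seed for a named stage of a pipeline, so that
# each sampling stage consumes an independent stream and upstream stages are
# unaffected by how many draws a downstream stage makes.
stage_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 1103L + h * 12289) %% 2147483629)
}

# Evaluate `expr` under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_prob_vector <- function(p, what, tol = 1e-12) {
  if (any(!is.finite(p)) || any(p < -tol)) {
    stopf("%s must be finite and nonnegative", what)
  }
  if (abs(sum(p) - 1) > max(tol, 1e-8)) {
    stopf("%s must sum to 1 (got %.12g)", what, sum(p))
  }
  invisible(TRUE)
}
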