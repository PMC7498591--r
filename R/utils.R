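# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`;
# NULL seed leaves the global RNG stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(force(expr))
  }
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0.", name))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0.", name))
  invisible(x)
}

check_fraction <- function(x, name) {
  check_scalar(x, name)
  if (x < 0 || x > 1) abort(sprintf("`%s` must lie in [0, 1].", name))
  invisible(x)
}

# Coerce a frame_stack / list of matrices / single matrix to a list of
# numeric matrices.
as_frame_list <- function(stack) {
  if (inherits(stack, "frame_stack")) {
    return(stack$frames)
  }
  if (is.matrix(stack)) {
    return(list(stack))
  }
  if (is.list(stack) && all(vapply(stack, is.matrix, logical(1)))) {
    return(stack)
  }
  abort("`stack` must be a frame_stack, a matrix, or a list of matrices.")
}

stack_frame_rate <- function(stack, frame_rate = NULL) {
  if (!is.null(frame_rate)) {
    return(frame_rate)
  }
  if (inherits(stack, "frame_stack") && !is.null(stack$camera)) {
    return(stack$camera$frame_rate)
  }
  abort("`frame_rate` must be supplied when the stack carries no camera metadata.")
}
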