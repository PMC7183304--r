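# Internal helpers: deterministic child seeds and scoped RNG state.

#' Derive a deterministic child seed
#'
#' Hashes a root seed together with an arbitrary sequence of tokens
#' (site ids, design parameters, replicate numbers, ...) into a 32-bit
#' integer seed. The same tokens always give the same child, regardless
#' of the order in which combinations are visited, so any part of a
#' simulation can be reproduced in isolation.
#'
#' @param root integer root seed.
#' @param ... tokens (coerced to character) identifying the stream.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
derive_seed <- function(root, ...) {
  tokens <- as.character(c(...))
  h <- as.numeric(root) %% 2147483647
  for (tok in tokens) {
    for (b in utf8ToInt(tok)) h <- (h * 31 + b) %% 2147483647
  }
  as.integer(h)
}

# Set the RNG to `seed` for the calling function only; the caller's
# .Random.seed is restored when the returned function is evaluated
# (register it with on.exit). A NULL seed leaves the RNG untouched.
local_seed <- function(seed) {
  if (is.null(seed)) return(function() invisible(NULL))
  env <- globalenv()
  old <- if (exists(".Random.seed", envir = env, inherits = FALSE)) {
    get(".Random.seed", envir = env, inherits = FALSE)
  } else {
    NULL
  }
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = env, inherits = FALSE)) {
        rm(".Random.seed", envir = env)
      }
    } else {
      assign(".Random.seed", old, envir = env)
    }
    invisible(NULL)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_coralmse <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "coralmse_error")))
}
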