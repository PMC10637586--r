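## Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed` and restores the previous
#' RNG state afterwards, so seeded internals never disturb a caller's stream.
#' @param seed integer seed
#' @param code expression to evaluate
#' @return the value of `code`
#' @keywords internal
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else suppressWarnings(rm(".Random.seed", envir = env))
  })
  set.seed(seed)
  force(code)
}

#' Derive a child seed from a master seed and a stream name
#'
#' Deterministic seed splitting: the master seed and the characters of the
#' stream label are folded into a 31-bit integer by a multiplicative hash, so
#' each pipeline stage, replicate and patient draws from its own stream while
#' remaining fully determined by the master seed.
#'
#' @param master integer master seed
#' @param ... stream components (strings or numbers), e.g. `"patient"`, `7`
#' @return an integer in `[1, 2^31 - 2]`
#' @export
#' @examples
#' derive_seed(42, "consensus", 3)
derive_seed <- function(master, ...) {
  mod <- 2147483629
  h <- as.numeric(master) %% mod
  for (part in list(...)) {
    for (ch in utf8ToInt(paste0("/", as.character(part)))) {
      h <- (h * 31 + ch) %% mod
    }
  }
  as.integer(h %% (mod - 2) + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) &&
  x == round(x) && x >= 0

## Row-index triplet of the TRUE voxels of a 3D logical array.
which_voxels <- function(mask) {
  idx <- which(mask)
  arrayInd(idx, dim(mask))
}
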