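# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Convert centimorgan to Morgan
#'
#' All internal computations use Morgans; centimorgans appear only at I/O
#' boundaries (segment tables, error models, length grids).
#'
#' @param x numeric, lengths in cM.
#' @return numeric, lengths in Morgans.
#' @export
cm_to_morgan <- function(x) x / 100

#' Convert Morgan to centimorgan
#' @param x numeric, lengths in Morgans.
#' @return numeric, lengths in cM.
#' @export
morgan_to_cm <- function(x) x * 100

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL leaves the RNG untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a reproducible child seed (kept below 2^31) from a base seed.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * as.numeric(k)) %% 2147483629)
}

stop_domain <- function(...) stop(..., call. = FALSE)
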