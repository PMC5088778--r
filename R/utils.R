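#' @importFrom rlang .data %||%
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards. `seed = NULL` runs unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream of child seeds from one parent seed, keeping them well below
# .Machine$integer.max so downstream set.seed() calls are valid.
child_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  with_seed(seed, sample.int(.Machine$integer.max %/% 2L, n))
}
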