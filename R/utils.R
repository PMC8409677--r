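#' @keywords internal
"_PACKAGE"

#' Derive a reproducible sub-stream seed
#'
#' Every stochastic stage of the pipeline draws its seed from the run seed plus
#' a stage name, so stages can be re-run in isolation and still reproduce the
#' monolithic run.
#'
#' @param seed integer master seed.
#' @param stream character stage name.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 + h) %% 2147483647)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

# 8-bit clamp
clamp255 <- function(x) pmin(pmax(x, 0), 255)

# luminance of an H x W x 3 array on the 0..255 scale
luminance <- function(img) (img[, , 1] + img[, , 2] + img[, , 3]) / 3

stop_pollen <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
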