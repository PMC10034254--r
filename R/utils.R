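#' @importFrom stats quantile median sd rnorm runif rpois rgeom predict setNames
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(x, y) if (is.null(x)) y else x

## Evaluate expr with a local RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

## Derive a child seed from a parent seed and a stage tag; keeps within 32-bit range.
childSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L)
}

assertThat <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
  invisible(TRUE)
}

## mean/SD/median/IQR summary used by every report
summariseDistances <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) {
    return(list(n = 0L, mean = NA_real_, sd = NA_real_,
                median = NA_real_, iqr = NA_real_))
  }
  list(n = length(x), mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
       median = median(x), iqr = unname(quantile(x, 0.75) - quantile(x, 0.25)))
}

## Vectorised categorical sampling: one draw per row of a probability matrix.
## u is a vector of uniforms (length nrow) so callers control the RNG stream.
sampleRows <- function(prob, u) {
  cp <- t(apply(prob, 1L, cumsum))
  cp[, ncol(cp)] <- 1 + 1e-12
  1L + rowSums(cp < u)
}
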