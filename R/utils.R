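#' Decibel / linear intensity conversions
#'
#' \code{dbToLinear(x)} is \code{10^(x/10)}; \code{linearToDb(x)} is
#' \code{10*log10(x)}. The two are exact inverses on representable values.
#'
#' @param x numeric vector or matrix.
#' @return converted values, same shape.
#' @examples
#' dbToLinear(30)          # 1000
#' linearToDb(dbToLinear(17.3))
#' @export
dbToLinear <- function(x) 10^(x / 10)

#' @rdname dbToLinear
#' @export
linearToDb <- function(x) 10 * log10(x)

## Centered sliding-window box sum via a padded integral image.
## Output cell (r, c) sums the h x w window with top-left
## (r - floor(h/2), c - floor(w/2)); cells whose window exceeds the raster
## are NA. Used by the RSC window statistics.
.boxSum <- function(m, h, w) {
  nr <- nrow(m); nc <- ncol(m)
  if (h > nr || w > nc) stop("window larger than raster")
  P <- matrix(0, nr + 1L, nc + 1L)
  P[-1L, -1L] <- t(apply(apply(m, 2L, cumsum), 1L, cumsum))
  ra <- seq_len(nr - h + 1L); ca <- seq_len(nc - w + 1L)
  S <- P[ra + h, ca + w, drop = FALSE] - P[ra, ca + w, drop = FALSE] -
       P[ra + h, ca, drop = FALSE] + P[ra, ca, drop = FALSE]
  out <- matrix(NA_real_, nr, nc)
  out[ra + h %/% 2L, ca + w %/% 2L] <- S
  out
}

## Half-up rounding of a proportion to whole percent (0.85 -> 85, 0.745 -> 75).
## base::round() rounds half to even, which is not the convention used in
## clinical tables; the tiny epsilon guards against 187/220-style binary
## representation of exact halves.
.percentHalfUp <- function(p) {
  ifelse(is.na(p), NA_real_, floor(p * 100 + 0.5 + 1e-9))
}

## Run a thunk under a fixed RNG seed without disturbing the caller's stream.
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
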