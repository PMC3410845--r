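# Small internal helpers shared across modules.

#' Round half away from zero
#'
#' Base `round()` rounds half to even; printed phenotype tables round half
#' away from zero, so 0.5 -> 1 and -0.5 -> -1.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Bilinear interpolation of a matrix at fractional (row, col) coordinates.
# Coordinates are 1-based; points outside the matrix are an error.
#' @keywords internal
#' @noRd
bilinear_sample <- function(mat, row, col) {
  H <- nrow(mat); W <- ncol(mat)
  if (any(row < 1 | row > H | col < 1 | col > W)) {
    stop("sample coordinates fall outside the frame")
  }
  r0 <- pmin(floor(row), H - 1L); c0 <- pmin(floor(col), W - 1L)
  fr <- row - r0; fc <- col - c0
  v00 <- mat[cbind(r0, c0)];     v10 <- mat[cbind(r0 + 1L, c0)]
  v01 <- mat[cbind(r0, c0 + 1L)]; v11 <- mat[cbind(r0 + 1L, c0 + 1L)]
  (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
    (1 - fr) * fc * v01 + fr * fc * v11
}

# Evaluate an expression with a locally seeded RNG, restoring the caller's
# RNG state afterwards so generators never perturb user code.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
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
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}

# Clip to 8-bit grey levels and round to integers.
#' @keywords internal
#' @noRd
clip8 <- function(x) round(pmin(pmax(x, 0), 255))
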