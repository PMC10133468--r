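#' Greenwood place-frequency map parameters
#'
#' The Greenwood function relates relative position along the cochlear spiral
#' to the characteristic frequency of the basilar membrane at that position:
#' \deqn{F(x) = A (10^{a x} - K)}
#' where `x` is the proportion of cochlear length measured *from the apex*
#' (`x = 0` at the helicotrema, `x = 1` at the round window). The defaults are
#' the published human constants (A = 165.4 Hz, a = 2.1, K = 0.88), which put
#' the apical frequency at 19.85 Hz and the basal end near 20.7 kHz.
#'
#' @param A Scale constant in Hz. Must be positive.
#' @param a Exponent slope per unit relative distance. Must be positive.
#' @param K Integration constant; `0 <= K < 1` so that the apical frequency
#'   stays positive.
#' @return An object of class `greenwood_params`.
#' @examples
#' gp <- greenwood_params()
#' greenwood_frequency(c(0, 0.5, 1), gp)
#' @export
greenwood_params <- function(A = 165.4, a = 2.1, K = 0.88) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(a), length(a) == 1L, is.finite(a),
            is.numeric(K), length(K) == 1L, is.finite(K))
  if (A <= 0) stop("Greenwood scale 'A' must be positive")
  if (a <= 0) stop("Greenwood slope 'a' must be positive")
  if (K < 0 || K >= 1) stop("Greenwood constant 'K' must satisfy 0 <= K < 1")
  structure(list(A = A, a = a, K = K), class = "greenwood_params")
}

#' @export
print.greenwood_params <- function(x, ...) {
  cat(sprintf("Greenwood map F(x) = %.4g * (10^(%.4g x) - %.4g)\n",
              x$A, x$a, x$K))
  cat(sprintf("  apex (x = 0): %.4g Hz;  base (x = 1): %.6g Hz\n",
              greenwood_frequency(0, x), greenwood_frequency(1, x)))
  invisible(x)
}

#' Greenwood frequency at a relative cochlear position
#'
#' @param x Relative distance from the apex as a proportion of cochlear
#'   length, in `[0, 1]`. Vectorised.
#' @param params A [greenwood_params()] object.
#' @return Characteristic frequency in Hz, strictly increasing in `x`.
#' @seealso [greenwood_position()] for the analytic inverse,
#'   [place_frequencies()] to map a whole electrode array.
#' @export
greenwood_frequency <- function(x, params = greenwood_params()) {
  stopifnot(inherits(params, "greenwood_params"), is.numeric(x))
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop("relative position 'x' must lie within [0, 1]")
  }
  params$A * (10^(params$a * x) - params$K)
}

#' Inverse Greenwood map: relative position for a frequency
#'
#' Analytic inverse of [greenwood_frequency()]:
#' `x = log10(f/A + K) / a`.
#'
#' @param frequency Frequency in Hz; must lie within the range spanned by the
#'   map on `[0, 1]`.
#' @param params A [greenwood_params()] object.
#' @return Relative distance from the apex in `[0, 1]`.
#' @export
greenwood_position <- function(frequency, params = greenwood_params()) {
  stopifnot(inherits(params, "greenwood_params"), is.numeric(frequency))
  fmin <- greenwood_frequency(0, params)
  fmax <- greenwood_frequency(1, params)
  if (any(frequency < fmin - 1e-9) || any(frequency > fmax + 1e-9)) {
    stop(sprintf("frequency outside the Greenwood range [%.4g, %.6g] Hz",
                 fmin, fmax))
  }
  x <- log10(frequency / params$A + params$K) / params$a
  pmin(pmax(x, 0), 1)
}
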