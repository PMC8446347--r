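#' Saturating firing-rate nonlinearity
#'
#' Constructs the static nonlinearity phi(x) that maps the activity variable
#' x (analogous to a membrane potential) to an output firing rate. The
#' function is built from two tanh branches joined at the inflection point
#' `r0`:
#' \deqn{\phi(x) = r_0 (1 + \tanh[(x - r_0)/r_0]) \quad (x \le r_0)}
#' \deqn{\phi(x) = r_0 + r_{max} \tanh[(x - r_0)/r_{max}] \quad (x > r_0)}
#' Both branches give value `r0` and slope 1 at the join, so phi is C1.
#' phi is strictly increasing and bounded in (0, r0 + rmax); the upper
#' bound `r0 + rmax` is the saturation ceiling of the model.
#'
#' Rates are in arbitrary units: the model never assigns Hz.
#'
#' @param r0 rate at the inflection point (rate units, > 0).
#' @param rmax maximum deviation of the rate above `r0` (rate units, > 0).
#' @return An object of class `rate_fn`.
#' @seealso [firing_rate()], [rate_ceiling()]
#' @examples
#' f <- rate_fn()
#' firing_rate(c(-20, 10, 90), f)
#' @export
rate_fn <- function(r0 = 10, rmax = 80) {
  if (!is.numeric(r0) || length(r0) != 1L || !is.finite(r0) || r0 <= 0)
    stop("'r0' must be a single finite positive number", call. = FALSE)
  if (!is.numeric(rmax) || length(rmax) != 1L || !is.finite(rmax) || rmax <= 0)
    stop("'rmax' must be a single finite positive number", call. = FALSE)
  structure(list(r0 = r0, rmax = rmax), class = "rate_fn")
}

#' Evaluate the firing-rate nonlinearity
#'
#' @param x activity value(s); any finite real, vectorized.
#' @param f a [rate_fn()] object.
#' @return Rates, same shape as `x`, each in (0, r0 + rmax).
#' @export
firing_rate <- function(x, f = rate_fn()) {
  stopifnot(inherits(f, "rate_fn"))
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be finite numeric", call. = FALSE)
  r0 <- f$r0
  rmax <- f$rmax
  out <- ifelse(x <= r0,
                r0 * (1 + tanh((x - r0) / r0)),
                r0 + rmax * tanh((x - r0) / rmax))
  ## 1 + tanh(z) underflows to 0 in double precision for z < -19; a tiny
  ## floor keeps rates strictly positive, as the exact nonlinearity is.
  out <- pmax(out, 1e-12 * r0)
  if (is.matrix(x)) dim(out) <- dim(x)
  out
}

#' Saturation ceiling of a rate function
#'
#' @param f a [rate_fn()] object.
#' @return `r0 + rmax`, the supremum of attainable rates.
#' @export
rate_ceiling <- function(f) {
  stopifnot(inherits(f, "rate_fn"))
  f$r0 + f$rmax
}

#' @export
print.rate_fn <- function(x, ...) {
  cat(sprintf("<rate_fn> r0 = %g, rmax = %g (ceiling %g)\n",
              x$r0, x$rmax, x$r0 + x$rmax))
  invisible(x)
}
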