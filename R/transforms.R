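#' Modulus transformation of growth rates
#'
#' Sign-preserving power transform used to bring strongly right-skewed annual
#' growth increments to an approximately normal scale before model fitting:
#' `g^lambda` for `g >= 0` and `-(-g)^lambda` for `g < 0`. The transform is an
#' odd, strictly increasing bijection on the reals, so negative increments
#' (shrinkage, stem breakage) are handled without truncation.
#'
#' @param g numeric vector of growth increments (any sign, any unit).
#' @param lambda power exponent; the pipeline default is 0.4.
#' @return transformed values, same length as `g`.
#' @seealso [modulus_inverse()]
#' @export
#' @examples
#' modulus_transform(c(-32, 0, 32)) # -4, 0, 4
modulus_transform <- function(g, lambda = 0.4) {
  stopifnot(is.numeric(g), is.numeric(lambda), length(lambda) == 1L, lambda > 0)
  sign(g) * abs(g)^lambda
}

#' Inverse modulus transformation
#'
#' Exact inverse of [modulus_transform()]: `sign(x) * |x|^(1/lambda)`.
#'
#' @param x transformed values.
#' @param lambda exponent used in the forward transform.
#' @return values on the original growth scale.
#' @export
modulus_inverse <- function(x, lambda = 0.4) {
  stopifnot(is.numeric(x), length(lambda) == 1L, lambda > 0)
  sign(x) * abs(x)^(1 / lambda)
}

#' Log expected lifespan from annual survival probability
#'
#' Transforms an annual survival probability `s` in (0, 1) to the logarithm of
#' the expected lifespan under constant annual survival, `log(1 / (1 - s))`.
#' The transform is a strictly increasing bijection from (0, 1) to the whole
#' real line restricted here to survival values, so species orderings by
#' survival are preserved exactly while the heavy compression near s = 1 is
#' linearized for multivariate analysis.
#'
#' @param s numeric vector of annual survival probabilities, all in (0, 1).
#' @return `log(1 / (1 - s))`.
#' @export
#' @examples
#' lifespan_transform(0.5) # log(2)
lifespan_transform <- function(s) {
  stopifnot(is.numeric(s))
  bad <- !is.na(s) & (s <= 0 | s >= 1)
  if (any(bad)) {
    stop("survival probabilities must lie strictly in (0, 1); offending value(s): ",
         paste(utils::head(s[bad], 3L), collapse = ", "))
  }
  log(1 / (1 - s))
}

#' Probability of surviving a census interval
#'
#' Per-observation likelihood term of the survival model: an individual with
#' annual survival probability `s` survives an interval of `t` years with
#' probability `s^t`. Exposed as a function because interval censoring is the
#' defining feature of multi-year census data.
#'
#' @param s annual survival probability in \[0, 1\].
#' @param t interval length in years, `t > 0`.
#' @return `s^t`, recycled over the longer argument.
#' @export
#' @examples
#' interval_survival_prob(0.9, 2) # 0.81
interval_survival_prob <- function(s, t) {
  stopifnot(is.numeric(s), is.numeric(t))
  if (any(!is.na(s) & (s < 0 | s > 1))) stop("s must lie in [0, 1]")
  if (any(!is.na(t) & t <= 0)) stop("t must be positive")
  s^t
}
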