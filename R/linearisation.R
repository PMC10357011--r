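#' Two-coefficient count linearisation model
#'
#' CMOS line sensors of this class respond almost linearly to flux except
#' at low count values, where counts underestimate the flux. The response
#' is modelled with a two-coefficient saturating-logarithm family relating
#' the normalised expected linear count rate r to the normalised observed
#' count c:
#'
#'   f(c; a, b) = log(1 + c^b / a) / log(1 + 1 / a),   a > 0, b > 0
#'
#' The family is pinned at f(1) = 1 (both axes are scaled to max = 1
#' before fitting), is strictly increasing, tends to zero as counts
#' approach zero with a vanishing slope for b > 1 (so low-count noise is
#' not artificially amplified, unlike gamma-variate or log-linear
#' corrections, which dive negative below one count), and is log-linear in
#' c asymptotically. In the limit of large `a` it reduces to the power law
#' c^b, so `a = 1e12, b = 1` is numerically an identity response.
#'
#' @param a,b Positive model coefficients.
#' @param r_squared Optional goodness of fit stored by [fit_linearisation()].
#' @return An object of class `lin_model`.
#' @seealso [fit_linearisation()], [linearise()]
#' @export
#' @examples
#' m <- lin_model(0.14231, 1.06125)  # a published unit's coefficients
#' lin_apply(0.5, m)                 # normalised rate at half counts
#' lin_invert(lin_apply(0.5, m), m)  # round trip
lin_model <- function(a, b, r_squared = NA_real_) {
  stopifnot(is.numeric(a), is.numeric(b), length(a) == 1L, length(b) == 1L,
            is.finite(a), is.finite(b), a > 0, b > 0)
  structure(list(a = a, b = b, r_squared = r_squared), class = "lin_model")
}

#' @export
print.lin_model <- function(x, ...) {
  cat(sprintf("<lin_model> a = %.6g, b = %.6g", x$a, x$b))
  if (is.finite(x$r_squared)) cat(sprintf(" (R^2 = %.5f)", x$r_squared))
  cat("\n")
  invisible(x)
}

#' Apply or invert the linearisation response
#'
#' `lin_apply()` maps normalised counts to normalised linear rate;
#' `lin_invert()` is its exact algebraic inverse (the generative
#' direction: ideal linear rate to observed counts). Both are odd
#' extensions over negative inputs: the sign is switched, the function
#' applied, and the sign switched back, so negative dark-subtracted counts
#' are never systematically amplified.
#'
#' @param c_norm,r_norm Numeric vectors (any sign).
#' @param model A [lin_model()].
#' @return Numeric vector of the same length.
#' @export
lin_apply <- function(c_norm, model) {
  stopifnot(inherits(model, "lin_model"))
  s <- sign(c_norm)
  s * log1p(abs(c_norm)^model$b / model$a) / log1p(1 / model$a)
}

#' @rdname lin_apply
#' @export
lin_invert <- function(r_norm, model) {
  stopifnot(inherits(model, "lin_model"))
  s <- sign(r_norm)
  s * (model$a * expm1(abs(r_norm) * log1p(1 / model$a)))^(1 / model$b)
}

#' Linearise dark-subtracted photosite counts
#'
#' Applies the fitted response to each photosite's count, expressed as a
#' fraction of the saturation ceiling (the count scale on which the model
#' is anchored), returning linearised counts on the original count scale:
#' `c_lin = ceiling * f(c / ceiling)`. Zero maps to zero, and negative
#' counts follow the odd-extension sign rule.
#'
#' @param counts A [count_spectrum()] or a bare numeric vector.
#' @param model A [lin_model()].
#' @param ceiling Saturation ceiling in counts (default 900).
#' @return Numeric vector of linearised counts.
#' @export
linearise <- function(counts, model, ceiling = 900) {
  stopifnot(ceiling > 0)
  c_p <- if (inherits(counts, "count_spectrum")) counts$c else as.numeric(counts)
  ceiling * lin_apply(c_p / ceiling, model)
}
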