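#' Link specification for binary marginal models
#'
#' Constructs the link object used throughout the package. Three inverse
#' links are supported:
#' \describe{
#'   \item{`"skewed_logit"`}{the Burr type-10 ("scobit") form
#'     \eqn{\pi = 1 - (1 + e^{\eta})^{-\alpha}}, asymmetric for
#'     \eqn{\alpha \ne 1}; the default.}
#'   \item{`"prentice"`}{the power-logit form
#'     \eqn{\pi = \{e^{\eta}/(1+e^{\eta})\}^{\alpha}}.}
#'   \item{`"logit"`}{the standard logistic CDF (`alpha` is forced to 1).}
#' }
#' Both asymmetric families reduce exactly to the logit at \eqn{\alpha = 1}.
#'
#' @param family One of `"skewed_logit"`, `"logit"`, `"prentice"`.
#' @param alpha Positive skewness parameter (dimensionless). `alpha = 1`
#'   gives the symmetric logistic response curve.
#' @return An object of class `"link_spec"` with elements `family` and
#'   `alpha`.
#' @examples
#' lk <- link_spec("skewed_logit", alpha = 2)
#' inverse_link(0, lk) # 1 - 2^-2 = 0.75
#' @export
link_spec <- function(family = c("skewed_logit", "logit", "prentice"),
                      alpha = 1) {
  family <- match.arg(family)
  if (!is.numeric(alpha) || length(alpha) != 1L || !is.finite(alpha) ||
      alpha <= 0) {
    stop("`alpha` must be a single finite positive number", call. = FALSE)
  }
  if (family == "logit" && alpha != 1) {
    stop("family \"logit\" requires alpha = 1", call. = FALSE)
  }
  structure(list(family = family, alpha = as.numeric(alpha)),
            class = "link_spec")
}

#' @export
print.link_spec <- function(x, ...) {
  cat(sprintf("<link_spec> family = %s, alpha = %g\n", x$family, x$alpha))
  invisible(x)
}

as_link_spec <- function(link) {
  if (inherits(link, "link_spec")) return(link)
  if (is.character(link) && length(link) == 1L) return(link_spec(link))
  stop("`link` must be a link_spec object or a family name", call. = FALSE)
}

# log(1 + exp(x)) without overflow; accurate over the whole real line
log1pexp <- function(x) {
  out <- x
  lo <- x <= -37
  mid <- x > -37 & x <= 18
  hi2 <- x > 18 & x <= 33.3
  top <- x > 33.3
  out[lo] <- exp(x[lo])
  out[mid] <- log1p(exp(x[mid]))
  out[hi2] <- x[hi2] + exp(-x[hi2])
  out[top] <- x[top]
  out
}

#' Inverse link: linear predictor to probability
#'
#' Maps the linear predictor \eqn{\eta} to \eqn{\pi \in (0,1)} under the
#' chosen link. Evaluated in log space so it is stable for \eqn{|\eta|}
#' up to several hundred.
#'
#' @param eta Numeric vector of linear predictor values.
#' @param link A [link_spec()] (or family name, with `alpha = 1`).
#' @return Probabilities, same length as `eta`.
#' @seealso [forward_link()], [mean_derivative()]
#' @export
inverse_link <- function(eta, link = link_spec()) {
  link <- as_link_spec(link)
  stopifnot(is.numeric(eta))
  a <- link$alpha
  switch(link$family,
    logit = stats::plogis(eta),
    # 1 - (1+e^eta)^-a = -expm1(-a * log(1+e^eta))
    skewed_logit = -expm1(-a * log1pexp(eta)),
    # (e^eta/(1+e^eta))^a = exp(-a * log(1+e^-eta))
    prentice = exp(-a * log1pexp(-eta))
  )
}

#' Forward link: probability to linear predictor
#'
#' The quantile inverse of [inverse_link()]: returns the \eqn{\eta} whose
#' inverse-link image is `pi`.
#'
#' @param pi Numeric vector of probabilities strictly inside (0, 1).
#' @inheritParams inverse_link
#' @return Linear predictor values.
#' @export
forward_link <- function(pi, link = link_spec()) {
  link <- as_link_spec(link)
  if (any(!is.finite(pi)) || any(pi <= 0) || any(pi >= 1)) {
    stop("`pi` must lie strictly inside (0, 1)", call. = FALSE)
  }
  a <- link$alpha
  switch(link$family,
    logit = stats::qlogis(pi),
    # eta = log((1-pi)^(-1/a) - 1)
    skewed_logit = log(expm1(-log1p(-pi) / a)),
    prentice = {
      p1 <- exp(log(pi) / a) # pi^(1/a), the logistic probability
      log(p1) - log1p(-p1)
    }
  )
}

#' Derivative of the mean with respect to the linear predictor
#'
#' \eqn{d\pi/d\eta}, the diagonal entries of the \eqn{\Lambda} matrix in
#' the GEE score. For the skewed logit the closed form is
#' \eqn{\alpha e^{\eta} (1+e^{\eta})^{-\alpha-1}}.
#'
#' @inheritParams inverse_link
#' @return Strictly positive derivative values, same length as `eta`.
#' @export
mean_derivative <- function(eta, link = link_spec()) {
  link <- as_link_spec(link)
  stopifnot(is.numeric(eta))
  a <- link$alpha
  switch(link$family,
    logit = stats::dlogis(eta),
    skewed_logit = exp(log(a) + eta - (a + 1) * log1pexp(eta)),
    # a * sigma(eta)^a * (1 - sigma(eta))
    prentice = exp(log(a) - a * log1pexp(-eta) - log1pexp(eta))
  )
}

#' Point of maximal covariate sensitivity
#'
#' The response curve of an asymmetric link is steepest at a probability
#' other than 0.5. For the Burr-form skewed logit the maximizing linear
#' predictor is \eqn{\eta^* = -\log\alpha} (so \eqn{\alpha > 1} shifts
#' the steepest point above 0.5, \eqn{\alpha < 1} below); for the
#' Prentice form it is \eqn{\eta^* = +\log\alpha}. At \eqn{\alpha = 1}
#' both give \eqn{(\eta^*, \pi^*) = (0, 0.5)}.
#'
#' @inheritParams inverse_link
#' @return A list with `eta_star` (argmax of [mean_derivative()]) and
#'   `pi_star` (its inverse-link image).
#' @export
sensitivity_peak <- function(link = link_spec()) {
  link <- as_link_spec(link)
  eta_star <- switch(link$family,
    logit = 0,
    skewed_logit = -log(link$alpha),
    prentice = log(link$alpha)
  )
  list(eta_star = eta_star, pi_star = inverse_link(eta_star, link))
}
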