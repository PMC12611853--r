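# Activation registry. Each entry provides the elementwise function and its
# derivative; GELU is available in the exact Gaussian-CDF form and in the
# tanh approximation with cubic-correction constant 0.044715.

.selu_lambda <- 1.0507009873554805
.selu_alpha <- 1.6732632423543772

erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

gelu_exact <- function(x) 0.5 * x * (1 + erf(x / sqrt(2)))

gelu_tanh <- function(x) {
  0.5 * x * (1 + tanh(sqrt(2 / pi) * (x + 0.044715 * x^3)))
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))

.activations <- list(
  ReLU = list(
    f = function(x, p) pmax(x, 0),
    df = function(x, p) as.numeric(x > 0)
  ),
  LeakyReLU = list(
    f = function(x, p) ifelse(x > 0, x, p$slope * x),
    df = function(x, p) ifelse(x > 0, 1, p$slope)
  ),
  ELU = list(
    f = function(x, p) ifelse(x > 0, x, p$alpha * (exp(pmin(x, 0)) - 1)),
    df = function(x, p) ifelse(x > 0, 1, p$alpha * exp(pmin(x, 0)))
  ),
  SELU = list(
    f = function(x, p) .selu_lambda * ifelse(x > 0, x, .selu_alpha * (exp(pmin(x, 0)) - 1)),
    df = function(x, p) .selu_lambda * ifelse(x > 0, 1, .selu_alpha * exp(pmin(x, 0)))
  ),
  GELU = list(
    f = function(x, p) if (isTRUE(p$tanh_approx)) gelu_tanh(x) else gelu_exact(x),
    df = function(x, p) {
      if (isTRUE(p$tanh_approx)) {
        u <- sqrt(2 / pi) * (x + 0.044715 * x^3)
        th <- tanh(u)
        0.5 * (1 + th) + 0.5 * x * (1 - th^2) * sqrt(2 / pi) * (1 + 3 * 0.044715 * x^2)
      } else {
        0.5 * (1 + erf(x / sqrt(2))) + x * stats::dnorm(x)
      }
    }
  ),
  Swish = list(
    f = function(x, p) x * stats::plogis(x),
    df = function(x, p) {
      s <- stats::plogis(x)
      s + x * s * (1 - s)
    }
  ),
  Mish = list(
    f = function(x, p) x * tanh(softplus(x)),
    df = function(x, p) {
      sp <- softplus(x)
      th <- tanh(sp)
      th + x * (1 - th^2) * stats::plogis(x)
    }
  )
)

#' Activation functions
#'
#' Build an activation from the registry used throughout the network blocks.
#' `GELU` defaults to the exact Gaussian-CDF form
#' \eqn{f(i) = 0.5\, i\, (1 + \mathrm{erf}(i/\sqrt{2}))}; set
#' `tanh_approx = TRUE` for the tanh approximation
#' \eqn{\mathrm{erf}(i/\sqrt 2) \approx \tanh(\sqrt{2/\pi}(i + 0.044715\, i^3))}.
#'
#' @param name one of `"SELU"`, `"ELU"`, `"GELU"`, `"Mish"`, `"Swish"`,
#'   `"ReLU"`, `"LeakyReLU"`.
#' @param slope negative-side slope for `LeakyReLU` (must be positive).
#' @param alpha scale of the negative saturation for `ELU`.
#' @param tanh_approx use the tanh approximation of GELU.
#' @return an object of class `nodseg_activation` with elements `f` (the
#'   elementwise map) and `df` (its derivative), callable on scalars or
#'   arrays of any shape.
#' @examples
#' act <- activation("GELU")
#' act$f(1)   # ~0.841
#' @export
activation <- function(name, slope = 0.01, alpha = 1.0, tanh_approx = FALSE) {
  if (!name %in% names(.activations)) {
    stop("unknown activation '", name, "'; registered: ",
         paste(names(.activations), collapse = ", "))
  }
  if (name == "LeakyReLU" && slope <= 0) stop("LeakyReLU slope must be > 0")
  p <- list(slope = slope, alpha = alpha, tanh_approx = tanh_approx)
  entry <- .activations[[name]]
  structure(
    list(name = name, params = p,
         f = function(x) entry$f(x, p),
         df = function(x) entry$df(x, p)),
    class = "nodseg_activation"
  )
}

#' List registered activation names
#' @return character vector of activation names.
#' @export
activation_names <- function() names(.activations)
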