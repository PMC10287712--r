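#' Clamped logit and inverse-logit transforms
#'
#' The QY response is modelled linearly on the logit scale,
#' \eqn{\mathrm{logit}(p) = \log(p/(1-p))}. Field QY readings of exactly 0
#' occur in deep winter; proportions are therefore clamped into
#' \eqn{[\epsilon, 1-\epsilon]} before transforming so the response never
#' becomes infinite. `inv_logit()` is the exact two-sided inverse on the
#' clamped domain.
#'
#' @param p proportions in \eqn{[0, 1]}.
#' @param x values on the logit (log-odds) scale.
#' @param eps clamp bound, a single number in \eqn{(0, 0.5)}. Default `1e-3`.
#' @return `logit()`: log-odds of the clamped proportions. `inv_logit()`:
#'   proportions in \eqn{(0, 1)}.
#' @examples
#' logit(0.5)            # 0
#' logit(0, eps = 1e-3)  # log(0.001/0.999)
#' inv_logit(logit(0.3)) # 0.3
#' @export
logit <- function(p, eps = 1e-3) {
  check_number(eps, "eps")
  if (eps <= 0 || eps >= 0.5) stop_("`eps` must be strictly inside (0, 0.5)")
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_("`p` must lie in [0, 1]")
  qlogis(pmin(pmax(p, eps), 1 - eps))
}

#' @rdname logit
#' @export
inv_logit <- function(x) plogis(x)
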