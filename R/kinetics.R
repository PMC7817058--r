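#' Transport and ribosome-binding kinetics of a translation inhibitor
#'
#' Membrane transport is first order, \eqn{J(a_{ex}, a) = p_{in} a_{ex} -
#' p_{out} a}; binding to translating ribosomes follows mass action with
#' second-order on-rate `k_on` and first-order off-rate `k_off`.
#' `k_off = 0` describes effectively irreversible binders such as
#' streptomycin.
#'
#' @param p_in influx rate constant, \eqn{h^{-1}}.
#' @param p_out efflux rate constant, \eqn{h^{-1}}.
#' @param k_on forward binding rate constant, \eqn{\mu M^{-1} h^{-1}}.
#' @param k_off reverse binding rate constant, \eqn{h^{-1}}.
#' @return An object of class `drug_kinetics` with the rates and the
#'   dissociation constant `K_D = k_off / k_on` (\eqn{\mu M}).
#' @export
drug_kinetics <- function(p_in, p_out, k_on, k_off) {
  stopifnot(p_in >= 0, p_out >= 0, k_on > 0, k_off >= 0)
  structure(
    list(p_in = p_in, p_out = p_out, k_on = k_on, k_off = k_off,
         K_D = k_off / k_on),
    class = "drug_kinetics")
}

#' @export
print.drug_kinetics <- function(x, ...) {
  cat("Translation-inhibitor kinetics\n")
  cat(sprintf("  p_in  = %.4g h^-1   p_out = %.4g h^-1\n", x$p_in, x$p_out))
  cat(sprintf("  k_on  = %.4g uM^-1 h^-1   k_off = %.4g h^-1   K_D = %.4g uM\n",
              x$k_on, x$k_off, x$K_D))
  invisible(x)
}

#' Reduce full kinetics to the two-parameter dose-response shape
#'
#' The single-drug steady state depends on the kinetics only through the
#' characteristic rate \eqn{\lambda_0^* = 2\sqrt{p_{out}\kappa_t K_D}} and
#' the concentration scale \eqn{IC_{50}^* = \Delta r \lambda_0^*/(2 p_{in})}.
#' The dimensionless response parameter \eqn{\alpha = \lambda_0^*/\lambda_0}
#' controls curve steepness (small `alpha`: steep, possibly bistable;
#' large `alpha`: shallow).  The 50%-inhibition concentration is
#' \eqn{IC_{50} = IC_{50}^* (\alpha^2+1)/(2\alpha)}, equivalently
#' \eqn{\Delta r \lambda_0 (\alpha^2+1)/(4 p_{in})}, a form that remains
#' valid in the irreversible-binding limit `alpha = 0`.
#'
#' @param kinetics a [drug_kinetics()] object.
#' @param laws a [growth_laws()] object.
#' @return An object of class `response_shape` with fields `alpha`, `ic50`
#'   (\eqn{\mu M}), `lambda0_star` (\eqn{h^{-1}}), `ic50_star` (\eqn{\mu M}),
#'   and `irreversible` (`TRUE` when `alpha == 0`).
#' @examples
#' laws <- growth_laws()
#' reduce_kinetics(drug_kinetics(100, 10, 1000, 400), laws)
#' @export
reduce_kinetics <- function(kinetics, laws) {
  stopifnot(inherits(kinetics, "drug_kinetics"), inherits(laws, "growth_laws"))
  lambda0_star <- 2 * sqrt(kinetics$p_out * laws$kappa_t * kinetics$K_D)
  alpha <- lambda0_star / laws$lambda0
  ic50_star <- laws$delta_r * lambda0_star / (2 * kinetics$p_in)
  # exact for alpha > 0 and equal to the alpha -> 0 limit at alpha = 0
  ic50 <- laws$delta_r * laws$lambda0 * (alpha^2 + 1) / (4 * kinetics$p_in)
  response_shape(alpha, ic50 = ic50, lambda0_star = lambda0_star,
                 ic50_star = ic50_star)
}

#' Construct a dose-response shape directly from its response parameter
#'
#' @param alpha dimensionless response parameter (>= 0).
#' @param ic50 extracellular concentration at 50% inhibition, \eqn{\mu M};
#'   optional (dimensionless work in IC50 units does not need it).
#' @param lambda0_star,ic50_star optional underlying scales; filled by
#'   [reduce_kinetics()].
#' @return A `response_shape` object.
#' @export
response_shape <- function(alpha, ic50 = NA_real_, lambda0_star = NA_real_,
                           ic50_star = NA_real_) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha >= 0)
  structure(
    list(alpha = alpha, ic50 = ic50, lambda0_star = lambda0_star,
         ic50_star = ic50_star, irreversible = (alpha == 0)),
    class = "response_shape")
}

#' @export
print.response_shape <- function(x, ...) {
  cat(sprintf("Dose-response shape: alpha = %.5g", x$alpha))
  if (x$irreversible) cat("  (irreversible binder)")
  cat("\n")
  if (is.finite(x$ic50)) cat(sprintf("  IC50 = %.5g uM\n", x$ic50))
  if (is.finite(x$lambda0_star))
    cat(sprintf("  lambda0* = %.5g h^-1, IC50* = %.5g uM\n",
                x$lambda0_star, x$ic50_star))
  invisible(x)
}

#' Canonical kinetics realising a given response parameter
#'
#' The steady-state dose-response curve depends on the kinetics only through
#' `alpha`, but the full dynamical (and two-drug) system needs a concrete
#' parameter set.  This preset fixes `k_on`, `p_out` and `p_in` at typical
#' values for translation inhibitors and solves
#' \eqn{K_D = (\alpha\lambda_0)^2/(4\kappa_t p_{out})} for the dissociation
#' constant.
#'
#' @param alpha response parameter (>= 0).
#' @param laws a [growth_laws()] object.
#' @param k_on,p_out,p_in preset rates (\eqn{\mu M^{-1}h^{-1}},
#'   \eqn{h^{-1}}, \eqn{h^{-1}}).
#' @return A [drug_kinetics()] object whose [reduce_kinetics()] alpha equals
#'   `alpha`.
#' @export
shape_to_kinetics <- function(alpha, laws, k_on = 1000, p_out = 10,
                              p_in = 100) {
  if (inherits(alpha, "response_shape")) alpha <- alpha$alpha
  stopifnot(alpha >= 0)
  K_D <- (alpha * laws$lambda0)^2 / (4 * laws$kappa_t * p_out)
  drug_kinetics(p_in = p_in, p_out = p_out, k_on = k_on, k_off = K_D * k_on)
}
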