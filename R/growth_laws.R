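#' Bacterial growth-law constants
#'
#' Bundles the empirical growth-law parameters that tie ribosome
#' concentration to growth rate in *E. coli*.  Under nutrient variation the
#' unperturbed ribosome concentration follows
#' \eqn{r_u = r_{min} + \lambda/\kappa_t} (first growth law); under
#' translation inhibition at fixed nutrients the total ribosome
#' concentration is upregulated,
#' \eqn{r_{tot} = r_{max} - \lambda \Delta r [1/\lambda_0 - 1/(\kappa_t \Delta r)]}.
#'
#' The defaults are the standard published constants
#' (\eqn{\kappa_t = 0.06\,\mu M^{-1} h^{-1}}, \eqn{r_{min} = 19.3\,\mu M},
#' \eqn{r_{max} = 65.8\,\mu M}).  `lambda0` is the drug-free growth rate set
#' by the nutrient environment; it must not exceed
#' \eqn{\lambda_{max} = \kappa_t \Delta r}, the growth rate at which the
#' inhibition line reaches zero ribosome upregulation headroom.
#'
#' @param kappa_t translational capacity, \eqn{\mu M^{-1} h^{-1}}.
#' @param r_min minimal ribosome concentration, \eqn{\mu M}.
#' @param r_max maximal ribosome concentration, \eqn{\mu M}.
#' @param lambda0 drug-free growth rate, \eqn{h^{-1}}.
#' @return An object of class `growth_laws` with fields `kappa_t`, `r_min`,
#'   `r_max`, `delta_r`, `lambda0`, `lambda_max`.
#' @examples
#' laws <- growth_laws()
#' laws$delta_r  # 46.5 uM
#' @export
growth_laws <- function(kappa_t = 0.06, r_min = 19.3, r_max = 65.8,
                        lambda0 = 1) {
  stopifnot(is.numeric(kappa_t), kappa_t > 0,
            is.numeric(r_min), is.numeric(r_max),
            is.numeric(lambda0))
  if (!(r_max > r_min && r_min > 0))
    stop("need r_max > r_min > 0")
  delta_r <- r_max - r_min
  lambda_max <- kappa_t * delta_r
  if (!(lambda0 > 0 && lambda0 <= lambda_max))
    stop(sprintf("lambda0 must lie in (0, lambda_max = %.4g]", lambda_max))
  structure(
    list(kappa_t = kappa_t, r_min = r_min, r_max = r_max,
         delta_r = delta_r, lambda0 = lambda0, lambda_max = lambda_max),
    class = "growth_laws")
}

#' @export
print.growth_laws <- function(x, ...) {
  cat("Bacterial growth laws\n")
  cat(sprintf("  kappa_t    = %.4g uM^-1 h^-1\n", x$kappa_t))
  cat(sprintf("  r_min      = %.4g uM\n", x$r_min))
  cat(sprintf("  r_max      = %.4g uM\n", x$r_max))
  cat(sprintf("  delta_r    = %.4g uM\n", x$delta_r))
  cat(sprintf("  lambda0    = %.4g h^-1\n", x$lambda0))
  cat(sprintf("  lambda_max = %.4g h^-1\n", x$lambda_max))
  invisible(x)
}

# total ribosome concentration under translation inhibition (second growth
# law), valid for 0 <= lambda <= lambda0
r_tot_of_lambda <- function(laws, lambda) {
  laws$r_max - lambda * laws$delta_r *
    (1 / laws$lambda0 - 1 / (laws$kappa_t * laws$delta_r))
}

# ribosome synthesis rate s(lambda) = lambda * r_tot(lambda)
s_of_lambda <- function(laws, lambda) lambda * r_tot_of_lambda(laws, lambda)
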