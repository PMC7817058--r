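#' IC50 fold-change of a translation inhibitor under a starvation-mimicking
#' antibiotic
#'
#' A starvation-mimicking antibiotic (SMA, e.g. mupirocin) lowers the
#' drug-free growth rate to \eqn{g(c_s)\lambda_0}, rescaling the
#' translation inhibitor's response parameter to
#' \eqn{\alpha = \alpha_F/g(c_s)}.  The resulting relative change in IC50
#' is
#' \deqn{\psi = \frac{IC_{50}}{IC_{50,F}} =
#'   \frac{\alpha_F^2 + g^2(c_s)}{(\alpha_F^2+1)\, g(c_s)}.}
#' In the limits \eqn{\alpha_F \to 0} and \eqn{\alpha_F \to \infty} this
#' becomes \eqn{\psi = g} and \eqn{\psi = 1/g}; for \eqn{\alpha_F \le 1}
#' the minimum \eqn{\psi = 2\alpha_F/(1+\alpha_F^2)} is attained at
#' \eqn{g = \alpha_F}, while for \eqn{\alpha_F > 1} the fold-change rises
#' monotonically with SMA inhibition.
#'
#' @param alpha_F response parameter in the absence of the SMA (>= 0).
#' @param g relative growth under the SMA alone, in (0, 1]; vectorized.
#' @return IC50 fold-change(s) `psi`.
#' @examples
#' sma_psi(1.04, 0.5)            # chloramphenicol-like
#' sma_psi(0.46, 0.46)           # streptomycin-like, at its minimum
#' @export
sma_psi <- function(alpha_F, g) {
  stopifnot(alpha_F >= 0)
  if (any(g <= 0) || any(g > 1)) stop("g must lie in (0, 1]")
  (alpha_F^2 + g^2) / ((alpha_F^2 + 1) * g)
}

#' SMA dose-response function from a table or a parametric curve
#'
#' The SMA's own dose-response \eqn{g(c_s)} is treated as given: either
#' tabulated (monotone spline interpolation) or as a single-drug curve with
#' its own response parameter.
#'
#' @param table optional data frame / matrix with columns `(c_s, g)`;
#'   `g(0)` must be 1 and `g` non-increasing.
#' @param alpha optional response parameter: `g(c_s)` is then the
#'   upper-branch single-drug curve with `c_s` in IC50 units.
#' @return A function `g(c_s)` returning values in (0, 1].
#' @export
sma_g_function <- function(table = NULL, alpha = NULL) {
  if (!is.null(table)) {
    table <- as.data.frame(table)
    cs <- table[[1]]; g <- table[[2]]
    stopifnot(!is.unsorted(cs), abs(g[1] - 1) < 1e-9 && cs[1] == 0,
              all(diff(g) <= 1e-12))
    f <- stats::splinefun(cs, g, method = "hyman")
    function(c_s) pmin(1, pmax(f(c_s), 1e-12))
  } else if (!is.null(alpha)) {
    function(c_s) pmax(observable_y(alpha, c_s), 1e-12)
  } else stop("supply either a table or an alpha for the SMA curve")
}

#' Dose-response surface of a translation inhibitor combined with an SMA
#'
#' For each SMA concentration the translation inhibitor's curve is
#' re-parameterised (\eqn{\alpha = \alpha_F/g}, concentration scale
#' \eqn{\psi}) and evaluated on the upper branch:
#' \deqn{y(c, c_s) = g(c_s) \times f(\alpha_F/g(c_s),\, c/\psi),}
#' where `f` is the single-drug dose-response solution.  This deviates from
#' the simple product \eqn{g \cdot f(\alpha_F, c)} because the SMA reshapes
#' the inhibitor's dose-response curve, not just its plateau.
#'
#' @param alpha_F translation inhibitor's response parameter absent the
#'   SMA.
#' @param c_grid inhibitor concentrations in units of its SMA-free IC50.
#' @param cs_grid SMA concentrations (units of whatever `g` expects).
#' @param g SMA dose-response function from [sma_g_function()], or a
#'   table/alpha accepted by it.
#' @return A `dose_response_surface` with rows indexing `c_grid` and
#'   columns `cs_grid`.
#' @export
sma_surface <- function(alpha_F, c_grid, cs_grid, g) {
  stopifnot(alpha_F >= 0, all(c_grid >= 0), all(cs_grid >= 0))
  if (!is.function(g)) {
    g <- if (is.numeric(g) && length(g) == 1) sma_g_function(alpha = g)
         else sma_g_function(table = g)
  }
  y <- matrix(NA_real_, length(c_grid), length(cs_grid))
  for (j in seq_along(cs_grid)) {
    gj <- g(cs_grid[j])
    psi <- sma_psi(alpha_F, gj)
    y[, j] <- gj * observable_y(alpha_F / gj, c_grid / psi)
  }
  dose_response_surface(c_grid, cs_grid, y,
                        meta = list(alpha_F = alpha_F, model = "sma"))
}
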