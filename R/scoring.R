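# 2-D trapezoidal integral of matrix M over grids x (rows) and y (cols)
trapz2 <- function(x, y, M) {
  wx <- c(diff(x), 0) / 2 + c(0, diff(x)) / 2
  wy <- c(diff(y), 0) / 2 + c(0, diff(y)) / 2
  as.numeric(wx %*% M %*% wy)
}

# largest y in (0, 1] solving cA * uA(y) + cB * uB(y) = 1, where u_i = 1/C_i
# are reciprocal single-drug inverse dose-response functions.  Vectorized
# over concentration pairs: block scan on a dense descending y grid picks
# the bracket of the largest crossing, then uniroot refines it.
largest_crossing <- function(uA, uB, cA, cB, n_y = 4096) {
  yg <- c(seq(1 - 1e-9, 0.01, length.out = n_y),
          exp(seq(log(0.01), log(1e-8), length.out = 512))[-1])
  invA <- uA(yg); invB <- uB(yg)
  n <- length(cA)
  out <- numeric(n)
  blk <- 512L
  for (s in seq(1, n, by = blk)) {
    idx <- s:min(s + blk - 1, n)
    H <- outer(invA, cA[idx]) + outer(invB, cB[idx])  # K x block
    below <- H < 1
    first <- apply(below, 2, function(v) match(TRUE, v))
    for (m in seq_along(idx)) {
      j <- idx[m]; k <- first[m]
      if (cA[j] == 0 && cB[j] == 0) { out[j] <- 1; next }
      if (is.na(k)) { out[j] <- 0; next }      # beyond both drugs' reach
      if (k == 1) { out[j] <- 1; next }        # below numerical resolution
      h <- function(y) cA[j] * uA(y) + cB[j] * uB(y) - 1
      out[j] <- stats::uniroot(h, lower = yg[k], upper = yg[k - 1],
                               tol = 1e-13)$root
    }
  }
  out
}

#' Loewe additive reference surface
#'
#' The additive expectation built from the single-drug responses alone: for
#' each concentration pair, `y_add` solves the isobole condition
#' \eqn{c_A/C_A(y) + c_B/C_B(y) = 1}, where \eqn{C_i(y)} is drug *i*'s
#' closed-form inverse dose-response.  All isoboles of the resulting
#' surface are straight lines by construction.  For bistable drugs
#' (`alpha < alpha_crit()`) the analytic inverse, defined on all of (0, 1],
#' is used, with the largest solution reported; self-combination is then
#' exactly additive including the discontinuous drop.  If no solution
#' exists in (0, 1] (both drugs beyond reach, possible only for
#' `alpha = 0`), `y_add = 0`.
#'
#' @param shape_A,shape_B [response_shape()] objects or bare alphas.
#'   Alternatively supply `inverse_A`/`inverse_B`.
#' @param c_A,c_B concentration grids in each drug's IC50 units.
#' @param inverse_A,inverse_B optional inverse dose-response functions
#'   `C(y)` (normalized concentration as a function of relative growth),
#'   overriding the closed form; used e.g. for resistant strains.
#' @return A `dose_response_surface` holding `y_add`.
#' @examples
#' ref <- loewe_additive_surface(1, 1, seq(0, 2, 0.5), seq(0, 2, 0.5))
#' ref$y[1, ]  # first row equals drug B's single-drug curve
#' @export
loewe_additive_surface <- function(shape_A = NULL, shape_B = NULL, c_A, c_B,
                                   inverse_A = NULL, inverse_B = NULL) {
  mk_u <- function(shape, inv) {
    if (!is.null(inv)) return(function(y) 1 / inv(y))
    alpha <- if (inherits(shape, "response_shape")) shape$alpha else shape
    function(y) y * (alpha^2 + 1) / ((1 - y) * (4 * y^2 + alpha^2))
  }
  uA <- mk_u(shape_A, inverse_A)
  uB <- mk_u(shape_B, inverse_B)
  grid <- expand.grid(cA = c_A, cB = c_B)
  y <- largest_crossing(uA, uB, grid$cA, grid$cB)
  dose_response_surface(c_A, c_B, matrix(y, length(c_A), length(c_B)),
                        meta = list(reference = "loewe"))
}

#' Bliss independence reference surface
#'
#' Multiplies the single-drug relative responses:
#' \eqn{y_{bliss}(c_A, c_B) = y_A(c_A)\, y_B(c_B)}.  Coincides with Loewe
#' additivity only for exponential dose-response curves.
#'
#' @param curve_A,curve_B [dose_response_curve()] objects evaluated on the
#'   desired grids.
#' @return A `dose_response_surface`.
#' @export
bliss_surface <- function(curve_A, curve_B) {
  stopifnot(inherits(curve_A, "dose_response_curve"),
            inherits(curve_B, "dose_response_curve"))
  dose_response_surface(curve_A$concentration, curve_B$concentration,
                        outer(curve_A$growth_relative,
                              curve_B$growth_relative),
                        meta = list(reference = "bliss"))
}

#' Loewe interaction score
#'
#' Log-ratio of the volume under the dose-response surface to the volume
#' under the Loewe additive reference on the same grid:
#' \deqn{LI = \log \frac{\int y\, dc_A\, dc_B}{\int y_{add}\, dc_A\, dc_B}.}
#' Negative values indicate synergy, positive antagonism; `|LI|` below the
#' tolerance band is classified additive.
#'
#' @param surface a `dose_response_surface` (model or measured).
#' @param reference the additive reference surface on the same grid (a
#'   `dose_response_surface` or bare matrix).
#' @param tolerance half-width of the additive band.
#' @return Object of class `interaction_score`: list with `li`, `label`,
#'   `tolerance`, and the two volumes.
#' @export
li_score <- function(surface, reference, tolerance = 0.01) {
  stopifnot(inherits(surface, "dose_response_surface"))
  yref <- if (inherits(reference, "dose_response_surface")) reference$y
          else as.matrix(reference)
  stopifnot(identical(dim(surface$y), dim(yref)))
  v <- trapz2(surface$c_A, surface$c_B, surface$y)
  vadd <- trapz2(surface$c_A, surface$c_B, yref)
  if (vadd <= 0) stop("additive reference has zero volume")
  li <- log(v / vadd)
  label <- if (li < -tolerance) "synergy"
           else if (li > tolerance) "antagonism" else "additive"
  structure(list(li = li, label = label, tolerance = tolerance,
                 volume = v, volume_additive = vadd),
            class = "interaction_score")
}

#' @export
print.interaction_score <- function(x, ...) {
  cat(sprintf("LI = %+.4f  [%s]  (additive band +/- %g)\n",
              x$li, x$label, x$tolerance))
  invisible(x)
}

#' Full model surface, Loewe reference and LI score for a drug pair
#'
#' Convenience wrapper: builds concrete kinetics for each response
#' parameter, solves the full two-drug surface, constructs the Loewe
#' additive reference from the closed-form single-drug inverses, and
#' scores the interaction.
#'
#' The Loewe reference is built from the full model's own single-drug
#' responses (exact inverse dose-response of each drug's kinetic system,
#' normalised by its numerically determined IC50) — the same single-drug
#' curves that form the surface's axes — so that any non-zero LI reflects
#' genuine interaction rather than reference-model mismatch.
#'
#' @param alpha_A,alpha_B response parameters (> 0), realised as concrete
#'   kinetics by [shape_to_kinetics()]; or [drug_kinetics()] objects.
#' @param deltas a [binding_modifiers()] object.
#' @param laws a [growth_laws()] object.
#' @param c_max grid upper end, IC50 units.
#' @param n grid resolution per axis.
#' @return List with `surface`, `reference` and `score`.
#' @export
pair_interaction <- function(alpha_A, alpha_B, deltas = binding_modifiers(),
                             laws = growth_laws(), c_max = 3, n = 121) {
  grid <- seq(0, c_max, length.out = n)
  kin <- lapply(list(alpha_A, alpha_B), function(d)
    if (inherits(d, "drug_kinetics")) d else shape_to_kinetics(d, laws))
  surf <- pair_surface(kin, deltas, laws, grid, grid)
  ic50 <- surf$meta$ic50
  invA <- function(y) aex_of_y(y, kin[[1]], laws) / ic50[1]
  invB <- function(y) aex_of_y(y, kin[[2]], laws) / ic50[2]
  ref <- loewe_additive_surface(c_A = grid, c_B = grid,
                                inverse_A = invA, inverse_B = invB)
  list(surface = surf, reference = ref, score = li_score(surf, ref))
}

#' Phase diagram of drug interactions over response parameters
#'
#' LI score for every pair `(alpha_A, alpha_B)` on (typically log-spaced)
#' response-parameter grids, with the model surface and Loewe reference
#' recomputed at each cell.  For symmetric binding modifiers the diagram is
#' symmetric under drug swap, and only the upper triangle is computed.
#'
#' @param alpha_A_grid,alpha_B_grid response parameter grids (> 0).
#' @param deltas a [binding_modifiers()] object.
#' @param laws a [growth_laws()] object.
#' @param c_max,n concentration grid specification per cell.
#' @return Object of class `phase_diagram`: `alpha_A_grid`, `alpha_B_grid`,
#'   matrix `li`.
#' @export
phase_diagram <- function(alpha_A_grid, alpha_B_grid = alpha_A_grid,
                          deltas = binding_modifiers(), laws = growth_laws(),
                          c_max = 3, n = 61) {
  stopifnot(all(alpha_A_grid > 0), all(alpha_B_grid > 0))
  symmetric <- identical(alpha_A_grid, alpha_B_grid) &&
    deltas$delta_on_A == deltas$delta_on_B &&
    deltas$delta_off_A == deltas$delta_off_B
  li <- matrix(NA_real_, length(alpha_A_grid), length(alpha_B_grid))
  for (i in seq_along(alpha_A_grid)) {
    for (j in seq_along(alpha_B_grid)) {
      if (symmetric && j < i) { li[i, j] <- li[j, i]; next }
      li[i, j] <- pair_interaction(alpha_A_grid[i], alpha_B_grid[j],
                                   deltas, laws, c_max, n)$score$li
    }
  }
  structure(list(alpha_A_grid = alpha_A_grid, alpha_B_grid = alpha_B_grid,
                 li = li, deltas = unclass(deltas)),
            class = "phase_diagram")
}

#' @export
print.phase_diagram <- function(x, ...) {
  cat(sprintf("Drug-interaction phase diagram: %d x %d alpha grid, LI in [%.3g, %.3g]\n",
              length(x$alpha_A_grid), length(x$alpha_B_grid),
              min(x$li), max(x$li)))
  invisible(x)
}

#' @export
plot.phase_diagram <- function(x, ...) {
  graphics::image(log2(x$alpha_A_grid), log2(x$alpha_B_grid), x$li,
                  xlab = "log2 alpha_A", ylab = "log2 alpha_B", ...)
  graphics::contour(log2(x$alpha_A_grid), log2(x$alpha_B_grid), x$li,
                    levels = 0, add = TRUE, lwd = 2, lty = 2)
  invisible(x)
}
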