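#' Constitutively expressed resistance enzyme
#'
#' An unregulated resistance enzyme (degrading enzyme or efflux pump) whose
#' expression tracks the gene-expression machinery: proportional to
#' \eqn{(1-\lambda_0/\lambda_{max})} across nutrient environments and to
#' \eqn{\lambda/\lambda_0} under translation inhibition.  Its activity is
#' summarised by the growth-coupled Michaelis-Menten removal flux of
#' [removal_flux()]; the enzyme pool itself is not a dynamic variable.
#'
#' @param v_max_prime maximal removal rate in the current nutrient
#'   environment, \eqn{V'_{max} = V_{max}(1-\lambda_0/\lambda_{max})},
#'   \eqn{\mu M\, h^{-1}}.
#' @param k_rem Michaelis-Menten constant, \eqn{\mu M}.
#' @param target which drug the enzyme removes, `"A"` or `"B"` (one enzyme
#'   per drug; no cross-resistance).
#' @return An object of class `resistance_enzyme`.
#' @examples
#' resistance_enzyme(1000, 0.1)   # strong, easily saturated enzyme
#' @export
resistance_enzyme <- function(v_max_prime, k_rem, target = "A") {
  stopifnot(v_max_prime >= 0, k_rem > 0, target %in% c("A", "B"))
  structure(list(v_max_prime = v_max_prime, k_rem = k_rem, target = target),
            class = "resistance_enzyme")
}

#' @export
print.resistance_enzyme <- function(x, ...) {
  cat(sprintf("Resistance enzyme (drug %s): V'_max = %.4g uM/h, K_rem = %.4g uM\n",
              x$target, x$v_max_prime, x$k_rem))
  invisible(x)
}

#' Growth-coupled antibiotic removal flux
#'
#' \deqn{j_{rem} = V'_{max}\,\frac{\lambda}{\lambda_0}\,
#'   \frac{a}{a + K_{rem}}.}
#' The \eqn{\lambda/\lambda_0} factor encodes the drop of constitutive
#' expression under translation inhibition and closes the positive feedback
#' loop that steepens dose-response curves.
#'
#' @param enzyme a [resistance_enzyme()].
#' @param lambda_rel relative growth rate \eqn{\lambda/\lambda_0} in
#'   `[0, 1]`.
#' @param a intracellular drug concentration, \eqn{\mu M} (vectorized).
#' @return Removal flux, \eqn{\mu M\, h^{-1}}.
#' @export
removal_flux <- function(enzyme, lambda_rel, a) {
  stopifnot(inherits(enzyme, "resistance_enzyme"),
            lambda_rel >= 0, lambda_rel <= 1 + 1e-12, all(a >= 0))
  enzyme$v_max_prime * lambda_rel * a / (a + enzyme$k_rem)
}

#' Closed-form inverse dose-response of the (optionally resistant)
#' single-drug system
#'
#' At steady state the growth laws pin every pool as a function of the
#' growth rate: \eqn{r_b = \Delta r(1-y)},
#' \eqn{a = r_b(\lambda + k_{off})\kappa_t/(k_{on}\lambda)}, and the drug
#' balance then yields the extracellular concentration
#' \eqn{a_{ex}(y) = [(\lambda + p_{out})a + \lambda r_b + j_{rem}(a,
#' \lambda)]/p_{in}} — an exact inverse including the resistance-enzyme
#' feedback evaluated self-consistently.
#'
#' @param y relative growth rate(s) in (0, 1]; vectorized.
#' @param kinetics a [drug_kinetics()] object.
#' @param laws a [growth_laws()] object.
#' @param enzyme optional [resistance_enzyme()].
#' @return Extracellular concentration(s), \eqn{\mu M}.
#' @export
aex_of_y <- function(y, kinetics, laws, enzyme = NULL) {
  if (any(y <= 0) || any(y > 1)) stop("y must lie in (0, 1]")
  lam <- y * laws$lambda0
  r_b <- laws$delta_r * (1 - y)
  a <- ifelse(y == 1, 0,
              r_b * (lam + kinetics$k_off) * laws$kappa_t /
                (kinetics$k_on * lam))
  flux <- if (is.null(enzyme)) 0 else removal_flux(enzyme, y, a)
  ((lam + kinetics$p_out) * a + lam * r_b + flux) / kinetics$p_in
}

# observable (largest-y) branch of a curve given its inverse a_ex(y):
# reuses the descending-scan crossing machinery of the Loewe construction
observable_from_inverse <- function(invfun, targets) {
  u <- function(y) 1 / invfun(y)
  zero <- function(y) rep(0, length(y))
  largest_crossing(u, zero, targets, rep(0, length(targets)))
}

# numerical IC50 of an observable curve defined by its inverse: the
# concentration at which the observable branch first reaches y <= 1/2
# (equal to the drop concentration when the fold sits above y = 1/2)
ic50_from_inverse <- function(invfun, upper_guess) {
  yof <- function(aex) observable_from_inverse(invfun, aex)
  hi <- upper_guess
  while (yof(hi) > 0.5) hi <- hi * 2
  lo <- 0
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    if (yof(mid) > 0.5) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Single-drug dose-response curve with a constitutive resistance gene
#'
#' Upper-branch steady state of the single-drug system augmented by the
#' growth-coupled removal flux, computed from the exact inverse
#' [aex_of_y()].  Because expression falls with growth rate, the enzyme
#' introduces a positive feedback that raises the IC50 and steepens the
#' curve, up to an abrupt drop — even for drugs whose enzyme-free response
#' is monostable.
#'
#' @param kinetics a [drug_kinetics()] object (or bare alpha, converted via
#'   [shape_to_kinetics()]).
#' @param enzyme a [resistance_enzyme()] (or `NULL` for the baseline).
#' @param laws a [growth_laws()] object.
#' @param c_grid concentrations in IC50 units; with `normalize = "self"`
#'   (the plotting convention for resistant strains) the axis is rescaled
#'   to this curve's own numerically determined IC50, making steepness
#'   directly comparable across resistance levels; with `"baseline"` the
#'   enzyme-free IC50 is used, making the resistance shift visible.
#' @param normalize `"self"` or `"baseline"`; see `c_grid`.
#' @return A `dose_response_curve` with extra attributes `ic50_uM`
#'   (numerical IC50 of this curve, \eqn{\mu M}), `ic50_baseline_uM`, and
#'   `ic50_ratio`.
#' @export
cerg_dose_response <- function(kinetics, enzyme, laws, c_grid,
                               normalize = c("self", "baseline")) {
  normalize <- match.arg(normalize)
  if (!inherits(kinetics, "drug_kinetics"))
    kinetics <- shape_to_kinetics(kinetics, laws)
  stopifnot(all(c_grid >= 0), !is.unsorted(c_grid))
  shape <- reduce_kinetics(kinetics, laws)
  ic50_base <- ic50_model(kinetics, laws)
  invfun <- function(y) aex_of_y(y, kinetics, laws, enzyme)
  ic50_res <- ic50_from_inverse(invfun, shape$ic50)
  axis_uM <- if (normalize == "self") ic50_res else ic50_base
  targets <- c_grid * axis_uM
  y <- observable_from_inverse(invfun, targets)
  drop_c <- ic50_res / axis_uM
  branch <- ifelse(targets * (1 - 1e-12) <= ic50_res | y > 0.5,
                   "upper", "lower")
  out <- data.frame(concentration = c_grid, growth_relative = y,
                    branch = branch)
  structure(out, class = c("dose_response_curve", "data.frame"),
            alpha = shape$alpha, units = paste(normalize, "ic50"),
            branch_policy = "largest-stable-root",
            ic50_uM = ic50_res, ic50_baseline_uM = ic50_base,
            ic50_ratio = ic50_res / ic50_base)
}

# numerical IC50 (uM) of the full kinetic single-drug system, optionally
# with a resistance enzyme.  (The closed-form reduced IC50 of
# reduce_kinetics() is its fast transport/binding limit and is used only to
# seed the bracket.)
ic50_model <- function(kinetics, laws, enzyme = NULL) {
  shape <- reduce_kinetics(kinetics, laws)
  ic50_from_inverse(function(y) aex_of_y(y, kinetics, laws, enzyme),
                    shape$ic50)
}

#' Two-drug dose-response surface in the presence of resistance genes
#'
#' Pair steady states with both growth-coupled removal fluxes included.
#' With `rescale_axes = TRUE` (the plotting convention for resistant
#' strains) the concentration axes are re-normalised to the resistant
#' strain's numerically determined IC50s, so surfaces with different
#' resistance strengths are directly comparable.
#'
#' @param drugs list of two drugs (alphas, `response_shape`s or
#'   `drug_kinetics`).
#' @param deltas a [binding_modifiers()] object.
#' @param enzymes list of [resistance_enzyme()] objects (targets `"A"` and
#'   `"B"`), or `NULL`.
#' @param laws a [growth_laws()] object.
#' @param c_A,c_B concentration grids in IC50 units (resistant IC50s when
#'   `rescale_axes`, enzyme-free otherwise).
#' @param rescale_axes logical; see above.
#' @return A `dose_response_surface`; `meta$ic50_axis_uM` records the
#'   concentration scale used per axis.
#' @export
cerg_pair_surface <- function(drugs, deltas, enzymes, laws,
                              c_A = seq(0, 3, length.out = 121),
                              c_B = seq(0, 3, length.out = 121),
                              rescale_axes = TRUE) {
  kin <- lapply(drugs, function(d) {
    if (inherits(d, "drug_kinetics")) d else shape_to_kinetics(d, laws)
  })
  enz <- split_enzymes(enzymes)
  ic50_axis <- c(
    ic50_model(kin[[1]], laws, if (rescale_axes) enz$A else NULL),
    ic50_model(kin[[2]], laws, if (rescale_axes) enz$B else NULL))
  surf <- pair_surface(kin, deltas, laws,
                       c_A * ic50_axis[1], c_B * ic50_axis[2],
                       enzymes = enzymes, a_ex_units = TRUE)
  surf$c_A <- c_A
  surf$c_B <- c_B
  surf$meta$ic50_axis_uM <- ic50_axis
  surf$meta$rescale_axes <- rescale_axes
  surf
}

#' Model surface, Loewe reference and LI score for a resistant pair
#'
#' As [pair_interaction()], but with resistance enzymes: both the surface
#' and the Loewe additive reference are built for the resistant strain (the
#' reference from the exact resistant single-drug inverses), on axes
#' rescaled to the resistant IC50s.
#'
#' @inheritParams cerg_pair_surface
#' @param c_max,n concentration grid specification.
#' @return List with `surface`, `reference` and `score`.
#' @export
cerg_pair_interaction <- function(drugs, deltas, enzymes,
                                  laws = growth_laws(), c_max = 3, n = 121) {
  kin <- lapply(drugs, function(d) {
    if (inherits(d, "drug_kinetics")) d else shape_to_kinetics(d, laws)
  })
  enz <- split_enzymes(enzymes)
  grid <- seq(0, c_max, length.out = n)
  surf <- cerg_pair_surface(kin, deltas, enzymes, laws, grid, grid)
  ic50_axis <- surf$meta$ic50_axis_uM
  invA <- function(y) aex_of_y(y, kin[[1]], laws, enz$A) / ic50_axis[1]
  invB <- function(y) aex_of_y(y, kin[[2]], laws, enz$B) / ic50_axis[2]
  ref <- loewe_additive_surface(c_A = grid, c_B = grid,
                                inverse_A = invA, inverse_B = invB)
  list(surface = surf, reference = ref, score = li_score(surf, ref))
}

#' Steepness of a dose-response curve
#'
#' Maximal absolute finite-difference slope `|dy/dc|` on the
#' IC50-normalized concentration axis.  For curves with an abrupt drop the
#' metric grows with grid refinement; it is a comparative, grid-matched
#' measure.
#'
#' @param curve a `dose_response_curve` (>= 3 points).
#' @return Dimensionless steepness.
#' @examples
#' crv <- dose_response_curve(response_shape(4), seq(0, 3, 0.1))
#' steepness_metric(crv)
#' @export
steepness_metric <- function(curve) {
  stopifnot(inherits(curve, "dose_response_curve"))
  if (nrow(curve) < 3) stop("need at least 3 points")
  max(abs(diff(curve$growth_relative) / diff(curve$concentration)))
}
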