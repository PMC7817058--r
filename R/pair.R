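#' Binding-interaction modifiers for the second binding step
#'
#' Dimensionless factors scaling the on/off rates of one antibiotic on
#' ribosomes already bound by the other.  `delta_on = 0` for both drugs is
#' competitive binding (no double-bound ribosomes can form); all ones is
#' fully independent binding; `delta_on > 1` describes mutual stabilisation
#' (direct physical or allosteric interaction on the ribosome).
#'
#' @param delta_on_A,delta_on_B on-rate modifiers (>= 0).
#' @param delta_off_A,delta_off_B off-rate modifiers (>= 0).
#' @return An object of class `binding_modifiers`.
#' @examples
#' binding_modifiers()            # independent binding
#' binding_modifiers(0, 0)        # competitive binding
#' binding_modifiers(5, 5)        # symmetric stabilisation
#' @export
binding_modifiers <- function(delta_on_A = 1, delta_on_B = delta_on_A,
                              delta_off_A = 1, delta_off_B = delta_off_A) {
  stopifnot(delta_on_A >= 0, delta_on_B >= 0,
            delta_off_A >= 0, delta_off_B >= 0)
  structure(list(delta_on_A = delta_on_A, delta_on_B = delta_on_B,
                 delta_off_A = delta_off_A, delta_off_B = delta_off_B),
            class = "binding_modifiers")
}

#' @export
print.binding_modifiers <- function(x, ...) {
  cat(sprintf("Binding modifiers: delta_on = (%.3g, %.3g), delta_off = (%.3g, %.3g)",
              x$delta_on_A, x$delta_on_B, x$delta_off_A, x$delta_off_B))
  if (x$delta_on_A == 0 && x$delta_on_B == 0) cat("  [competitive]")
  else if (all(unlist(x) == 1)) cat("  [independent]")
  cat("\n")
  invisible(x)
}

# internal: kinetics + optional enzyme -> parameter list for the C++ solver
solver_par <- function(kinetics, enzyme = NULL) {
  list(p_in = kinetics$p_in, p_out = kinetics$p_out,
       k_on = kinetics$k_on, k_off = kinetics$k_off,
       v_max_prime = if (is.null(enzyme)) 0 else enzyme$v_max_prime,
       k_rem = if (is.null(enzyme)) 1 else enzyme$k_rem)
}

solver_laws <- function(laws) {
  laws[c("kappa_t", "r_min", "r_max", "delta_r", "lambda0")]
}

# split an enzymes argument (NULL, single enzyme, or list of up to two with
# $target "A"/"B") into per-drug slots
split_enzymes <- function(enzymes) {
  out <- list(A = NULL, B = NULL)
  if (is.null(enzymes)) return(out)
  if (inherits(enzymes, "resistance_enzyme")) enzymes <- list(enzymes)
  for (e in enzymes) {
    stopifnot(inherits(e, "resistance_enzyme"))
    if (!is.null(out[[e$target]]))
      stop("more than one enzyme per drug (no cross-resistance modelled)")
    out[[e$target]] <- e
  }
  out
}

#' Time derivatives of the two-drug kinetic system
#'
#' Right-hand side of the six-variable mass-action model with two
#' intracellular drug pools, unbound ribosomes, two single-bound pools and
#' the double-bound pool `r_d`.  The terms `delta_on_i * k_on_i * a_i *
#' r_b_ibar` (drug *i* binding a ribosome that already carries the other
#' drug) and `delta_off_i * k_off_i * r_d` (drug *i* leaving a double-bound
#' ribosome) couple the drugs; when `delta_on = 0` for both, `r_d` has no
#' source and the system reduces term-by-term to two single-drug models
#' sharing the ribosome pool.
#'
#' @param state numeric vector `(a_A, a_B, r_u, r_b_A, r_b_B, r_d)`,
#'   \eqn{\mu M}.
#' @param a_ex length-2 vector of extracellular concentrations, \eqn{\mu M}.
#' @param kinetics list of two [drug_kinetics()] objects (A, B).
#' @param deltas a [binding_modifiers()] object.
#' @param laws a [growth_laws()] object.
#' @param enzymes optional [resistance_enzyme()] or list of two.
#' @return Numeric vector of the six time derivatives, same order as
#'   `state`.
#' @export
pair_rhs <- function(state, a_ex, kinetics, deltas, laws, enzymes = NULL) {
  a <- state[1:2]; r_u <- state[3]; r_b <- state[4:5]; r_d <- state[6]
  kA <- kinetics[[1]]; kB <- kinetics[[2]]
  enz <- split_enzymes(enzymes)
  lambda <- laws$kappa_t * max(r_u - laws$r_min, 0)
  free <- max(r_u - laws$r_min, 0)
  k_on <- c(kA$k_on, kB$k_on); k_off <- c(kA$k_off, kB$k_off)
  p_in <- c(kA$p_in, kB$p_in); p_out <- c(kA$p_out, kB$p_out)
  don <- c(deltas$delta_on_A, deltas$delta_on_B)
  doff <- c(deltas$delta_off_A, deltas$delta_off_B)
  f <- -k_on * a * free + k_off * r_b
  J <- p_in * a_ex - p_out * a
  oth <- c(2, 1)
  da <- -lambda * a + f + doff * k_off * r_d -
    don * k_on * a * r_b[oth] + J
  for (i in 1:2) {
    e <- enz[[c("A", "B")[i]]]
    if (!is.null(e))
      da[i] <- da[i] - removal_flux(e, lambda / laws$lambda0, a[i])
  }
  drb <- -lambda * r_b - f + doff[oth] * k_off[oth] * r_d -
    don[oth] * k_on[oth] * a[oth] * r_b
  drd <- -lambda * r_d + sum(don * k_on * a * r_b[oth]) -
    sum(doff * k_off) * r_d
  dru <- -lambda * r_u + sum(f) + s_of_lambda(laws, lambda)
  c(da, dru, drb, drd)
}

#' Upper-branch steady state of the two-drug system
#'
#' Locates the population-observable fixed point of [pair_rhs()] at given
#' external concentrations: at fixed growth rate the remaining steady-state
#' equations are solved exactly, and the ribosome-balance residual is
#' driven to zero by scanning growth rate downward from `lambda0` and
#' bisecting the first (i.e. largest) root.
#'
#' @param a_ex length-2 vector of extracellular concentrations, \eqn{\mu M}.
#' @param kinetics list of two [drug_kinetics()] objects.
#' @param deltas a [binding_modifiers()] object.
#' @param laws a [growth_laws()] object.
#' @param enzymes optional resistance enzyme(s).
#' @param lambda_hint optional warm-start growth rate, \eqn{h^{-1}}.
#' @return List with `y` (relative growth), `lambda`, the steady `state`
#'   vector `(a_A, a_B, r_u, r_b_A, r_b_B, r_d)`, `balance_residual`, and
#'   `converged`.
#' @export
pair_steady_state <- function(a_ex, kinetics, deltas, laws, enzymes = NULL,
                              lambda_hint = NULL) {
  stopifnot(length(a_ex) == 2, all(a_ex >= 0))
  enz <- split_enzymes(enzymes)
  res <- pair_point_cpp(a_ex[1], a_ex[2],
                        solver_par(kinetics[[1]], enz$A),
                        solver_par(kinetics[[2]], enz$B),
                        unclass(deltas), solver_laws(laws),
                        lam_warm = if (is.null(lambda_hint)) -1 else lambda_hint)
  state <- c(a_A = res$a_A, a_B = res$a_B, r_u = res$r_u,
             r_b_A = res$r_b_A, r_b_B = res$r_b_B, r_d = res$r_d)
  rhs <- pair_rhs(state, a_ex, kinetics, deltas, laws, enzymes)
  conv <- max(abs(rhs)) < 1e-6 * max(1, laws$r_max) ||
    res$lambda <= 1e-10 * laws$lambda0
  if (!conv)
    warning(sprintf("pair steady state poorly converged at a_ex = (%g, %g): max |rhs| = %g",
                    a_ex[1], a_ex[2], max(abs(rhs))))
  list(y = res$y, lambda = res$lambda, state = state,
       balance_residual = res$balance_residual, rhs = rhs, converged = conv)
}

#' Two-drug dose-response surface
#'
#' Computes relative growth `y(c_A, c_B)` on a concentration grid by the
#' upper-branch steady-state solver, warm-starting each grid point from its
#' neighbour (continuation).  Drugs may be given as `response_shape`s /
#' bare `alpha`s (converted to concrete kinetics by [shape_to_kinetics()])
#' or as `drug_kinetics`.
#'
#' @param drugs list of two drugs: `response_shape`, numeric alpha, or
#'   `drug_kinetics`.
#' @param deltas a [binding_modifiers()] object.
#' @param laws a [growth_laws()] object.
#' @param c_A,c_B sorted concentration grids starting at 0, in IC50 units
#'   (of each drug's enzyme-free IC50 unless `a_ex_units = TRUE`).
#' @param enzymes optional resistance enzyme(s).
#' @param a_ex_units if `TRUE`, `c_A`/`c_B` are already extracellular
#'   concentrations in \eqn{\mu M}.
#' @return Object of class `dose_response_surface`: list with `c_A`, `c_B`,
#'   matrix `y` (rows = `c_A`), and `meta` (parameters, IC50s used).
#' @examples
#' \donttest{
#' laws <- growth_laws()
#' s <- pair_surface(list(4, 4), binding_modifiers(), laws,
#'                   seq(0, 3, length.out = 31), seq(0, 3, length.out = 31))
#' s$y[1, 1]  # 1 at the origin
#' }
#' @export
pair_surface <- function(drugs, deltas, laws,
                         c_A = seq(0, 3, length.out = 121),
                         c_B = seq(0, 3, length.out = 121),
                         enzymes = NULL, a_ex_units = FALSE) {
  stopifnot(length(drugs) == 2, !is.unsorted(c_A), !is.unsorted(c_B),
            all(c_A >= 0), all(c_B >= 0))
  kin <- lapply(drugs, function(d) {
    if (inherits(d, "drug_kinetics")) d else shape_to_kinetics(d, laws)
  })
  shapes <- lapply(kin, reduce_kinetics, laws = laws)
  enz <- split_enzymes(enzymes)
  if (a_ex_units) {
    aexA <- c_A; aexB <- c_B
    ic50 <- c(NA_real_, NA_real_)
  } else {
    # normalize by the full model's own IC50s so that c = 1 halves growth
    # exactly on each axis (the closed-form reduced IC50 differs by the
    # fast-kinetics approximation)
    ic50 <- c(ic50_model(kin[[1]], laws), ic50_model(kin[[2]], laws))
    aexA <- c_A * ic50[1]; aexB <- c_B * ic50[2]
  }
  y <- pair_grid_cpp(aexA, aexB,
                     solver_par(kin[[1]], enz$A), solver_par(kin[[2]], enz$B),
                     unclass(deltas), solver_laws(laws))
  structure(
    list(c_A = c_A, c_B = c_B, y = y,
         meta = list(alpha = c(shapes[[1]]$alpha, shapes[[2]]$alpha),
                     ic50 = ic50, deltas = unclass(deltas),
                     kinetics = lapply(kin, unclass),
                     enzymes = lapply(enz, function(e)
                       if (is.null(e)) NULL else unclass(e)),
                     laws = unclass(laws), a_ex_units = a_ex_units)),
    class = "dose_response_surface")
}

#' Construct a dose-response surface object from raw grids
#'
#' Used when scoring externally measured checkerboards.
#'
#' @param c_A,c_B concentration grids.
#' @param y growth matrix (rows = `c_A`).
#' @param meta optional metadata list.
#' @return A `dose_response_surface` object.
#' @export
dose_response_surface <- function(c_A, c_B, y, meta = list()) {
  y <- as.matrix(y)
  stopifnot(nrow(y) == length(c_A), ncol(y) == length(c_B))
  structure(list(c_A = c_A, c_B = c_B, y = y, meta = meta),
            class = "dose_response_surface")
}

#' @export
print.dose_response_surface <- function(x, ...) {
  cat(sprintf("Dose-response surface: %d x %d grid, c_A in [%g, %g], c_B in [%g, %g]\n",
              length(x$c_A), length(x$c_B), min(x$c_A), max(x$c_A),
              min(x$c_B), max(x$c_B)))
  if (!is.null(x$meta$alpha))
    cat(sprintf("  alpha = (%.4g, %.4g)\n", x$meta$alpha[1], x$meta$alpha[2]))
  cat(sprintf("  y range [%.4g, %.4g]\n", min(x$y), max(x$y)))
  invisible(x)
}

#' @export
as.data.frame.dose_response_surface <- function(x, ...) {
  data.frame(c_A = rep(x$c_A, times = length(x$c_B)),
             c_B = rep(x$c_B, each = length(x$c_A)),
             y = as.vector(x$y))
}

#' @export
plot.dose_response_surface <- function(x, ...) {
  graphics::image(x$c_A, x$c_B, x$y, xlab = "c_A", ylab = "c_B",
                  col = grey.colors(64, 0, 1), ...)
  graphics::contour(x$c_A, x$c_B, x$y, add = TRUE)
  invisible(x)
}

#' Exact-additivity certificate for competitive binding
#'
#' When double-bound ribosomes cannot form (`delta_on = 0`), the isoboles
#' of the two-drug model are exactly linear:
#' \eqn{\Delta r(1-\lambda/\lambda_0) = a_{ex,A}\Upsilon_A \xi_A +
#' a_{ex,B}\Upsilon_B\xi_B}, with binding coefficient
#' \eqn{\xi_i = k_{on,i}\lambda/[(k_{off,i}+\lambda)\kappa_t]} and transport
#' coefficient \eqn{\Upsilon_i = p_{in,i}/[\lambda(k_{on,i}/\kappa_t+1) +
#' p_{out,i} - \xi_i k_{off,i}]}, both functions of \eqn{\lambda} and drug
#' *i*'s kinetics only.  This function computes the coefficients and traces
#' the numerical isobole of the competitive-binding surface, reporting the
#' maximal relative deviation from the linear prediction.
#'
#' @param kinetics list of two [drug_kinetics()] objects.
#' @param laws a [growth_laws()] object.
#' @param lambda_target isobole growth rate, \eqn{h^{-1}}, in
#'   `(0, lambda0)`.
#' @param n_points number of points along the trace.
#' @return List of class `additivity_certificate` with `xi`, `upsilon`,
#'   `isobole_gap` (max relative deviation) and the traced isobole.
#' @export
additivity_certificate <- function(kinetics, laws, lambda_target,
                                   n_points = 50) {
  stopifnot(lambda_target > 0, lambda_target < laws$lambda0)
  lam <- lambda_target
  xi <- vapply(kinetics, function(k)
    k$k_on * lam / ((k$k_off + lam) * laws$kappa_t), numeric(1))
  upsilon <- vapply(seq_along(kinetics), function(i) {
    k <- kinetics[[i]]
    k$p_in / (lam * (k$k_on / laws$kappa_t + 1) + k$p_out - xi[i] * k$k_off)
  }, numeric(1))
  rb_target <- laws$delta_r * (1 - lam / laws$lambda0)
  aA_max <- rb_target / (upsilon[1] * xi[1])
  aB_max <- rb_target / (upsilon[2] * xi[2])
  deltas <- binding_modifiers(0, 0, 1, 1)
  aA <- seq(0, aA_max, length.out = n_points + 1)[seq_len(n_points)]
  aB_lin <- (rb_target - aA * upsilon[1] * xi[1]) / (upsilon[2] * xi[2])
  aB_num <- vapply(seq_along(aA), function(i) {
    f <- function(ab)
      pair_steady_state(c(aA[i], ab), kinetics, deltas, laws)$lambda - lam
    stats::uniroot(f, lower = 0, upper = aB_max * 1.5, tol = 1e-13,
                   extendInt = "downX")$root
  }, numeric(1))
  gap <- max(abs(aB_num - aB_lin)) / aB_max
  structure(list(xi_A = xi[1], xi_B = xi[2],
                 upsilon_A = upsilon[1], upsilon_B = upsilon[2],
                 lambda_target = lam, isobole_gap = gap,
                 trace = data.frame(a_ex_A = aA, a_ex_B_linear = aB_lin,
                                    a_ex_B_numeric = aB_num)),
            class = "additivity_certificate")
}

#' @export
print.additivity_certificate <- function(x, ...) {
  cat(sprintf("Additivity certificate at lambda = %.4g h^-1\n",
              x$lambda_target))
  cat(sprintf("  xi = (%.5g, %.5g), Upsilon = (%.5g, %.5g)\n",
              x$xi_A, x$xi_B, x$upsilon_A, x$upsilon_B))
  cat(sprintf("  max relative isobole deviation from linearity: %.3g\n",
              x$isobole_gap))
  invisible(x)
}

#' Rescaled concentration of the slow-growth limit
#'
#' \eqn{c_i' = c_i (\alpha_i^2+1)\lambda_{max}/(\alpha_i^2 \lambda_0)}; the
#' natural dose variable of the analytic slow-growth solutions.
#'
#' @param c normalized concentration(s), IC50 units.
#' @param shape a [response_shape()] or bare alpha (> 0; the limit is not
#'   defined for irreversible binders).
#' @param laws a [growth_laws()] object.
#' @return Rescaled concentration(s).
#' @export
c_prime <- function(c, shape, laws) {
  alpha <- if (inherits(shape, "response_shape")) shape$alpha else shape
  if (alpha <= 0) stop("c_prime undefined for alpha = 0")
  c * (alpha^2 + 1) * laws$lambda_max / (alpha^2 * laws$lambda0)
}

#' Analytic slow-growth dose-response surface
#'
#' Closed-form relative growth in the limit of reversibly binding
#' antibiotics with fast kinetics at low growth rates:
#' \deqn{y \approx \frac{\lambda_{max}}{\lambda_0}\,
#'   \frac{\delta_{off,A}+\delta_{off,B}+c_A'\delta_{on,A}\delta_{off,B}
#'         +c_B'\delta_{on,B}\delta_{off,A}}
#'        {(1+c_A'+c_B')[\delta_{off,B}\Phi_A+\delta_{off,A}\Phi_B]
#'         + c_A' c_B' \Phi_{AB}}}
#' with \eqn{\Phi_A = 1+c_A'\delta_{on,A}}, \eqn{\Phi_B = 1+c_B'\delta_{on,B}},
#' \eqn{\Phi_{AB} = \delta_{on,A}+\delta_{on,B}+\delta_{on,A}\delta_{on,B}
#' (c_A'+c_B')}.  Special cases are dispatched to their exact reduced
#' forms: all deltas 1 gives the Bliss-like product
#' \eqn{(\lambda_{max}/\lambda_0)/[(1+c_A')(1+c_B')]}; `delta_on = 0` gives
#' the Loewe form \eqn{(\lambda_{max}/\lambda_0)/(1+c_A'+c_B')};
#' `delta_on_i = delta`, `delta_off_i = 1` gives
#' \eqn{(\lambda_{max}/\lambda_0)/(1+c_A'+c_B'+\delta c_A' c_B')}.
#'
#' @param c_prime_A,c_prime_B rescaled concentrations (vectors; the surface
#'   is evaluated on their outer grid).
#' @param deltas a [binding_modifiers()] object.
#' @param laws a [growth_laws()] object.
#' @return Matrix of `y` values (rows = `c_prime_A`).
#' @export
slow_growth_surface <- function(c_prime_A, c_prime_B, deltas, laws) {
  stopifnot(all(c_prime_A >= 0), all(c_prime_B >= 0))
  k <- laws$lambda_max / laws$lambda0
  dA <- deltas$delta_on_A; dB <- deltas$delta_on_B
  oA <- deltas$delta_off_A; oB <- deltas$delta_off_B
  cA <- matrix(c_prime_A, length(c_prime_A), length(c_prime_B))
  cB <- matrix(c_prime_B, length(c_prime_A), length(c_prime_B), byrow = TRUE)
  if (dA == 0 && dB == 0)
    return(k / (1 + cA + cB))
  if (oA == 1 && oB == 1 && dA == dB) {
    if (dA == 1) return(k / ((1 + cA) * (1 + cB)))
    return(k / (1 + cA + cB + dA * cA * cB))
  }
  phiA <- 1 + cA * dA
  phiB <- 1 + cB * dB
  phiAB <- dA + dB + dA * dB * (cA + cB)
  num <- oA + oB + cA * dA * oB + cB * dB * oA
  den <- (1 + cA + cB) * (oB * phiA + oA * phiB) + cA * cB * phiAB
  k * num / den
}
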