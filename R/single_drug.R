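#' Closed-form inverse dose-response of a single translation inhibitor
#'
#' The steady-state relation between relative growth \eqn{y =
#' \lambda/\lambda_0} and normalized extracellular concentration \eqn{c =
#' a_{ex}/IC_{50}} inverts in closed form:
#' \deqn{c(y) = \frac{(1-y)(4y^2 + \alpha^2)}{y(\alpha^2+1)}.}
#' No iteration is involved; `c(1) = 0` and `c(1/2) = 1` for every `alpha`.
#'
#' @param alpha response parameter (>= 0).
#' @param y relative growth rate(s) in (0, 1]; vectorized.
#' @return Normalized concentration(s) `c` in IC50 units.
#' @examples
#' inverse_dose_response(0.5, c(1, 0.5))  # 0 and 1
#' @export
inverse_dose_response <- function(alpha, y) {
  stopifnot(alpha >= 0)
  if (any(y <= 0)) stop("y must be positive")
  (1 - y) * (4 * y^2 + alpha^2) / (y * (alpha^2 + 1))
}

# dc/dy of the closed form; its sign is the 1-D stability criterion
# (stable branches have dc/dy < 0)
dcdy <- function(alpha, y) (4 - alpha^2 / y^2 - 8 * y) / (alpha^2 + 1)

#' Critical response parameter for growth bistability
#'
#' Below \eqn{\alpha_{crit} = 2/(3\sqrt 3) \approx 0.385} the concentration-
#' growth relation `c(y)` is non-monotonic on (0, 1) and the steady-state
#' cubic admits two stable growth rates over a window of concentrations.
#'
#' @return The exact value `2 / (3 * sqrt(3))`.
#' @export
alpha_crit <- function() 2 / (3 * sqrt(3))

#' Bracket the bistability threshold by a monotonicity scan
#'
#' Independent numerical route to [alpha_crit()]: for each trial `alpha`,
#' `c(y)` is tested for non-monotonicity on a fine grid in (0, 1); the
#' largest non-monotonic `alpha` is bracketed by bisection.
#'
#' @param tol bracketing tolerance on alpha.
#' @param n_y number of grid points used in the monotonicity test.
#' @return Numerically bracketed threshold (midpoint of final bracket).
#' @export
alpha_crit_scan <- function(tol = 1e-8, n_y = 4001) {
  y <- seq(1e-4, 1 - 1e-4, length.out = n_y)
  nonmono <- function(alpha) any(diff(inverse_dose_response(alpha, y)) > 0)
  lo <- 0.1; hi <- 1
  stopifnot(nonmono(lo), !nonmono(hi))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (nonmono(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Concentration window of bistability
#'
#' For `alpha < alpha_crit()` the fold points are the roots of
#' \eqn{4y^2(1-2y) = \alpha^2} in (0, 1/2); mapping them through the
#' closed-form `c(y)` gives the concentration interval inside which two
#' stable growth rates coexist.
#'
#' @param alpha response parameter (>= 0).
#' @return Ordered numeric interval `c(lower, upper)` in IC50 units, or
#'   `NULL` when `alpha >= alpha_crit()` (no bistability).
#' @export
bistable_window <- function(alpha) {
  stopifnot(alpha >= 0)
  if (alpha^2 >= 4 / 27) return(NULL)
  if (alpha == 0) return(c(0, 1))  # folds at y -> 0 and y = 1/2
  f <- function(y) 4 * y^2 * (1 - 2 * y) - alpha^2
  y_lo <- stats::uniroot(f, c(1e-12, 1 / 3), tol = 1e-14)$root
  y_hi <- stats::uniroot(f, c(1 / 3, 1 / 2 - 1e-14), tol = 1e-14)$root
  sort(c(inverse_dose_response(alpha, y_lo),
         inverse_dose_response(alpha, y_hi)))
}

#' Steady-state growth rates at a given concentration
#'
#' Solves the steady-state cubic
#' \eqn{4y^3 - 4y^2 + [\alpha^2 + c(\alpha^2+1)]y - \alpha^2 = 0}
#' for all real roots in (0, 1] and classifies their stability by the sign
#' of `dc/dy` (middle root of three is unstable).  The irreversible limit
#' `alpha = 0` is handled by its exact quadratic factorisation rather than
#' as a degenerate cubic.
#'
#' @param alpha response parameter (>= 0).
#' @param c normalized concentration (scalar, >= 0).
#' @return An object of class `steady_state_set`: data frame with columns
#'   `y` (descending) and `stable`.
#' @export
steady_state_growth <- function(alpha, c) {
  stopifnot(alpha >= 0, length(c) == 1, c >= 0)
  if (alpha == 0) {
    # y (4y^2 - 4y + c) = 0; positive roots (1 +/- sqrt(1-c))/2
    if (c > 1) y <- numeric(0)
    else if (c == 0) y <- 1
    else {
      s <- sqrt(1 - c)
      y <- c((1 + s) / 2, (1 - s) / 2)
      y <- y[y > 0]
    }
  } else {
    co <- c(-alpha^2, alpha^2 + c * (alpha^2 + 1), -4, 4)
    z <- polyroot(co)
    y <- Re(z[abs(Im(z)) < 1e-8 * (abs(z) + 1)])
    # Newton polish on the cubic
    for (i in seq_len(3)) {
      p <- ((4 * y - 4) * y + co[2]) * y + co[1]
      dp <- (12 * y - 8) * y + co[2]
      y <- y - p / dp
    }
    y <- sort(unique(round(y, 14)), decreasing = TRUE)
    y <- y[y > 1e-14 & y <= 1 + 1e-12]
    y <- pmin(y, 1)
  }
  y <- sort(y, decreasing = TRUE)
  stable <- if (length(y) == 3) c(TRUE, FALSE, TRUE) else
    dcdy(alpha, y) < 0 | y == 1
  structure(data.frame(y = y, stable = stable),
            class = c("steady_state_set", "data.frame"))
}

# upper edge of the bistable window (Inf when monostable): concentration at
# which the upper branch folds
upper_fold_c <- function(alpha) {
  w <- bistable_window(alpha)
  if (is.null(w)) Inf else w[2]
}

# observable (population) branch: largest real root at each concentration;
# beyond the fold only the low root survives, producing the abrupt drop
observable_y <- function(alpha, c_vals) {
  vapply(c_vals, function(cc) {
    r <- steady_state_growth(alpha, cc)
    if (nrow(r) == 0) 0 else max(r$y)
  }, numeric(1))
}

#' Single-drug dose-response curve (upper-branch policy)
#'
#' Reports, per concentration, the largest stable steady-state growth rate:
#' the branch that dominates batch cultures.  Inside the bistable window
#' the high-growth branch is reported up to its fold, beyond which the
#' curve drops discontinuously to the low-growth branch.
#'
#' @param shape a [response_shape()] object or a bare `alpha`.
#' @param c_grid sorted non-negative concentrations in IC50 units (or
#'   \eqn{\mu M} with `units = "uM"`, requiring `shape$ic50`).
#' @param units `"ic50"` (default) or `"uM"`.
#' @return Object of class `dose_response_curve`: data frame with columns
#'   `concentration`, `growth_relative`, `branch`, plus attributes `alpha`,
#'   `units`, `branch_policy`.
#' @examples
#' crv <- dose_response_curve(response_shape(4), seq(0, 3, 0.5))
#' crv$growth_relative[1]  # 1 at c = 0
#' @export
dose_response_curve <- function(shape, c_grid, units = c("ic50", "uM")) {
  units <- match.arg(units)
  if (inherits(shape, "response_shape")) alpha <- shape$alpha
  else { alpha <- shape; shape <- response_shape(alpha) }
  stopifnot(all(c_grid >= 0), !is.unsorted(c_grid))
  cc <- c_grid
  if (units == "uM") {
    if (!is.finite(shape$ic50)) stop("uM units need shape$ic50")
    cc <- c_grid / shape$ic50
  }
  y <- observable_y(alpha, cc)
  c_up <- upper_fold_c(alpha)
  branch <- ifelse(cc <= c_up, "upper", "lower")
  out <- data.frame(concentration = c_grid, growth_relative = y,
                    branch = branch)
  structure(out, class = c("dose_response_curve", "data.frame"),
            alpha = alpha, units = units,
            branch_policy = "largest-stable-root")
}

#' @export
print.dose_response_curve <- function(x, ...) {
  cat(sprintf("Dose-response curve (alpha = %.5g, %d points, %s units)\n",
              attr(x, "alpha"), nrow(x), attr(x, "units")))
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("  ...\n")
  invisible(x)
}

#' @export
plot.dose_response_curve <- function(x, ...) {
  plot(x$concentration, x$growth_relative, type = "l",
       xlab = sprintf("concentration (%s)", attr(x, "units")),
       ylab = "relative growth rate y", ylim = c(0, 1), ...)
  invisible(x)
}

#' Time derivatives of the single-drug kinetic system
#'
#' Right-hand side of the three-variable mass-action model: intracellular
#' drug `a`, unbound ribosomes `r_u`, bound ribosomes `r_b`.  Growth rate is
#' \eqn{\lambda = \kappa_t \max(r_u - r_{min}, 0)}; ribosome synthesis
#' follows \eqn{s(\lambda) = \lambda\, r_{tot}(\lambda)}; only translating
#' ribosomes \eqn{(r_u - r_{min})} can be bound.  An optional resistance
#' enzyme adds a growth-coupled Michaelis-Menten removal flux to `da/dt`.
#'
#' @param state named or positional numeric vector `(a, r_u, r_b)` in
#'   \eqn{\mu M}.
#' @param a_ex extracellular drug concentration, \eqn{\mu M}.
#' @param kinetics a [drug_kinetics()] object.
#' @param laws a [growth_laws()] object.
#' @param enzyme optional [resistance_enzyme()].
#' @return Numeric vector `(da/dt, dr_u/dt, dr_b/dt)`.
#' @export
single_drug_rhs <- function(state, a_ex, kinetics, laws, enzyme = NULL) {
  a <- state[[1]]; r_u <- state[[2]]; r_b <- state[[3]]
  lambda <- laws$kappa_t * max(r_u - laws$r_min, 0)
  free <- max(r_u - laws$r_min, 0)
  f <- -kinetics$k_on * a * free + kinetics$k_off * r_b
  J <- kinetics$p_in * a_ex - kinetics$p_out * a
  da <- -lambda * a + f + J
  if (!is.null(enzyme))
    da <- da - removal_flux(enzyme, lambda / laws$lambda0, a)
  dru <- -lambda * r_u + f + s_of_lambda(laws, lambda)
  drb <- -lambda * r_b - f
  c(da, dru, drb)
}

# drug-free fixed point of the single-drug system
drug_free_state <- function(laws) {
  c(a = 0, r_u = laws$r_min + laws$lambda0 / laws$kappa_t, r_b = 0)
}

#' Integrate the single-drug system to steady state
#'
#' Time integration from the drug-free inoculum; the dynamical route to the
#' population-observable branch.  Mainly used to cross-check the algebraic
#' steady state.
#'
#' @inheritParams single_drug_rhs
#' @param t_end integration horizon, h.
#' @param ... passed to [deSolve::ode()].
#' @return Final state vector `(a, r_u, r_b)`.
#' @export
integrate_single_drug <- function(a_ex, kinetics, laws, enzyme = NULL,
                                  t_end = 2000 / laws$lambda0, ...) {
  rhs <- function(t, y, p) list(single_drug_rhs(y, a_ex, kinetics, laws,
                                                enzyme))
  out <- deSolve::ode(y = drug_free_state(laws), times = c(0, t_end),
                      func = rhs, parms = NULL,
                      rtol = 1e-11, atol = 1e-11, ...)
  st <- out[nrow(out), -1]
  names(st) <- c("a", "r_u", "r_b")
  st
}
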