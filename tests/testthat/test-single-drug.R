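test_that("closed-form inverse dose-response has its anchor points", {
  for (alpha in c(0, 0.1, 0.3849, 1, 4, 128)) {
    expect_equal(inverse_dose_response(alpha, 1), 0)
    expect_equal(inverse_dose_response(alpha, 0.5), 1)
  }
  expect_error(inverse_dose_response(1, 0), "positive")
  # stationary point of c(y) at the bifurcation: alpha^2 = 4/27, y = 1/3
  a <- sqrt(4 / 27)
  expect_equal(inverse_dose_response(a, 1 / 3), 32 / 31, tolerance = 1e-14)
  eps <- 1e-7
  dnum <- (inverse_dose_response(a, 1 / 3 + eps) -
           inverse_dose_response(a, 1 / 3 - eps)) / (2 * eps)
  expect_lt(abs(dnum), 1e-6)
})

test_that("bistability threshold equals 2/(3 sqrt 3) by independent oracles", {
  # oracle 1: maximize 4 y^2 (1 - 2y) on (0, 1/2)
  opt <- optimize(function(y) 4 * y^2 * (1 - 2 * y), c(0, 0.5),
                  maximum = TRUE, tol = 1e-12)
  expect_equal(opt$maximum, 1 / 3, tolerance = 1e-6)
  expect_equal(sqrt(opt$objective), alpha_crit(), tolerance = 1e-10)
  # oracle 2: monotonicity scan of the closed form
  expect_equal(alpha_crit_scan(1e-8), alpha_crit(), tolerance = 1e-6)
  expect_equal(alpha_crit(), 2 / (3 * sqrt(3)))
})

test_that("bistable window closes at alpha_crit and opens to (0,1) at 0", {
  expect_null(bistable_window(0.5))
  expect_null(bistable_window(alpha_crit()))
  expect_equal(bistable_window(0), c(0, 1))
  w <- bistable_window(0.2)
  expect_length(w, 2)
  expect_true(w[1] < w[2])
  # fold points solve 4y^2(1-2y) = alpha^2 (root-finding oracle)
  y_lo <- uniroot(function(y) 4 * y^2 * (1 - 2 * y) - 0.04, c(1e-9, 1 / 3),
                  tol = 1e-14)$root
  y_hi <- uniroot(function(y) 4 * y^2 * (1 - 2 * y) - 0.04, c(1 / 3, 0.5),
                  tol = 1e-14)$root
  expect_equal(sort(c(inverse_dose_response(0.2, y_lo),
                      inverse_dose_response(0.2, y_hi))), w,
               tolerance = 1e-10)
  # window shrinks as alpha grows towards the threshold
  w2 <- bistable_window(0.35)
  expect_lt(diff(w2), diff(w))
})

test_that("cubic steady states match the closed form and classify stability", {
  # three roots inside the window, outer two stable
  r <- steady_state_growth(0.2, 0.9)
  expect_equal(nrow(r), 3)
  expect_equal(r$stable, c(TRUE, FALSE, TRUE))
  expect_true(all(diff(r$y) < 0))
  # mutual inverse: c(y_root) recovers the concentration
  for (alpha in c(0.1, 0.2, 1, 4)) {
    for (cc in c(0.2, 0.8, 1.5, 2.9)) {
      r <- steady_state_growth(alpha, cc)
      for (y in r$y)
        expect_lt(abs(inverse_dose_response(alpha, y) - cc), 1e-10)
    }
  }
  # single stable root at c = 0 and in the monostable regime
  expect_equal(steady_state_growth(1, 0)$y, 1)
  r <- steady_state_growth(1, 2)
  expect_equal(nrow(r), 1)
  expect_true(r$stable)
  # alpha >> 1: y ~ 1/(1+c)
  r <- steady_state_growth(100, 3)
  expect_equal(nrow(r), 1)
  expect_equal(r$y, 1 / 4, tolerance = 1e-3)
})

test_that("closed-form roots agree with brute-force cubic extraction on a lattice", {
  for (alpha in 2^seq(-7, 7, by = 1)) {
    for (y in seq(0.02, 0.98, by = 0.04)) {
      cc <- inverse_dose_response(alpha, y)
      co <- c(-alpha^2, alpha^2 + cc * (alpha^2 + 1), -4, 4)
      z <- polyroot(co)
      roots <- Re(z[abs(Im(z)) < 1e-7])
      expect_lt(min(abs(roots - y)), 1e-10)
      expect_true(any(abs(steady_state_growth(alpha, cc)$y - y) < 1e-10))
    }
  }
})

test_that("dose-response curves follow the upper-branch policy", {
  # shallow: smooth, monotone
  crv <- dose_response_curve(response_shape(4), seq(0, 3, by = 0.05))
  expect_equal(crv$growth_relative[1], 1)
  expect_true(all(diff(crv$growth_relative) <= 0))
  expect_true(all(crv$growth_relative >= 0 & crv$growth_relative <= 1))
  expect_true(all(crv$branch == "upper"))
  # steep: discontinuous drop at the upper window edge
  alpha <- 2^-5
  w <- bistable_window(alpha)
  cg <- sort(c(seq(0, 3, by = 0.02), w[2] * c(0.999, 1.001)))
  crv <- dose_response_curve(response_shape(alpha), cg)
  jump <- max(abs(diff(crv$growth_relative)))
  expect_gt(jump, 0.4)
  i <- which.max(abs(diff(crv$growth_relative)))
  expect_equal(crv$concentration[i], w[2], tolerance = 2e-2)
  # uM units route
  sh <- reduce_kinetics(canon_kin(1), laws_default)
  crv_uM <- dose_response_curve(sh, c(0, sh$ic50), units = "uM")
  expect_equal(crv_uM$growth_relative[2], 0.5, tolerance = 1e-9)
})

test_that("high- and low-alpha limiting curves are reproduced", {
  cg <- seq(0, 10, by = 0.05)
  crv <- dose_response_curve(response_shape(2^7), cg)
  expect_lt(max(abs(crv$growth_relative - 1 / (1 + cg))), 1e-3)
  cg2 <- seq(0, 0.96, by = 0.005)
  crv2 <- dose_response_curve(response_shape(2^-7), cg2)
  expect_lt(max(abs(crv2$growth_relative - (1 + sqrt(1 - cg2)) / 2)), 1e-3)
})

test_that("drug-free state is a fixed point of the kinetic system", {
  laws <- laws_default
  kin <- canon_kin(1)
  st <- ribocomb:::drug_free_state(laws)
  expect_equal(single_drug_rhs(st, 0, kin, laws), c(0, 0, 0),
               tolerance = 1e-12)
  # with k_off = 0 bound ribosomes leave only by dilution
  kin0 <- drug_kinetics(100, 10, 1000, 0)
  st2 <- c(a = 0.01, r_u = 30, r_b = 5)
  rhs <- single_drug_rhs(st2, 0.1, kin0, laws)
  lam <- laws$kappa_t * (30 - laws$r_min)
  expect_equal(rhs[3], -lam * 5 + 1000 * 0.01 * (30 - laws$r_min),
               tolerance = 1e-12)
})

test_that("time integration lands on the exact steady state of the model", {
  laws <- laws_default
  kin <- canon_kin(1)
  aex <- 0.9 * ribocomb:::ic50_model(kin, laws)
  st <- integrate_single_drug(aex, kin, laws)
  y_ode <- laws$kappa_t * (st[["r_u"]] - laws$r_min) / laws$lambda0
  y_exact <- ribocomb:::observable_from_inverse(
    function(y) aex_of_y(y, kin, laws), aex)
  expect_equal(y_ode, y_exact, tolerance = 1e-8)
  # the reduced cubic is the fast transport/binding limit of the same
  # steady state: agreement at the percent level for these kinetics
  sh <- reduce_kinetics(kin, laws)
  y_cubic <- max(steady_state_growth(sh$alpha, aex / sh$ic50)$y)
  expect_equal(y_ode, y_cubic, tolerance = 5e-2)
})

test_that("1-D stability criterion matches the dynamical Jacobian", {
  laws <- laws_default
  kin <- canon_kin(0.2)
  # a dose inside the full model's bistable region: three fixed points
  ic50 <- ribocomb:::ic50_model(kin, laws)
  roots <- NULL
  for (fac in c(0.8, 0.85, 0.9, 0.95)) {
    roots <- full_model_roots(fac * ic50, kin, laws)
    aex <- fac * ic50
    if (length(roots) == 3) break
  }
  expect_equal(length(roots), 3)
  eps <- 1e-6
  for (y in roots) {
    st <- single_state_at(y, kin, laws)
    J <- num_jacobian(function(x) single_drug_rhs(x, aex, kin, laws), st)
    dyn_stable <- max(Re(eigen(J, only.values = TRUE)$values)) < 0
    # 1-D criterion on the exact inverse: stable iff a_ex(y) decreasing
    slope <- (aex_of_y(min(y + eps, 1 - 1e-12), kin, laws) -
              aex_of_y(y - eps, kin, laws))
    expect_identical(dyn_stable, slope < 0)
  }
})
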