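kinA <- canon_kin(1)
kinB <- canon_kin(4)

test_that("pair RHS reduces to the single-drug system when drug B is absent", {
  laws <- laws_default
  deltas <- binding_modifiers()
  st1 <- c(a = 0.2, r_u = 30, r_b = 8)
  st2 <- c(a_A = 0.2, a_B = 0, r_u = 30, r_b_A = 8, r_b_B = 0, r_d = 0)
  r1 <- single_drug_rhs(st1, 0.5, kinA, laws)
  r2 <- pair_rhs(st2, c(0.5, 0), list(kinA, kinB), deltas, laws)
  expect_equal(r2[c(1, 3, 4)], r1, tolerance = 1e-14,
               ignore_attr = TRUE)
  expect_equal(r2[c(2, 5, 6)], c(0, 0, 0), ignore_attr = TRUE)
})

test_that("competitive binding leaves the double-bound pool sourceless", {
  laws <- laws_default
  deltas <- binding_modifiers(0, 0, 1, 1)
  st <- c(a_A = 0.2, a_B = 0.4, r_u = 30, r_b_A = 5, r_b_B = 7, r_d = 0)
  rhs <- pair_rhs(st, c(0.5, 0.8), list(kinA, kinB), deltas, laws)
  expect_identical(as.numeric(rhs[6]), 0)
})

test_that("ribosome mass balance: binding fluxes cancel in the pool sum", {
  laws <- laws_default
  set.seed(42)
  for (i in 1:20) {
    deltas <- binding_modifiers(runif(1, 0, 5), runif(1, 0, 5),
                                runif(1, 0, 2), runif(1, 0, 2))
    st <- c(runif(2, 0, 2), runif(1, laws$r_min, laws$r_max),
            runif(3, 0, 10))
    rhs <- pair_rhs(st, runif(2, 0, 1), list(kinA, kinB), deltas, laws)
    lam <- laws$kappa_t * (st[3] - laws$r_min)
    pool <- sum(st[3:6])
    expect_equal(sum(rhs[3:6]),
                 -lam * pool + ribocomb:::s_of_lambda(laws, lam),
                 tolerance = 1e-9)
  }
})

test_that("surface boundaries equal the single-drug curves", {
  laws <- laws_default
  g <- seq(0, 3, length.out = 31)
  s <- pair_surface(list(kinA, kinB), binding_modifiers(), laws, g, g)
  yA <- ribocomb:::observable_from_inverse(
    function(y) aex_of_y(y, kinA, laws), g * s$meta$ic50[1])
  yB <- ribocomb:::observable_from_inverse(
    function(y) aex_of_y(y, kinB, laws), g * s$meta$ic50[2])
  expect_equal(s$y[, 1], yA, tolerance = 1e-9)
  expect_equal(s$y[1, ], yB, tolerance = 1e-9)
  expect_identical(s$y[1, 1], 1)
  expect_true(all(s$y >= 0 & s$y <= 1))
})

test_that("pair fixed points satisfy the ODE residual and ribosome balance", {
  laws <- laws_default
  deltas <- binding_modifiers(2, 0.5, 1.5, 0.8)
  ic <- c(ribocomb:::ic50_model(kinA, laws), ribocomb:::ic50_model(kinB, laws))
  set.seed(7)
  for (i in 1:12) {
    aex <- runif(2, 0, 3) * ic
    ps <- pair_steady_state(aex, list(kinA, kinB), deltas, laws)
    expect_lt(max(abs(ps$rhs)), 1e-8)
    r_tot <- ribocomb:::r_tot_of_lambda(laws, ps$lambda)
    expect_equal(sum(ps$state[3:6]), r_tot, tolerance = 1e-10)
    expect_true(ps$converged)
  }
})

test_that("steady-state solver agrees with time integration from a drug-free inoculum", {
  laws <- laws_default
  deltas <- binding_modifiers(1.5, 1.5, 1, 1)
  ic <- c(ribocomb:::ic50_model(kinA, laws), ribocomb:::ic50_model(kinB, laws))
  aex <- c(0.8, 1.2) * ic
  ps <- pair_steady_state(aex, list(kinA, kinB), deltas, laws)
  y0 <- c(a_A = 0, a_B = 0, r_u = laws$r_min + laws$lambda0 / laws$kappa_t,
          r_b_A = 0, r_b_B = 0, r_d = 0)
  out <- deSolve::ode(y0, times = c(0, 3000),
                      func = function(t, y, p)
                        list(pair_rhs(y, aex, list(kinA, kinB), deltas,
                                      laws)),
                      parms = NULL, rtol = 1e-10, atol = 1e-10)
  ru_end <- out[nrow(out), "r_u"]
  y_ode <- as.numeric(laws$kappa_t * (ru_end - laws$r_min) / laws$lambda0)
  expect_equal(ps$y, y_ode, tolerance = 1e-6)
})

test_that("swapping the drugs transposes the surface", {
  laws <- laws_default
  g <- seq(0, 3, length.out = 21)
  dAB <- binding_modifiers(2, 0.5, 1, 1)
  dBA <- binding_modifiers(0.5, 2, 1, 1)
  sAB <- pair_surface(list(kinA, kinB), dAB, laws, g, g)
  sBA <- pair_surface(list(kinB, kinA), dBA, laws, g, g)
  expect_equal(sAB$y, t(sBA$y), tolerance = 1e-9)
})

test_that("additivity certificate: exact linear isoboles under competition", {
  laws <- laws_default
  cert <- additivity_certificate(list(kinA, kinB), laws,
                                 lambda_target = 0.5, n_points = 50)
  expect_lt(cert$isobole_gap, 1e-6)
  # Upsilon depends only on lambda and own-drug kinetics: recompute at
  # several doses of the other drug via the steady state
  deltas <- binding_modifiers(0, 0, 1, 1)
  ups <- sapply(c(0.05, 0.2, 0.4), function(aexB) {
    ps <- pair_steady_state(c(0.1, aexB), list(kinA, kinB), deltas, laws)
    # invert a_A = Upsilon_A a_ex,A at the achieved growth rate
    cert_i <- additivity_certificate(list(kinA, kinB), laws, ps$lambda,
                                     n_points = 2)
    ps$state[["a_A"]] / 0.1 - cert_i$upsilon_A
  })
  expect_lt(max(abs(ups)), 1e-8)
})

test_that("high-alpha competitive isoboles approach c_A + c_B = lambda0/lambda - 1", {
  laws <- laws_default
  # the limit needs k_off, p_out >> lambda; concentrations in units of the
  # model's own IC50
  kin_hi <- list(shape_to_kinetics(50, laws, p_out = 1000),
                 shape_to_kinetics(50, laws, p_out = 1000))
  ic <- ribocomb:::ic50_model(kin_hi[[1]], laws)
  cert <- additivity_certificate(kin_hi, laws, lambda_target = 0.4)
  cA <- cert$trace$a_ex_A / ic
  cB <- cert$trace$a_ex_B_numeric / ic
  expect_equal(cA + cB, rep(laws$lambda0 / 0.4 - 1, length(cA)),
               tolerance = 5e-3)
})

test_that("rescaled slow-growth concentration follows its formula", {
  laws2 <- growth_laws(lambda0 = growth_laws()$lambda_max / 2)
  expect_equal(c_prime(1, 1, laws2), 4)
  expect_equal(c_prime(0, 2, laws2), 0)
  expect_error(c_prime(1, 0, laws2), "alpha")
  # lambda0 = lambda_max, alpha -> infinity: c' -> c
  lawsE <- growth_laws(lambda0 = growth_laws()$lambda_max)
  expect_equal(c_prime(2, 1e6, lawsE), 2, tolerance = 1e-10)
})

test_that("slow-growth closed form dispatches its exact special cases", {
  set.seed(11)
  laws <- laws_default
  k <- laws$lambda_max / laws$lambda0
  for (i in 1:1000) {
    cA <- runif(1, 0, 5); cB <- runif(1, 0, 5)
    delta <- runif(1, 0, 5)
    # all deltas one: Bliss-like product form
    y1 <- slow_growth_surface(cA, cB, binding_modifiers(), laws)
    expect_equal(as.numeric(y1), k / ((1 + cA) * (1 + cB)),
                 tolerance = 1e-14)
    # delta_on = delta, delta_off = 1 at delta = 1 equals the product form
    y14 <- slow_growth_surface(cA, cB, binding_modifiers(1, 1, 1, 1), laws)
    expect_equal(as.numeric(y14), as.numeric(y1), tolerance = 1e-14)
    # delta_off = 0: complete mutual trapping, y = 0
    y0 <- slow_growth_surface(cA, cB,
                              binding_modifiers(delta, delta, 0, 0), laws)
    expect_identical(as.numeric(y0), 0)
    # delta_on = 0: Loewe additive form, independent of delta_off
    yL <- slow_growth_surface(cA, cB,
                              binding_modifiers(0, 0, delta, delta), laws)
    expect_equal(as.numeric(yL), k / (1 + cA + cB), tolerance = 1e-14)
    # symmetric delta_on, unit delta_off
    yd <- slow_growth_surface(cA, cB,
                              binding_modifiers(delta, delta, 1, 1), laws)
    expect_equal(as.numeric(yd), k / (1 + cA + cB + delta * cA * cB),
                 tolerance = 1e-13)
  }
})

test_that("slow-growth approximation improves with alpha (surface correlation)", {
  laws <- laws_default
  g <- seq(0, 3, length.out = 41)
  cors <- sapply(c(2^-1, 2, 2^3), function(al) {
    s <- pair_surface(list(canon_kin(al), canon_kin(al)),
                      binding_modifiers(), laws, g, g)
    cp <- c_prime(g, al, laws)
    cor(as.vector(s$y),
        as.vector(slow_growth_surface(cp, cp, binding_modifiers(), laws)))
  })
  expect_true(all(diff(cors) > 0))
})

test_that("stabilising interactions amplify and destabilising ones weaken the interaction", {
  laws <- laws_default
  lis <- sapply(c(0.1, 1, 2.5, 5), function(delta)
    pair_interaction(4, 4, binding_modifiers(delta, delta, 1, 1), laws,
                     n = 61)$score$li)
  expect_lt(abs(lis[1]), abs(lis[2]))          # delta < 1: towards additive
  expect_true(all(diff(abs(lis[-1])) > 0))     # delta >= 1: |LI| grows
  expect_true(all(lis < 0))                    # shallow drugs: synergy side
})
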