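test_that("Loewe reference restores single-drug curves on the axes", {
  g <- seq(0, 3, by = 0.25)
  ref <- loewe_additive_surface(1, 4, g, g)
  crvA <- dose_response_curve(response_shape(1), g)
  crvB <- dose_response_curve(response_shape(4), g)
  expect_equal(ref$y[, 1], crvA$growth_relative, tolerance = 1e-8)
  expect_equal(ref$y[1, ], crvB$growth_relative, tolerance = 1e-8)
})

test_that("identical shapes make the additive surface a function of c_A + c_B", {
  g <- seq(0, 2, by = 0.2)
  for (alpha in c(2^-5, 1, 4)) {
    ref <- loewe_additive_surface(alpha, alpha, g, g)
    ysum <- ribocomb:::observable_y(alpha, outer(g, g, `+`))
    expect_equal(as.vector(ref$y), as.vector(ysum), tolerance = 1e-7)
  }
})

test_that("Loewe isoboles of the additive surface are straight lines", {
  g <- seq(0, 3, length.out = 61)
  ref <- loewe_additive_surface(1, 3, g, g)
  # along the straight line c_A/C_A(y*) + c_B/C_B(y*) = 1 the surface is
  # constant at y*
  for (ystar in c(0.3, 0.5, 0.7)) {
    CA <- inverse_dose_response(1, ystar)
    CB <- inverse_dose_response(3, ystar)
    tt <- seq(0, 1, by = 0.1)
    yline <- ribocomb:::largest_crossing(
      function(y) y * (1^2 + 1) / ((1 - y) * (4 * y^2 + 1^2)),
      function(y) y * (3^2 + 1) / ((1 - y) * (4 * y^2 + 3^2)),
      tt * CA, (1 - tt) * CB)
    expect_equal(yline, rep(ystar, length(tt)), tolerance = 1e-9)
  }
})

test_that("Bliss surface multiplies the single-drug responses", {
  g <- seq(0, 3, by = 0.5)
  crvA <- dose_response_curve(response_shape(1), g)
  crvB <- dose_response_curve(response_shape(4), g)
  bl <- bliss_surface(crvA, crvB)
  expect_equal(bl$y, outer(crvA$growth_relative, crvB$growth_relative))
  # y_bliss <= min(y_A, y_B) pointwise
  expect_true(all(bl$y <= outer(crvA$growth_relative,
                                rep(1, length(g))) + 1e-15))
  expect_true(all(bl$y <= outer(rep(1, length(g)),
                                crvB$growth_relative) + 1e-15))
  # inert partner: y_B = 1 everywhere recovers drug A's curve
  crv1 <- dose_response_curve(response_shape(4), rep(0, length(g)))
  bl1 <- bliss_surface(crvA, crv1)
  expect_equal(bl1$y, matrix(crvA$growth_relative, length(g), length(g)))
})

test_that("exponential dose-response curves make Loewe and Bliss coincide", {
  g <- seq(0, 3, length.out = 31)
  yexp <- exp(-log(2) * g)          # halves at c = 1
  inv <- function(y) -log(y) / log(2)
  ref <- loewe_additive_surface(c_A = g, c_B = g,
                                inverse_A = inv, inverse_B = inv)
  expect_equal(ref$y, outer(yexp, yexp), tolerance = 1e-8)
})

test_that("LI score is zero against the surface's own additive construction", {
  g <- seq(0, 3, length.out = 41)
  ref <- loewe_additive_surface(1, 4, g, g)
  sc <- li_score(ref, ref)
  expect_identical(sc$li, 0)
  expect_identical(sc$label, "additive")
  # synergy / antagonism classification by sign
  expect_identical(li_score(dose_response_surface(g, g, ref$y * 0.8),
                            ref)$label, "synergy")
  expect_identical(li_score(dose_response_surface(g, g, pmin(ref$y * 1.2, 1)),
                            ref)$label, "antagonism")
  expect_error(li_score(ref, dose_response_surface(g, g, 0 * ref$y)),
               "zero volume")
})

test_that("LI is invariant under drug relabeling", {
  laws <- laws_default
  a <- pair_interaction(0.5, 4, binding_modifiers(2, 0.5, 1, 1), laws,
                        n = 41)
  b <- pair_interaction(4, 0.5, binding_modifiers(0.5, 2, 1, 1), laws,
                        n = 41)
  expect_equal(a$score$li, b$score$li, tolerance = 1e-8)
})

test_that("phase diagram is symmetric and has the expected corner signs", {
  laws <- laws_default
  ag <- 2^c(-5, -1, 2)
  pd <- phase_diagram(ag, ag, binding_modifiers(), laws, n = 41)
  expect_equal(pd$li, t(pd$li), tolerance = 1e-8)
  expect_gt(pd$li[1, 1], 0)     # steep-steep corner: antagonism
  expect_lt(pd$li[3, 3], 0)     # shallow-shallow corner: synergy
})

test_that("LI varies smoothly along a diagonal alpha sweep", {
  laws <- laws_default
  alphas <- 2^seq(-3, 2, by = 0.5)
  lis <- sapply(alphas, function(al)
    pair_interaction(al, al, binding_modifiers(), laws, n = 41)$score$li)
  # no jumps beyond grid effects, and a single antagonism -> synergy
  # crossing along the sweep
  expect_true(all(abs(diff(lis)) < 0.35))
  expect_equal(sum(diff(sign(lis)) != 0), 1)
  expect_gt(lis[1], 0)
  expect_lt(lis[length(lis)], 0)
})

test_that("the diagonal interaction ordering follows the direct-interaction strength", {
  laws <- laws_default
  li_of <- function(delta)
    pair_interaction(2^-4, 2^-4,
                     binding_modifiers(delta, delta, 1, 1), laws,
                     n = 41)$score$li
  li_tiny <- li_of(0.05); li_1 <- li_of(1); li_hi <- li_of(3)
  expect_true(abs(li_tiny) < abs(li_1))  # delta -> 0: towards additivity
  expect_true(abs(li_hi) > abs(li_1))    # delta > 1: amplified
  expect_true(li_1 > 0 && li_hi > 0)     # steep pair: antagonism side
})
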