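test_that("sign statistic vanishes on the boundary and tracks the sign of D", {
  # on the equal-activator saturation boundary the statistic is ~ 0
  for (w in c(2.5, 4, 8)) {
    xp <- (w - 2) / w^2
    s <- two_activator_system(xp, 1e10, 1e10, w, w)
    expect_lt(abs(synergy_sign_statistic(s)), 1e-8)
  }
  # above/below the boundary: statistic and D share their sign
  set.seed(31)
  for (i in 1:200) {
    s <- two_activator_system(runif_log(1, 1e-3, 2),
                              runif_log(1, 1e-2, 1e4),
                              runif_log(1, 1e-2, 1e4),
                              runif_log(1, 1, 100), runif_log(1, 1, 100))
    stat <- synergy_sign_statistic(s)
    d <- D_via_occupancy(s)
    if (abs(d) > 1e-12) expect_identical(sign(stat), sign(d))
  }
  expect_error(
    synergy_sign_statistic(two_activator_system(0.1, 1, 1, 3, 3, omega3 = 2)),
    "omega")
})

test_that("equal-activator critical polymerase curve matches the bisection oracle", {
  for (w in c(2.25, 2.5, 3, 4, 6, 10)) {
    root <- uniroot(saturated_D_equal, c(1e-12, 1), w = w, tol = 1e-12)$root
    expect_lt(abs(critical_xp_equal_activators(w) - root), 1e-8)
  }
  expect_equal(critical_xp_equal_activators(2), 0)
  expect_true(is.na(critical_xp_equal_activators(1.5)))
  # interior maximum at w = 4 with value 1/8, decay to 0 at large w
  wmax <- optimize(critical_xp_equal_activators, c(2, 100),
                   maximum = TRUE)
  expect_equal(wmax$maximum, 4, tolerance = 1e-4)
  expect_equal(wmax$objective, 1 / 8, tolerance = 1e-10)
  expect_lt(critical_xp_equal_activators(1e8), 1e-7)
  # the whole curve sits below the high-polymerase ceiling of 1/2
  expect_true(all(critical_xp_equal_activators(seq(2, 1e3, by = 0.5)) < 0.5))
  expect_error(critical_xp_equal_activators(-1), "positive")
})

test_that("energy parameterization of the critical curve is a change of variables", {
  expect_equal(critical_xp_vs_energy(log(2)), 0)
  expect_equal(critical_xp_vs_energy(log(4)), 1 / 8, tolerance = 1e-12)
  g <- seq(log(2), 5, length.out = 40)
  expect_equal(critical_xp_vs_energy(g), critical_xp_equal_activators(exp(g)),
               tolerance = 1e-12)
})

test_that("two-body hyperbola reproduces the limiting-statistic root structure", {
  # diagonal crossing: root of the limiting statistic on w_A = w_B
  diag_root <- uniroot(function(w) limiting_synergy_statistic(w, w),
                       c(1.01, 10), tol = 1e-12)$root
  expect_equal(diag_root, 2, tolerance = 1e-10)
  expect_equal(two_body_hyperbola(2), 2, tolerance = 1e-12)
  # horizontal asymptote at 1
  expect_equal(two_body_hyperbola(1e8), 1, tolerance = 1e-7)
  expect_identical(two_body_hyperbola(1), Inf)
  # above the curve the full model is synergistic at strong activation
  set.seed(32)
  for (i in 1:50) {
    w_a <- runif_log(1, 1.2, 50)
    crit <- two_body_hyperbola(w_a)
    s_above <- two_activator_system(1e-4, 1e6, 1e6, w_a, crit * 1.3)
    s_below <- two_activator_system(1e-4, 1e6, 1e6, w_a, max(1, crit * 0.7))
    expect_gt(D_via_occupancy(s_above), 0)
    expect_lt(D_via_occupancy(s_below), 0)
  }
})

test_that("three-body hyperbola shrinks with omega3 and nests the two-body case", {
  w <- exp(seq(log(1.05), log(50), length.out = 60))
  expect_equal(three_body_hyperbola(w, 1), two_body_hyperbola(w),
               tolerance = 1e-12)
  # diagonal crossing for omega3 = 4 located by the oracle
  diag_root <- uniroot(function(w) limiting_synergy_statistic(w, w, 4),
                       c(0.01, 10), tol = 1e-12)$root
  expect_equal(three_body_hyperbola(diag_root, 4), diag_root,
               tolerance = 1e-8)
  # asymptotes approach the axes as omega3 grows
  expect_lt(three_body_hyperbola(5, 10), three_body_hyperbola(5, 2))
  expect_identical(three_body_hyperbola(0.05, 10), Inf)  # at/below asymptote
})

test_that("the universal three-body threshold is 2, attained as w -> 1+", {
  val <- minimal_universal_three_body_factor()
  expect_equal(val, 2, tolerance = 1e-3)
  # margin: just above the threshold the statistic is positive on the grid
  w <- exp(seq(log(1 + 1e-4), log(100), length.out = 100))
  grid <- expand.grid(a = w, b = w)
  expect_true(all(limiting_synergy_statistic(grid$a, grid$b,
                                             val * 1.01) > 0))
  # the binding configuration is the weak-activator corner
  stat <- limiting_synergy_statistic(grid$a, grid$b, val)
  worst <- grid[which.min(stat), ]
  expect_lt(max(worst$a, worst$b), 1.01)
})

test_that("saturated D is re-entrant in the activator strength below the peak", {
  for (xp in c(0.02, 0.06, 0.1)) {
    w_grid <- exp(seq(log(1.01), log(1e4), length.out = 2000))
    sgn <- sign(saturated_D_equal(xp, w_grid))
    flips <- which(diff(sgn) != 0)
    expect_length(flips, 2L)
    expect_identical(unique(sgn[sgn != 0])[1], -1)  # starts negative
    expect_identical(sgn[length(sgn)], -1)          # ends negative
    # the two roots sit where the critical curve equals xp (within one
    # grid cell of the 2000-point scan)
    roots <- w_grid[flips]
    expect_true(all(abs(critical_xp_equal_activators(roots) - xp) < 5e-3))
  }
})

test_that("regime classification reproduces the catalogued cases and signs", {
  # low activator doses: only less-than-additive
  lab1 <- classify_regime(two_activator_system(0.1, 1e-4, 1e-4, 5, 5))
  expect_identical(lab1$case_id, "1")
  expect_identical(lab1$predicted_sign, "negative")

  # weak activators despite a strong TF-TF interaction
  lab2 <- classify_regime(
    two_activator_system(0.1, 10, 10, 1.01, 1.02, omega_AB = 50))
  expect_identical(lab2$case_id, "2")
  expect_identical(lab2$predicted_sign, "negative")

  # polymerase at or above half its dissociation constant, neutral factors
  lab3 <- classify_regime(two_activator_system(0.8, 1, 1, 5, 5))
  expect_identical(lab3$case_id, "3")
  expect_identical(lab3$predicted_sign, "negative")

  # strong three-body interaction
  lab7b <- classify_regime(
    two_activator_system(1e-3, 1e4, 1e4, 5, 5, omega3 = 3))
  expect_identical(lab7b$case_id, "7b")
  expect_identical(lab7b$predicted_sign, "positive")

  # moderate three-body interaction: sign from the hyperbola, checked
  # against the brute-force D
  s7a_pos <- two_activator_system(1e-3, 1e4, 1e4, 3, 3, omega3 = 1.5)
  lab <- classify_regime(s7a_pos)
  expect_identical(lab$case_id, "7a")
  expect_identical(lab$predicted_sign, "positive")
  expect_gt(D_via_occupancy(s7a_pos), 0)
  s7a_neg <- two_activator_system(1e-3, 1e3, 1e3, 1.2, 1.2, omega3 = 1.5)
  lab <- classify_regime(s7a_neg)
  expect_identical(lab$case_id, "7a")
  expect_identical(lab$predicted_sign, "negative")
  expect_lt(D_via_occupancy(s7a_neg), 0)

  # nonlinearity-driven synergy at strong activation, omega3 = 1
  s6 <- two_activator_system(1e-3, 1e4, 1e4, 5, 5, omega_AB = 3)
  lab6 <- classify_regime(s6)
  expect_identical(lab6$case_id, "6")
  expect_identical(lab6$predicted_sign, "positive")
  expect_gt(D_via_occupancy(s6), 0)

  # equal activators at saturation: critical polymerase curve decides
  s5b <- two_activator_system(0.05, 1e4, 1e4, 4, 4)
  lab5b <- classify_regime(s5b)
  expect_identical(lab5b$case_id, "5b")
  expect_identical(lab5b$predicted_sign, "positive")
  s5a <- two_activator_system(0.3, 1e4, 1e4, 4, 9)
  lab5a <- classify_regime(s5a)
  expect_identical(lab5a$case_id, "5a")
  expect_identical(lab5a$predicted_sign,
                   if (D_via_occupancy(s5a) > 0) "positive" else "negative")

  expect_error(classify_regime(two_activator_system(0.1, 1, 1, 0.5, 2)),
               "activators only")
})

test_that("the sign-scan oracle is deterministic, symmetric and boundary-consistent", {
  tmpl <- two_activator_system(0.05, 1, 1, 1, 1)
  scan <- sign_scan_oracle(tmpl, c("x_A", "x_B"),
                           list(x_A = c(1e-2, 1e2), x_B = c(1e-2, 1e2)),
                           n = 15)
  # neutral factors: less-than-additive everywhere
  expect_true(all(scan$sign == -1))
  # symmetric template: scan invariant under exchanging the dose axes
  tmpl2 <- two_activator_system(0.05, 1, 1, 6, 6)
  scan2 <- sign_scan_oracle(tmpl2, c("x_A", "x_B"),
                            list(x_A = c(1e-2, 1e2), x_B = c(1e-2, 1e2)),
                            n = 15)
  m <- matrix(scan2$sign, 15, 15)
  expect_identical(m, t(m))
  expect_error(sign_scan_oracle(tmpl, "x_Q", list(x_Q = c(1, 2))), "unknown")
  expect_error(
    sign_scan_oracle(tmpl, c("x_A", "x_B", "w_A", "w_B"),
                     list(x_A = c(1, 2), x_B = c(1, 2), w_A = c(1, 2),
                          w_B = c(1, 2)), n = 40),
    "grid too large")
})
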