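test_that("energy-to-factor map obeys the Boltzmann sign convention and inverts", {
  rt <- 1.98720425864083e-3 * 298.15

  zero <- factors_from_energies(
    energy_parameters(c(A = 0, B = 0), delta_e_pair = c("A:B" = 0),
                      delta_e3 = c("A:B" = 0)))
  expect_equal(unname(zero$w), c(1, 1))
  expect_equal(unname(zero$omega_tf), 1)
  expect_equal(unname(zero$omega3), 1)

  # an activating (negative) shift of -RT ln 2 doubles the weight
  act <- factors_from_energies(energy_parameters(c(A = -rt * log(2))))
  expect_equal(unname(act$w), 2, tolerance = 1e-12)

  en <- energy_parameters(c(A = -1.2, B = 0.3),
                          delta_e_pair = c("A:B" = -0.5),
                          delta_e3 = c("A:B" = 0.8),
                          temperature = 310)
  round_trip <- energies_from_factors(factors_from_energies(en),
                                      temperature = 310)
  expect_equal(round_trip$delta_e, en$delta_e, tolerance = 1e-12)
  expect_equal(round_trip$delta_e_pair, en$delta_e_pair, tolerance = 1e-12)
  expect_equal(round_trip$delta_e3, en$delta_e3, tolerance = 1e-12)

  expect_error(energy_parameters(c(A = 1), temperature = 0), "positive")
  expect_error(energy_parameters(c(A = 1), delta_e_pair = c("B:A" = 1)),
               "ordered|unknown")
})

test_that("state enumeration covers every polymerase/TF-subset combination once", {
  s2 <- enumerate_states(2)
  expect_equal(nrow(s2), 8L)
  key <- paste(s2$rnap_bound, s2$bound_tfs)
  expect_equal(anyDuplicated(key), 0L)
  # conventional display order: empty, P, A, B, PA, PB, AB, PAB
  disp <- s2[attr(s2, "display_order"), ]
  expect_equal(disp$bound_tfs, c("", "", "A", "B", "A", "B", "A,B", "A,B"))
  expect_equal(disp$rnap_bound,
               c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE, FALSE, TRUE))

  s0 <- enumerate_states(0)
  expect_equal(nrow(s0), 2L)
  expect_equal(s0$rnap_bound, c(FALSE, TRUE))

  s3 <- enumerate_states(3)
  expect_equal(nrow(s3), 16L)
  expect_equal(anyDuplicated(paste(s3$rnap_bound, s3$bound_tfs)), 0L)

  expect_error(enumerate_states(-1), "non-negative")
})

test_that("state weights follow the factorized Boltzmann form", {
  params <- cooperativity_parameters(c(A = 5, B = 7),
                                     omega_tf = c("A:B" = 1.5),
                                     omega3 = c("A:B" = 2))
  doses <- c(A = 0.7, B = 1.3)
  expect_identical(
    state_weight(list(rnap_bound = FALSE, bound_tfs = ""), doses, 0.2, params),
    1)
  expect_equal(
    state_weight(list(rnap_bound = TRUE, bound_tfs = ""), doses, 0.2, params),
    0.2)
  expect_equal(
    state_weight(list(rnap_bound = TRUE, bound_tfs = "A,B"), doses, 0.2,
                 params),
    0.2 * 0.7 * 1.3 * 5 * 7 * 1.5 * 2, tolerance = 1e-12)
  expect_equal(
    state_weight(list(rnap_bound = FALSE, bound_tfs = "A,B"), doses, 0.2,
                 params),
    0.7 * 1.3 * 1.5, tolerance = 1e-12)
  expect_error(
    state_weight(list(rnap_bound = TRUE, bound_tfs = "Z"), doses, 0.2, params),
    "unknown TF")
})

test_that("state probabilities normalize and match on/off partition sums", {
  set.seed(11)
  for (i in 1:100) {
    doses <- c(A = runif_log(1, 1e-3, 1e3), B = runif_log(1, 1e-3, 1e3))
    params <- cooperativity_parameters(
      c(A = runif_log(1, 1e-2, 1e2), B = runif_log(1, 1e-2, 1e2)),
      omega_tf = c("A:B" = runif_log(1, 1e-2, 1e2)),
      omega3 = c("A:B" = runif_log(1, 1e-2, 1e2)))
    x_p <- runif_log(1, 1e-3, 1e3)
    ss <- state_probabilities(doses, x_p, params)
    expect_lt(abs(sum(ss$states$probability) - 1), 1e-12)
    expect_gte(ss$v_off, 1)
    expect_equal(ss$v_on + ss$v_off, sum(ss$states$weight),
                 tolerance = 1e-12)
    expect_equal(occupancy_probability(doses, x_p, params),
                 sum(ss$states$probability[ss$states$rnap_bound]),
                 tolerance = 1e-12)
  }
})

test_that("probability ranking agrees with weights and free energies", {
  set.seed(12)
  for (i in 1:25) {
    w_a <- runif_log(1, 1, 50); w_b <- runif_log(1, 1, 50)
    x <- runif_log(1, 1e-2, 1e2)
    params <- cooperativity_parameters(c(A = w_a, B = w_b))
    ss <- state_probabilities(c(A = x, B = x), runif_log(1, 1e-2, 1e2), params)
    # ranking by probability is the ranking by statistical weight
    expect_identical(order(ss$states$probability), order(ss$states$weight))
    # states P+A and P+B share the concentration degeneracy x_P * x, so the
    # one with the lower free-energy shift must be the more probable
    on_a <- which(ss$states$rnap_bound & ss$states$bound_tfs == "A")
    on_b <- which(ss$states$rnap_bound & ss$states$bound_tfs == "B")
    dg <- ss$states$free_energy_shift
    pr <- ss$states$probability
    if (abs(dg[on_a] - dg[on_b]) > 1e-9)
      expect_identical(dg[on_a] < dg[on_b], pr[on_a] > pr[on_b])
  }
})

test_that("neutral factors reduce occupancy to the basal curve at any dose", {
  params <- cooperativity_parameters(c(A = 1, B = 1))
  grid <- runif_log(20, 1e-3, 1e3)
  for (x_p in c(0.1, 0.5, 2)) {
    for (x in grid) {
      expect_lt(abs(occupancy_probability(c(A = x, B = 3 * x), x_p, params) -
                      x_p / (1 + x_p)), 1e-12)
    }
  }
  # basal occupancy at half the polymerase dissociation constant
  expect_equal(
    occupancy_probability(numeric(0), 0.5, cooperativity_parameters(numeric(0))),
    1 / 3, tolerance = 1e-15)
})

test_that("log-space weights survive extreme doses and factors", {
  params <- cooperativity_parameters(c(A = 1e12, B = 1e12),
                                     omega_tf = c("A:B" = 1e12),
                                     omega3 = c("A:B" = 1e12))
  ss <- state_probabilities(c(A = 1e12, B = 1e12), 1e12, params)
  expect_true(all(is.finite(ss$states$probability)))
  expect_lt(abs(sum(ss$states$probability) - 1), 1e-12)
  p <- occupancy_probability(c(A = 1e12, B = 1e12), 1e12, params)
  expect_true(is.finite(p) && p >= 0 && p <= 1)
})

test_that("on/off sums and the transcription rate behave as contracted", {
  params <- cooperativity_parameters(c(A = 4, B = 6),
                                     omega_tf = c("A:B" = 2),
                                     omega3 = c("A:B" = 3))
  v0 <- on_off_sums(c(A = 0, B = 0), 0.7, params)
  expect_equal(unname(v0), c(0.7, 1), tolerance = 1e-12)
  xa <- 0.3; xb <- 1.1; xp <- 0.7
  v <- on_off_sums(c(A = xa, B = xb), xp, params)
  expect_equal(unname(v["v_on"]),
               xp * (1 + xa * 4 + xb * 6 + xa * xb * 4 * 6 * 2 * 3),
               tolerance = 1e-12)
  expect_equal(unname(v["v_off"]), 1 + xa + xb + xa * xb * 2,
               tolerance = 1e-12)

  expect_equal(transcription_rate(0, 10), 0)
  expect_equal(transcription_rate(1, 3.5), 3.5)
  expect_equal(transcription_rate(0.4, 2 * 7), 2 * transcription_rate(0.4, 7))
  expect_error(transcription_rate(0.5, 0), "positive")
})

test_that("dose constructors validate and reconcile absolute concentrations", {
  d <- activator_dose("CRP", concentration = 2e-6, kd = 1e-6)
  expect_equal(d$relative_concentration, 2)
  expect_error(activator_dose("A", relative_concentration = 3,
                              concentration = 2e-6, kd = 1e-6),
               "disagrees")
  expect_error(activator_dose("A", -0.1), "non-negative")
  expect_error(polymerase_dose(-1), "non-negative")
  expect_equal(polymerase_dose(0.5)$relative_concentration, 0.5)
})
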