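test_that("count/concentration conversion matches physical constants and round-trips", {
  p <- unitary_params()
  expect_equal(p$ions_per_uM, 1e-17 * 6.02214076e23 * 1e-6)
  # 0.1 uM resting calcium in a 1e-17 L dyad is ~0.6 ions
  expect_equal(count_from_concentration(0.1, p), 0.6022141, tolerance = 1e-6)
  # 5 uM is ~30 ions
  expect_equal(count_from_concentration(5, p), 30.1107, tolerance = 1e-6)
  expect_identical(count_from_concentration(0, p), 0)
  for (c in c(0.01, 0.6, 5, 123)) {
    expect_equal(concentration_from_count(count_from_concentration(c, p), p),
                 c, tolerance = 1e-15)
  }
  expect_error(count_from_concentration(-1, p), "concentration")
  expect_error(subspace_params(v = 0), "volume")
  expect_error(subspace_params(beta = -0.1), "beta")
})

test_that("influx count rate is linear in volume and zero without sources", {
  p1 <- unitary_params()
  p2 <- subspace_params(2e-17)
  a <- 0.049
  expect_equal(influx_count_rate(a, p1), (a + 0.01 * 0.1) * p1$ions_per_uM)
  expect_equal(influx_count_rate(a, p1), 0.3011, tolerance = 1e-3)
  expect_equal(influx_count_rate(a, p2), 2 * influx_count_rate(a, p1))
  p0 <- subspace_params(1e-17, beta = 0.01, c_inf = 0)
  expect_identical(influx_count_rate(0, p0), 0)
})

test_that("binding propensity has the right combinatorics and macroscopic limit", {
  p <- unitary_params()
  expect_identical(binding_propensity(0, 1, 0.05, p), 0)
  expect_identical(binding_propensity(1, 1, 0.05, p), 0)
  expect_equal(binding_propensity(10, 2, 0.05, p),
               2 * binding_propensity(10, 1, 0.05, p))
  # identity n(n-1) k+/w^2 = k+ (c^2 - c/w) with c = n/w
  n <- 17
  w <- p$ions_per_uM
  c <- n / w
  expect_equal(binding_propensity(n, 1, 0.05, p),
               0.05 * (c^2 - c / w), tolerance = 1e-14)
  # convergence to k+ c^2 at fixed concentration: relative error ~ 1/w
  kp <- 0.05
  c_fix <- 2
  errs <- vapply(c(10, 100, 1e4), function(w_target) {
    v <- w_target / (6.02214076e23 * 1e-6)
    pw <- subspace_params(v)
    n <- round(c_fix * pw$ions_per_uM)
    c_eff <- n / pw$ions_per_uM
    abs(binding_propensity(n, 1, kp, pw) - kp * c_eff^2) / (kp * c_eff^2)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3], 1e-3)
  expect_equal(errs[1] / errs[3], 1e3, tolerance = 0.1)  # ~1/w scaling
})

test_that("c_star and its inverse round-trip and validate", {
  expect_equal(c_star(0.049, 0.01, 0.1), 5)
  expect_equal(c_star(0, 0.01, 0.1), 0.1)
  expect_equal(alpha_from_c_star(12, 0.01, 0.1), 0.119)
  expect_equal(c_star(alpha_from_c_star(12, 0.01, 0.1), 0.01, 0.1), 12)
  expect_error(alpha_from_c_star(0.05, 0.01, 0.1), "c_star")
})

test_that("scheme construction validates and encodes the variants", {
  s <- make_scheme("single_regulated", "activated", alpha1 = 0.049,
                   kappa = 2, k_plus = 0.05)
  expect_s3_class(s, "channel_scheme")
  expect_equal(s$k_minus, 0.2)                 # kappa^2 k+
  expect_equal(s$alpha, c(0, 0.049))           # closed when calcium-free
  expect_equal(s$open_states, 2L)
  si <- make_scheme("single_regulated", "inactivated", alpha0 = 0.049,
                    kappa = 0.63, k_plus = 0.05)
  expect_equal(si$alpha, c(0.049, 0))          # open when calcium-free
  expect_equal(si$open_states, 1L)

  m <- make_scheme("multi_channel", "activated", alpha1 = 0.06,
                   kappa = 0.45, k_plus = 0.005, b_t = 4)
  expect_equal(m$n_states, 5L)
  expect_equal(m$alpha, 0.06 * (0:4) / 4)      # linear interpolation
  # binding multiplicity counts free channels, release counts bound
  bind <- m$transitions[m$transitions$ca_dependent, ]
  expect_equal(bind$mult[order(bind$from)], c(4L, 3L, 2L, 1L))
  rel <- m$transitions[m$transitions$dn == 2L, ]
  expect_equal(rel$mult[order(rel$from)], 1:4)

  cal <- make_scheme("calmodulin", "activated", alpha0 = 0, alpha1 = 0.049,
                     kappa = 2, k_plus = 0.05, gamma_plus = 1,
                     gamma_minus = 0.1, delta_plus = 0.2, delta_minus = 0.3)
  expect_equal(cal$n_states, 4L)
  expect_equal(cal$open_states, 4L)            # S4 is the effector state
  expect_equal(sum(cal$transitions$ca_dependent), 1L)

  expect_error(make_scheme("single_regulated", "activated", kappa = 2,
                           k_plus = 0.05), "alpha1")
  expect_error(make_scheme("single_regulated", "activated", alpha1 = -1,
                           kappa = 2, k_plus = 0.05), ">= 0")
  expect_error(make_scheme("multi_channel", "activated", alpha1 = 0.05,
                           kappa = 1, k_plus = 0.01, b_t = 2.5), "integer")
  expect_error(make_scheme("calmodulin", "activated", alpha1 = 0.049,
                           kappa = 2, k_plus = 0.05, gamma_plus = 1,
                           gamma_minus = 0.1, delta_plus = 0.2),
               "delta_minus")
})

test_that("multi-channel scheme with one channel is the two-state scheme", {
  s1 <- make_scheme("single_regulated", "activated", alpha1 = 0.049,
                    kappa = 2, k_plus = 0.05)
  m1 <- make_scheme("multi_channel", "activated", alpha1 = 0.049,
                    kappa = 2, k_plus = 0.05, b_t = 1)
  expect_equal(m1$alpha, s1$alpha)
  expect_equal(m1$open_fraction, s1$open_fraction)
  t1 <- s1$transitions[order(s1$transitions$from), ]
  t2 <- m1$transitions[order(m1$transitions$from), ]
  rownames(t1) <- rownames(t2) <- NULL
  expect_equal(t2, t1)
})
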