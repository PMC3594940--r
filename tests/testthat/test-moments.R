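test_that("Poisson predictions reproduce the closed-form fluctuation scaling", {
  p <- unitary_params()
  pr <- poisson_prediction(p, 0.049)
  expect_equal(pr$lambda, 30.1107, tolerance = 1e-5)
  expect_equal(pr$E_count, pr$Var_count)
  expect_equal(pr$E_C, 5)
  expect_equal(pr$CV, 1 / sqrt(pr$lambda))
  expect_equal(round(pr$CV, 2), 0.18)
  # CV drops as 1/sqrt(v) at fixed c_star
  expect_equal(round(poisson_prediction(subspace_params(3e-17), 0.049)$CV, 2),
               0.11)
  expect_equal(round(poisson_prediction(subspace_params(1e-16), 0.049)$CV, 3),
               0.058)
  # no influx: expectation relaxes to the bulk level
  expect_equal(poisson_prediction(p, 0)$E_C, 0.1)
})

test_that("summaries of the unregulated solve match the Poisson closed form", {
  p <- unitary_params()
  sd1 <- solve_cme(unregulated_reference(5), p)
  ms <- summarize_moments(sd1)
  pr <- poisson_prediction(p, 0.049)
  expect_equal(ms$E_count, pr$lambda, tolerance = 1e-8)
  expect_equal(ms$Var_count, pr$lambda, tolerance = 1e-8)
  expect_equal(ms$E_C, pr$E_C, tolerance = 1e-8)
  expect_equal(ms$CV_C, pr$CV, tolerance = 1e-8)
  # second moment identity mu2 = lambda + lambda^2
  expect_equal(unname(ms$mu["q2", 1]), pr$lambda + pr$lambda^2,
               tolerance = 1e-8)
})

test_that("two-state channel open probability rises with volume (0.23 -> 0.78)", {
  s <- activated_reference()
  ms1 <- summarize_moments(solve_cme(s, unitary_params(1)))
  ms8 <- summarize_moments(solve_cme(s, unitary_params(8)))
  expect_equal(ms1$p_open, 0.23, tolerance = 0.02 / 0.23)
  expect_equal(ms8$p_open, 0.78, tolerance = 0.02 / 0.78)
  expect_lt(ms1$p_open, ms8$p_open)
  # p_open is the sum of state marginals over the open states
  expect_equal(ms1$p_open, sum(ms1$p_state[s$open_states]))
})

test_that("decomposition of E[C] over channel states is exact and marginals sum to 1", {
  p <- unitary_params()
  for (scheme in list(activated_reference(),
                      make_scheme("multi_channel", "activated",
                                  alpha1 = 0.049, kappa = 0.45,
                                  k_plus = 0.005, b_t = 3))) {
    ms <- summarize_moments(solve_cme(scheme, p))
    expect_equal(sum(ms$p_state), 1, tolerance = 1e-12)
    expect_equal(ms$E_C,
                 sum(ms$p_state * ms$conditional_mean_uM), tolerance = 1e-12)
    expect_true(all(ms$conditional_var >= 0, na.rm = TRUE))
  }
})

test_that("stationary moment-balance residuals vanish", {
  p <- unitary_params()
  res_u <- check_moment_balance(solve_cme(unregulated_reference(5), p))
  expect_lt(max(abs(res_u)), 1e-8 * attr(res_u, "scale"))
  res_2 <- check_moment_balance(solve_cme(activated_reference(), p))
  expect_lt(max(abs(res_2)), 1e-8 * attr(res_2, "scale"))
  # volumes other than the unitary one
  res_8 <- check_moment_balance(solve_cme(activated_reference(),
                                          unitary_params(8)))
  expect_lt(max(abs(res_8)), 1e-8 * attr(res_8, "scale"))
  m <- make_scheme("multi_channel", "activated", alpha1 = 0.049,
                   kappa = 0.45, k_plus = 0.005, b_t = 2)
  expect_error(check_moment_balance(solve_cme(m, p)), "two-state")
})

test_that("bound-probability identity holds on every two-state solve", {
  for (cfg in list(list(par = unitary_params(1), s = activated_reference()),
                   list(par = unitary_params(4), s = activated_reference()),
                   list(par = unitary_params(1),
                        s = activated_reference(k_plus = 0.005)),
                   list(par = unitary_params(2),
                        s = inactivated_reference()))) {
    ident <- p_bound_identity(solve_cme(cfg$s, cfg$par))
    expect_lt(abs(ident["lhs"] - ident["rhs"]) / ident["lhs"], 1e-8)
  }
})

test_that("bound probability approaches the Hill form in the large-system limit", {
  # large volume and fast binding: mu0_bound -> E0[C]^2 / (kappa^2 + E0[C]^2)
  s <- activated_reference(k_plus = 0.5)
  p_big <- unitary_params(50)
  sd1 <- solve_cme(s, p_big)
  ms <- summarize_moments(sd1)
  e0 <- ms$conditional_mean_uM[1]
  hill <- e0^2 / (s$kappa^2 + e0^2)
  expect_equal(ms$p_state[2], hill, tolerance = 0.02)
})

test_that("fast and slow gating limits bracket the CME and match a bisection oracle", {
  p <- unitary_params()
  s <- activated_reference()
  lim <- fast_slow_limits(s, p)
  # slow limit closed form
  expect_equal(lim$slow$p_open, 0.01 / 4.01)
  expect_equal(lim$slow$E_C, 0.1)
  # fast limit: largest root of c = c_inf + (alpha/beta) c^2/(kappa^2+c^2)
  f <- function(c) 0.1 + 4.9 * c^2 / (4 + c^2) - c
  oracle <- bisect_root(f, 2, 5)
  expect_equal(lim$fast$E_C, oracle, tolerance = 1e-9)
  expect_equal(lim$fast$p_open, oracle^2 / (4 + oracle^2), tolerance = 1e-9)
  # sandwich property across a (volume, k+) grid
  for (kp in c(0.005, 0.05)) {
    sch <- activated_reference(k_plus = kp)
    for (mult in c(1, 2, 4, 8)) {
      ms <- summarize_moments(solve_cme(sch, unitary_params(mult)))
      expect_gte(ms$E_C, lim$slow$E_C)
      expect_lte(ms$E_C, lim$fast$E_C)
      expect_gte(ms$p_open, lim$slow$p_open)
      expect_lte(ms$p_open, lim$fast$p_open)
    }
  }
  # no influx: both limits collapse onto the bulk-equilibrated values
  s0 <- make_scheme("single_regulated", "activated", alpha1 = 0,
                    kappa = 2, k_plus = 0.05)
  lim0 <- fast_slow_limits(s0, p)
  expect_equal(lim0$fast$E_C, lim0$slow$E_C, tolerance = 1e-9)
  expect_equal(lim0$fast$p_open, lim0$slow$p_open, tolerance = 1e-9)
})

test_that("E[C] and p_open grow monotonically with volume for the activated channel", {
  s <- activated_reference()
  ser <- vapply(c(1, 2, 4, 8), function(mult) {
    ms <- summarize_moments(solve_cme(s, unitary_params(mult)))
    c(ms$E_C, ms$p_open)
  }, numeric(2))
  expect_true(all(diff(ser[1, ]) > 0))
  expect_true(all(diff(ser[2, ]) > 0))
})
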