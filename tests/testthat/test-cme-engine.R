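test_that("state space counts states and guards bad truncations", {
  p <- unitary_params()
  s2 <- activated_reference()
  sp <- build_state_space(s2, p, n_max = 5)
  expect_equal(sp$n_total, 12L)
  expect_equal(nrow(sp$states), 12L)
  expect_false(any(duplicated(sp$states)))
  m4 <- make_scheme("multi_channel", "activated", alpha1 = 0.049,
                    kappa = 0.45, k_plus = 0.005, b_t = 4)
  expect_equal(build_state_space(m4, p, n_max = 100)$n_total, 505L)
  expect_error(build_state_space(s2, p, n_max = 1), "n_max")
})

test_that("auto truncation certifies the Poisson tail", {
  p <- unitary_params()
  u <- unregulated_reference(c_star_val = 5)   # lambda ~ 30
  sd1 <- solve_cme(u, p)
  n_max <- sd1$space$n_max
  expect_gte(n_max, 96)
  expect_lt(ppois(n_max - 3, 30.1107, lower.tail = FALSE), 1e-10)
  expect_lt(sd1$tail_mass, 1e-10)
})

test_that("generator rows sum to zero and respect the lattice boundaries", {
  p <- unitary_params()
  for (scheme in list(unregulated_reference(),
                      activated_reference(),
                      make_scheme("multi_channel", "inactivated",
                                  alpha0 = 0.049, kappa = 0.63,
                                  k_plus = 0.05, b_t = 3),
                      make_scheme("calmodulin", "activated", alpha1 = 0.049,
                                  kappa = 2, k_plus = 0.05, gamma_plus = 1,
                                  gamma_minus = 0.1, delta_plus = 0.2,
                                  delta_minus = 0.3))) {
    gen <- build_generator(build_state_space(scheme, p, n_max = 40))
    expect_lt(max(abs(Matrix::rowSums(gen$Q))), 1e-12)
    expect_true(all(gen$Q[cbind(1:nrow(gen$Q), 1:nrow(gen$Q))] <= 0))
  }
  # no binding transition out of n = 1 (combinatorial factor vanishes)
  s2 <- activated_reference()
  gen <- build_generator(build_state_space(s2, p, n_max = 10))
  i_n1_free <- 1L * 2L + 0L + 1L   # n = 1, m = 0, n-major order
  row <- gen$Q[i_n1_free, ]
  expect_equal(sum(row != 0), 3)   # influx, efflux, diagonal only
})

test_that("unregulated chain: stationary law is Poisson and detailed balance holds", {
  p <- unitary_params()
  u <- unregulated_reference(c_star_val = 5)
  sd1 <- solve_cme(u, p)
  lam <- influx_count_rate(u$alpha, p) / p$beta
  n_max <- sd1$space$n_max
  pois <- dpois(0:n_max, lam)
  expect_lt(0.5 * sum(abs(sd1$p[, 1] - pois)), 1e-10)   # total variation
  # detailed balance n beta p_n = alpha_bar p_{n-1} where mass is resolvable
  pr <- sd1$p[, 1]
  ab <- influx_count_rate(u$alpha, p)
  n <- which(pr[-length(pr)] > 1e-6)    # p_{n-1} well above round-off
  rel <- abs((n) * p$beta * pr[n + 1] - ab * pr[n]) / (ab * pr[n])
  expect_lt(max(rel), 1e-10)
})

test_that("truncation is converged: doubling n_max leaves E[C] unchanged", {
  p <- unitary_params()
  s2 <- activated_reference()
  sd1 <- solve_cme(s2, p)
  sd2 <- solve_cme(s2, p, n_max = 2L * sd1$space$n_max)
  e1 <- summarize_moments(sd1)$E_C
  e2 <- summarize_moments(sd2)$E_C
  expect_lt(abs(e1 - e2) / e2, 1e-8)
})

test_that("multi-channel generator with one channel equals the two-state generator", {
  p <- unitary_params()
  s1 <- activated_reference()
  m1 <- make_scheme("multi_channel", "activated", alpha1 = 0.049,
                    kappa = 2, k_plus = 0.05, b_t = 1)
  g1 <- build_generator(build_state_space(s1, p, n_max = 60))
  g2 <- build_generator(build_state_space(m1, p, n_max = 60))
  expect_equal(max(abs(g1$Q - g2$Q)), 0)
})

test_that("direct solve agrees with the inverse-iteration fallback", {
  p <- unitary_params()
  s2 <- activated_reference()
  gen <- build_generator(build_state_space(s2, p, n_max = 120))
  direct <- stationary_distribution(gen)
  A <- Matrix::t(gen$Q)
  eig <- dyadCME:::inverse_iteration(A)
  expect_lt(0.5 * sum(abs(as.vector(t(direct$p)) - eig)), 1e-8)
})

test_that("reducible chains are rejected with a reachability error", {
  p <- unitary_params()
  # k+ = 0 disconnects the two channel rows
  s0 <- make_scheme("single_regulated", "activated", alpha1 = 0.049,
                    kappa = 2, k_plus = 0)
  gen <- build_generator(build_state_space(s0, p, n_max = 60))
  expect_error(stationary_distribution(gen), "reducible")
})

test_that("transient solve conserves probability and matches the birth-death mean", {
  p <- unitary_params()
  u <- unregulated_reference(c_star_val = 5)
  gen <- build_generator(build_state_space(u, p, n_max = 120))
  p0 <- numeric(121); p0[1] <- 1                 # start empty
  t_grid <- seq(0, 600, by = 60)
  ts <- transient_solve(gen, p0, t_grid)
  expect_true(all(abs(rowSums(ts$p) - 1) < 1e-8))
  lam <- influx_count_rate(u$alpha, p) / p$beta
  mean_t <- as.numeric(ts$p %*% (0:120))
  expect_equal(mean_t, lam * (1 - exp(-p$beta * t_grid)), tolerance = 1e-7)
  # stationary initial condition is a fixed point
  sd1 <- stationary_distribution(gen)
  ts2 <- transient_solve(gen, as.vector(t(sd1$p)), c(0, 300))
  expect_lt(max(abs(ts2$p[2, ] - as.vector(t(sd1$p)))), 1e-8)
})
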