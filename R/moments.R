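# Joint and conditional moments of the stationary distribution, the
# printed moment-balance identities, and the fast/slow gating limits.

#' Closed-form Poisson predictions for the unregulated subspace
#'
#' The unregulated ion-count chain is a linear birth-death process whose
#' stationary law is Poisson with mean `lambda = (alpha + beta c_inf) *
#' ions_per_uM / beta`; mean and variance of the count coincide, the
#' expected concentration is `c_star = alpha/beta + c_inf`, the
#' concentration variance is `c_star^2 / lambda`, and the coefficient of
#' variation of count and concentration alike is `1 / sqrt(lambda)`.
#'
#' @param params A [subspace_params()] object.
#' @param alpha Influx rate, uM/ms.
#' @return A list with `lambda`, `E_count`, `Var_count`, `CV`, `E_C`
#'   (uM), `Var_C` (uM^2).
#' @examples
#' poisson_prediction(subspace_params(1e-17), 0.049)
#' @export
poisson_prediction <- function(params, alpha) {
  stopifnot(inherits(params, "subspace_params"))
  if (alpha < 0) stop("`alpha` must be >= 0")
  lambda <- influx_count_rate(alpha, params) / params$beta
  cs <- c_star(alpha, params$beta, params$c_inf)
  list(lambda = lambda, E_count = lambda, Var_count = lambda,
       CV = 1 / sqrt(lambda), E_C = cs,
       Var_C = cs / params$ions_per_uM)
}

#' Moment summary of a stationary distribution
#'
#' Computes, by direct summation over the truncated lattice, the joint
#' moments `mu[q, m] = sum_n n^q p[n, m]` for q = 0..3, the channel-state
#' marginals, the means and variances of the ion count conditional on each
#' channel state (in ions and uM), the overall expected concentration and
#' its CV, and the open probability (state marginals weighted by each
#' state's open fraction, which for single-channel schemes is the plain
#' sum over the open states).
#'
#' @param sdist A `"stationary_dist"` object from
#'   [stationary_distribution()] or [solve_cme()].
#' @return An object of class `"moment_summary"`.
#' @export
summarize_moments <- function(sdist) {
  stopifnot(inherits(sdist, "stationary_dist"))
  scheme <- sdist$space$scheme
  params <- sdist$space$params
  w <- params$ions_per_uM
  p <- sdist$p
  n <- 0:(nrow(p) - 1L)
  mu <- vapply(0:3, function(q) colSums(n^q * p), numeric(ncol(p)))
  mu <- t(matrix(mu, nrow = ncol(p)))      # 4 x n_states, rows q = 0..3
  rownames(mu) <- paste0("q", 0:3)
  p_state <- mu[1, ]
  cond_mean <- ifelse(p_state > 0, mu[2, ] / p_state, NA_real_)
  cond_var <- ifelse(p_state > 0, mu[3, ] / p_state - cond_mean^2, NA_real_)
  E_count <- sum(mu[2, ])
  Var_count <- sum(mu[3, ]) - E_count^2
  structure(
    list(mu = mu, p_state = p_state,
         conditional_mean = cond_mean, conditional_var = cond_var,
         conditional_mean_uM = cond_mean / w,
         conditional_var_uM2 = cond_var / w^2,
         E_count = E_count, Var_count = Var_count,
         E_C = E_count / w, Var_C = Var_count / w^2,
         CV_C = sqrt(Var_count) / E_count,
         p_open = sum(p_state * scheme$open_fraction),
         scheme = scheme, params = params),
    class = "moment_summary")
}

#' @export
print.moment_summary <- function(x, ...) {
  cat("Stationary moment summary\n")
  cat(sprintf("  E[C] = %.6g uM  (E[count] = %.6g, CV = %.4g)\n",
              x$E_C, x$E_count, x$CV_C))
  cat(sprintf("  p_open = %.6g; state marginals: %s\n", x$p_open,
              paste(signif(x$p_state, 4), collapse = ", ")))
  invisible(x)
}

#' One-row record of a moment summary
#'
#' @param x A `"moment_summary"` object.
#' @param row.names,optional,... Ignored (base generic signature).
#' @return A one-row data.frame suitable for appending to a batch table.
#' @export
as.data.frame.moment_summary <- function(x, row.names = NULL,
                                         optional = FALSE, ...) {
  out <- data.frame(E_C_uM = x$E_C, Var_C_uM2 = x$Var_C, CV_C = x$CV_C,
                    E_count = x$E_count, Var_count = x$Var_count,
                    p_open = x$p_open)
  for (m in seq_along(x$p_state))
    out[[paste0("p_state_", m - 1L)]] <- x$p_state[m]
  out
}

#' Stationarity residuals of the printed moment equations
#'
#' Evaluates the right-hand sides of the moment ODEs at the stationary
#' moments computed from the CME solution.  For the unregulated chain:
#' d(mu1)/dt = alpha_bar - beta mu1 and d(mu2)/dt = alpha_bar +
#' (2 alpha_bar + beta) mu1 - 2 beta mu2.  For the two-state regulated
#' channel, the zeroth- and first-moment equations couple the branches
#' through the binding terms (the hierarchy is not closed: the first-
#' moment equations involve mu2 and mu3, which is why these equations are
#' used as residual checks on the CME solution, never integrated as a
#' model).  All residuals should vanish at stationarity up to truncation
#' error.
#'
#' @param sdist A `"stationary_dist"` for an unregulated or two-state
#'   (`single_regulated`) scheme.
#' @return A named numeric vector of residuals (1/ms-scaled moment
#'   rates), with attribute `"scale"` = `max(alpha_bar, k_minus)` for
#'   relative comparison.
#' @export
check_moment_balance <- function(sdist) {
  stopifnot(inherits(sdist, "stationary_dist"))
  scheme <- sdist$space$scheme
  params <- sdist$space$params
  ms <- summarize_moments(sdist)
  mu <- ms$mu
  beta <- params$beta
  ab <- influx_count_rate(scheme$alpha, params)

  if (scheme$kind == "unregulated") {
    mu1 <- mu[2, 1]; mu2 <- mu[3, 1]
    res <- c(dmu1 = ab[1] - beta * mu1,
             dmu2 = ab[1] + (2 * ab[1] + beta) * mu1 - 2 * beta * mu2)
    attr(res, "scale") <- max(ab[1], beta)
    return(res)
  }
  if (scheme$kind != "single_regulated")
    stop(sprintf(
      "moment-balance residuals are defined for unregulated and two-state schemes, not `%s`",
      scheme$kind))

  kbar <- scheme$k_plus / params$ions_per_uM^2
  km <- scheme$k_minus
  mu0 <- mu[1, ]; mu1 <- mu[2, ]; mu2 <- mu[3, ]; mu3 <- mu[4, ]
  res <- c(
    dmu0_free  = -kbar * mu2[1] + kbar * mu1[1] + km * mu0[2],
    dmu0_bound =  kbar * mu2[1] - kbar * mu1[1] - km * mu0[2],
    dmu1_free  = ab[1] * mu0[1] - beta * mu1[1] - kbar * mu3[1] +
                 kbar * mu2[1] + km * mu1[2] + 2 * km * mu0[2],
    dmu1_bound = ab[2] * mu0[2] - beta * mu1[2] + kbar * mu3[1] -
                 3 * kbar * mu2[1] + 2 * kbar * mu1[1] - km * mu1[2])
  attr(res, "scale") <- max(ab, km)
  res
}

#' Bound-probability identity for the two-state channel
#'
#' At stationarity the calcium-bound marginal satisfies
#' `mu0_bound = (mu2_free - mu1_free) / (kappa^2 w^2)` with `w` the
#' ions-per-uM volume factor; both sides are returned so agreement can be
#' asserted.  In the large-system limit the identity becomes the Hill form
#' `(E0[C])^2 / (kappa^2 + (E0[C])^2)`.
#'
#' @param sdist A `"stationary_dist"` for a `single_regulated` scheme.
#' @return Named numeric vector `c(lhs, rhs)`.
#' @export
p_bound_identity <- function(sdist) {
  stopifnot(inherits(sdist, "stationary_dist"))
  scheme <- sdist$space$scheme
  if (scheme$kind != "single_regulated")
    stop("the bound-probability identity applies to the two-state scheme")
  ms <- summarize_moments(sdist)
  w <- sdist$space$params$ions_per_uM
  c(lhs = unname(ms$mu[1, 2]),
    rhs = unname((ms$mu[3, 1] - ms$mu[2, 1]) / (scheme$kappa^2 * w^2)))
}

#' Fast- and slow-gating limits of the regulated channel
#'
#' Bracketing values for the stationary mean concentration and open
#' probability of a two-state channel:
#' \describe{
#'   \item{slow}{gating much slower than concentration relaxation.
#'     Activated channel: transitions out of the (closed) calcium-free
#'     state occur with the subspace equilibrated at the bulk level, so
#'     `E[C] ~ c_inf` and `p_open ~ c_inf^2 / (kappa^2 + c_inf^2)`.
#'     Inactivated channel (complementary occupancy): binding occurs with
#'     the subspace equilibrated at the open-state level `c0* = alpha0 /
#'     beta + c_inf`, giving `p_open ~ kappa^2 / (kappa^2 + c0*^2)`.}
#'   \item{fast}{binding equilibrates instantaneously: the simultaneous
#'     solution of the Hill occupancy and the flux balance, i.e. the
#'     deterministic mean-field equilibrium.  When that equation is
#'     bistable the upper stable root is reported (the limit approached
#'     from large volumes).  Solved through the exact cubic with a Newton
#'     polish to residual < 1e-12.}
#' }
#' For the activated channel the CME values at any volume lie between the
#' two limits.
#'
#' @param scheme A `single_regulated` [make_scheme()] object.
#' @param params A [subspace_params()] object.
#' @return A list with elements `slow` and `fast`, each a list of `E_C`
#'   (uM) and `p_open`.
#' @export
fast_slow_limits <- function(scheme, params) {
  stopifnot(inherits(scheme, "channel_scheme"),
            inherits(params, "subspace_params"))
  if (scheme$kind != "single_regulated")
    stop("fast/slow limits are defined for the two-state scheme")
  kap <- scheme$kappa
  beta <- params$beta
  ci <- params$c_inf
  a0 <- scheme$alpha[1]; a1 <- scheme$alpha[2]
  activated <- identical(scheme$variant, "activated")

  if (activated) {
    p_slow <- ci^2 / (kap^2 + ci^2)
    slow <- list(E_C = ci, p_open = p_slow)
  } else {
    c0s <- a0 / beta + ci
    p_free_slow <- kap^2 / (kap^2 + c0s^2)
    slow <- list(E_C = p_free_slow * c0s + (1 - p_free_slow) * ci,
                 p_open = p_free_slow)
  }

  eq <- ode_steady_states(kind = scheme$variant, alpha0 = a0, alpha1 = a1,
                          beta = beta, c_inf = ci, kappa = kap)
  stable_c <- eq$equilibria$c[eq$equilibria$stability == "stable"]
  c_fast <- max(stable_c)
  p_fast <- if (activated) c_fast^2 / (kap^2 + c_fast^2)
            else kap^2 / (kap^2 + c_fast^2)
  list(slow = slow, fast = list(E_C = c_fast, p_open = p_fast))
}
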