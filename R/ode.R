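# Mean-field ODE counterparts: equilibria, stability, kappa-bifurcation
# structure, and trajectories.
#
# The steady-state concentration of the mean-field model solves
#   0 = alpha1 c^2/(kappa^2 + c^2) + alpha0 kappa^2/(kappa^2 + c^2)
#       - beta (c - c_inf),
# with the channel pool in binding equilibrium (free fraction
# kappa^2/(kappa^2 + c^2)).  Multiplying through by (kappa^2 + c^2) gives
# an exact cubic, whose real roots in [c_inf, c_star] are found with
# polyroot() and polished by Newton iteration, guaranteeing that every
# equilibrium of the bifurcation diagram is captured.

equilibrium_cubic <- function(alpha0, alpha1, beta, c_inf, kappa) {
  # coefficients of  -beta c^3 + (alpha1 + beta c_inf) c^2
  #                  - beta kappa^2 c + kappa^2 (beta c_inf + alpha0) = 0
  c(kappa^2 * (beta * c_inf + alpha0),  # c^0
    -beta * kappa^2,                    # c^1
    alpha1 + beta * c_inf,              # c^2
    -beta)                              # c^3
}

rhs_scalar <- function(c, alpha0, alpha1, beta, c_inf, kappa) {
  h <- c^2 / (kappa^2 + c^2)
  alpha1 * h + alpha0 * (1 - h) - beta * (c - c_inf)
}

rhs_scalar_deriv <- function(c, alpha0, alpha1, beta, c_inf, kappa) {
  hp <- 2 * c * kappa^2 / (kappa^2 + c^2)^2
  (alpha1 - alpha0) * hp - beta
}

#' Equilibria and stability of the mean-field subspace model
#'
#' Finds all steady states of the deterministic calcium balance for a
#' calcium-activated (`alpha1 > 0 = alpha0`) or calcium-inactivated
#' (`alpha0 > 0 = alpha1`) channel pool, with stability.  Scalar stability
#' uses the sign of the derivative of the reduced right-hand side; if
#' `k_plus` and `b_t_conc` are supplied the 2-D Jacobian of the full
#' (c, b) system is used instead, which classifies correctly even when
#' binding kinetics are slow.
#'
#' @param kind `"activated"` or `"inactivated"` (convenience presets for
#'   `alpha0`/`alpha1`; either may also be given explicitly).
#' @param alpha0,alpha1 Influx when calcium-free / bound, uM/ms.
#' @param beta Coupling rate, 1/ms.
#' @param c_inf Bulk concentration, uM.
#' @param kappa Dissociation constant, uM (> 0).
#' @param k_plus Optional association rate constant, 1/(uM^2 ms), for 2-D
#'   stability.
#' @param b_t_conc Optional total channel concentration, uM, for 2-D
#'   stability.
#' @return An object of class `"equilibrium_set"`: list with `equilibria`
#'   (data.frame `c`, `bound_fraction`, `stability`), `classification`
#'   (`"monostable"` or `"bistable"`), and the parameters.
#' @examples
#' ode_steady_states("activated", alpha1 = 0.049, beta = 0.01,
#'                   c_inf = 0.1, kappa = 2)
#' @export
ode_steady_states <- function(kind = c("activated", "inactivated"),
                              alpha0 = NULL, alpha1 = NULL, beta = 0.01,
                              c_inf = 0.1, kappa, k_plus = NULL,
                              b_t_conc = NULL) {
  kind <- match.arg(kind)
  if (kappa <= 0) stop("`kappa` must be positive")
  if (is.null(alpha0)) alpha0 <- 0
  if (is.null(alpha1)) alpha1 <- 0
  if (any(c(alpha0, alpha1) < 0) || beta <= 0 || c_inf < 0)
    stop("rates must be nonnegative and `beta` positive")

  cs_hi <- max(alpha0, alpha1) / beta + c_inf
  coef <- equilibrium_cubic(alpha0, alpha1, beta, c_inf, kappa)
  roots <- polyroot(coef)
  scale <- max(abs(roots), 1)
  real <- Re(roots[abs(Im(roots)) < 1e-8 * scale])
  real <- real[real >= c_inf - 1e-9 & real <= cs_hi + 1e-9]
  # Newton polish on the scalar rhs
  real <- vapply(real, function(r) {
    for (i in 1:50) {
      f <- rhs_scalar(r, alpha0, alpha1, beta, c_inf, kappa)
      if (abs(f) < 1e-14) break
      fp <- rhs_scalar_deriv(r, alpha0, alpha1, beta, c_inf, kappa)
      if (fp == 0) break
      r <- r - f / fp
    }
    r
  }, numeric(1))
  # dedupe within 1e-8 uM, keeping the polished values
  real <- sort(real)
  if (length(real) > 1)
    real <- real[c(TRUE, diff(real) > 1e-8)]
  real <- pmin(pmax(real, c_inf), cs_hi)

  stab <- vapply(real, function(r) {
    if (!is.null(k_plus) && !is.null(b_t_conc)) {
      b <- b_t_conc * kappa^2 / (kappa^2 + r^2)
      km <- kappa^2 * k_plus
      J <- matrix(c(
        -beta - k_plus * 2 * r * b,
        (alpha0 - alpha1) / b_t_conc - k_plus * r^2 - km,
        -2 * k_plus * r * b,
        -k_plus * r^2 - km), 2, 2, byrow = TRUE)
      max(Re(eigen(J, only.values = TRUE)$values)) < 0
    } else {
      rhs_scalar_deriv(r, alpha0, alpha1, beta, c_inf, kappa) < 0
    }
  }, logical(1))
  eq <- data.frame(c = real,
                   bound_fraction = real^2 / (kappa^2 + real^2),
                   stability = ifelse(stab, "stable", "unstable"))
  classification <- if (sum(stab) == 2 && length(real) == 3) "bistable"
                    else "monostable"
  structure(list(equilibria = eq, classification = classification,
                 kind = kind, kappa = kappa,
                 params = list(alpha0 = alpha0, alpha1 = alpha1,
                               beta = beta, c_inf = c_inf)),
            class = "equilibrium_set")
}

#' @export
print.equilibrium_set <- function(x, ...) {
  cat(sprintf("Mean-field equilibria (%s channel, kappa = %g uM): %s\n",
              x$kind, x$kappa, x$classification))
  print(x$equilibria, row.names = FALSE)
  invisible(x)
}

#' Bifurcation scan over the dissociation constant
#'
#' Tabulates all equilibria and their stability on a grid of `kappa`
#' values and reports the interval of bistability (empty for the
#' calcium-inactivated channel), with saddle-node endpoints bracketed to
#' the grid resolution.
#'
#' @inheritParams ode_steady_states
#' @param kappa_grid Increasing positive grid of dissociation constants,
#'   uM.
#' @return A data.frame with columns `kappa_uM`, `c_uM`, `stability`,
#'   `classification`; the bistable kappa-interval (or `NULL`) is attached
#'   as attribute `"bistable_interval"`.
#' @export
bifurcation_scan <- function(kind = c("activated", "inactivated"),
                             kappa_grid, alpha0 = NULL, alpha1 = NULL,
                             beta = 0.01, c_inf = 0.1) {
  kind <- match.arg(kind)
  if (any(diff(kappa_grid) <= 0) || any(kappa_grid <= 0))
    stop("`kappa_grid` must be increasing and positive")
  rows <- lapply(kappa_grid, function(k) {
    eq <- ode_steady_states(kind, alpha0 = alpha0, alpha1 = alpha1,
                            beta = beta, c_inf = c_inf, kappa = k)
    data.frame(kappa_uM = k, c_uM = eq$equilibria$c,
               stability = eq$equilibria$stability,
               classification = eq$classification)
  })
  out <- do.call(rbind, rows)
  bist <- unique(out$kappa_uM[out$classification == "bistable"])
  attr(out, "bistable_interval") <-
    if (length(bist)) range(bist) else NULL
  out
}

#' Mean-field trajectory of the (c, b) system
#'
#' Integrates the deterministic balance for subspace calcium and free
#' channel concentration from given initial conditions.  With
#' `b_t_conc = NULL` the reduced single-variable model with a constant
#' influx `alpha` is integrated instead (closed form
#' `c(t) = c_star + (c0 - c_star) exp(-beta t)`).
#'
#' @param c0 Initial concentration, uM.
#' @param t_grid Output times, ms.
#' @param alpha Constant influx for the reduced model, uM/ms.
#' @param alpha0,alpha1,kappa,k_plus Channel-pool parameters (full model).
#' @param b0 Initial free-channel concentration, uM (full model).
#' @param b_t_conc Total channel concentration, uM, or `NULL`.
#' @param beta,c_inf Coupling rate (1/ms) and bulk level (uM).
#' @return A data.frame with columns `t_ms`, `c_uM` (and `b_uM` for the
#'   full model).
#' @export
mean_field_trajectory <- function(c0, t_grid, alpha = NULL, beta = 0.01,
                                  c_inf = 0.1, alpha0 = 0, alpha1 = 0,
                                  kappa = NULL, k_plus = NULL, b0 = NULL,
                                  b_t_conc = NULL) {
  if (c0 < 0) stop("`c0` must be >= 0")
  if (is.null(b_t_conc)) {
    if (is.null(alpha)) stop("the reduced model needs `alpha`")
    rhs <- function(t, y, parms)
      list(alpha - beta * (y[1] - c_inf))
    sol <- deSolve::lsoda(c(c = c0), t_grid, rhs, NULL,
                          atol = 1e-12, rtol = 1e-10)
    return(data.frame(t_ms = sol[, 1], c_uM = sol[, 2]))
  }
  if (is.null(kappa) || is.null(k_plus))
    stop("the full model needs `kappa` and `k_plus`")
  if (is.null(b0)) b0 <- b_t_conc
  if (b0 < 0 || b0 > b_t_conc) stop("`b0` must lie in [0, b_t_conc]")
  km <- kappa^2 * k_plus
  rhs <- function(t, y, parms) {
    c <- y[1]; b <- max(min(y[2], b_t_conc), 0)
    bind <- k_plus * c^2 * b
    unbind <- km * (b_t_conc - b)
    list(c(alpha0 * b / b_t_conc + alpha1 * (b_t_conc - b) / b_t_conc -
             beta * (c - c_inf) - bind + unbind,
           -bind + unbind))
  }
  sol <- deSolve::lsoda(c(c = c0, b = b0), t_grid, rhs, NULL,
                        atol = 1e-12, rtol = 1e-10)
  if (attr(sol, "istate")[1] < 0)
    stop("mean-field integration failed; see deSolve diagnostics")
  data.frame(t_ms = sol[, 1], c_uM = sol[, 2], b_uM = sol[, 3])
}
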