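# Truncated state space, sparse infinitesimal generator, stationary and
# transient solves.
#
# States are ordered n-major: index(n, m) = n * n_states + m + 1 with
# m = 0..n_states-1 the channel-state index.  Channel-state transitions
# change n by at most 2, so with this ordering the generator stays banded
# (bandwidth ~ 2 * n_states) and sparse direct solves have negligible
# fill-in.  Truncation at n_max is reflecting: transitions that would
# leave [0, n_max] are dropped and counted, and every stationary solve
# carries a tail-mass certificate.

#' Truncated lattice of (ion count, channel state) pairs
#'
#' @param scheme A [make_scheme()] channel scheme.
#' @param params A [subspace_params()] object.
#' @param n_max Truncation bound for the ion count, an integer >= 2, or
#'   `"auto"` (default) to certify the bound by solving: start at
#'   `ceiling(lambda_high + 12 * sqrt(lambda_high))` with `lambda_high`
#'   the largest per-state mean count, then double until the stationary
#'   tail mass drops below `tail_tol`.
#' @param tail_tol Tail-mass tolerance used by auto truncation.
#' @return An object of class `"cme_state_space"` with fields `n_max`,
#'   `n_states`, `n_total` (= `(n_max + 1) * n_states`), `scheme`,
#'   `params`, and the index maps `states` (data.frame of `n`, `m`).
#' @export
build_state_space <- function(scheme, params, n_max = "auto",
                              tail_tol = 1e-10) {
  stopifnot(inherits(scheme, "channel_scheme"),
            inherits(params, "subspace_params"))
  if (identical(n_max, "auto")) {
    sol <- solve_cme(scheme, params, tail_tol = tail_tol)
    n_max <- sol$space$n_max
  }
  if (length(n_max) != 1 || n_max < 2 || n_max != floor(n_max))
    stop("`n_max` must be an integer >= 2 or \"auto\"")
  n_max <- as.integer(n_max)
  n_total <- (n_max + 1L) * scheme$n_states
  if (n_total > 1e7)
    stop(sprintf("refusing a state space of %d states (> 1e7)", n_total))
  structure(
    list(n_max = n_max, n_states = scheme$n_states, n_total = n_total,
         states = data.frame(n = rep(0:n_max, each = scheme$n_states),
                             m = rep.int(0:(scheme$n_states - 1L), n_max + 1L)),
         scheme = scheme, params = params),
    class = "cme_state_space")
}

#' @export
print.cme_state_space <- function(x, ...) {
  cat(sprintf("CME state space: n in [0, %d] x %d channel state(s) = %d states\n",
              x$n_max, x$n_states, x$n_total))
  invisible(x)
}

state_index <- function(n, m, n_states) n * n_states + m + 1L

# Triplet list (from, to, rate) of all off-diagonal generator entries;
# out-of-lattice transitions are dropped and counted.
generator_triplets <- function(space, scheme, params) {
  n_max <- space$n_max
  M <- scheme$n_states
  n <- 0:n_max
  w <- params$ions_per_uM
  beta <- params$beta
  alpha_bar <- influx_count_rate(scheme$alpha, params)   # ions/ms, per state
  tri <- vector("list", 2L * M + nrow(scheme$transitions))
  k <- 0L
  dropped <- 0L
  for (m in 0:(M - 1L)) {
    a <- alpha_bar[m + 1L]
    if (a > 0) {                                 # (n, m) -> (n + 1, m)
      nn <- n[n < n_max]
      k <- k + 1L
      tri[[k]] <- cbind(state_index(nn, m, M), state_index(nn + 1L, m, M), a)
      dropped <- dropped + 1L                    # influx out of n_max
    }
    nn <- n[n >= 1L]                             # (n, m) -> (n - 1, m)
    k <- k + 1L
    tri[[k]] <- cbind(state_index(nn, m, M), state_index(nn - 1L, m, M),
                      nn * beta)
  }
  tr <- scheme$transitions
  for (r in seq_len(nrow(tr))) {
    from <- tr$from[r] - 1L
    to <- tr$to[r] - 1L
    if (tr$ca_dependent[r]) {                    # (n, from) -> (n - 2, to)
      nn <- n[n >= 2L]
      rate <- nn * (nn - 1) * tr$mult[r] * tr$rate[r] / w^2
    } else if (tr$dn[r] == 2L) {                 # (n, from) -> (n + 2, to)
      nn <- n[n <= n_max - 2L]
      rate <- rep.int(tr$mult[r] * tr$rate[r], length(nn))
      dropped <- dropped + 2L                    # n_max-1, n_max rows clipped
    } else {                                     # (n, from) -> (n, to)
      nn <- n
      rate <- rep.int(tr$mult[r] * tr$rate[r], length(nn))
    }
    if (length(nn) && tr$rate[r] > 0) {
      k <- k + 1L
      tri[[k]] <- cbind(state_index(nn, from, M),
                        state_index(nn + tr$dn[r], to, M), rate)
    }
  }
  list(triplets = do.call(rbind, tri[seq_len(k)]), dropped = dropped)
}

#' Sparse infinitesimal generator on a truncated state space
#'
#' Entry Q\[i, j\] (i != j) is the i -> j transition rate; the diagonal
#' makes every row sum to zero.  Boundary transitions that would exit the
#' lattice are removed (reflecting truncation) and counted in the
#' `n_boundary_dropped` field.
#'
#' @param space A [build_state_space()] object.
#' @param scheme,params The scheme/parameters the space was built for
#'   (defaults: the ones stored in `space`).
#' @return An object of class `"cme_generator"`: list with the sparse
#'   `Matrix::dgCMatrix` `Q`, the `space`, and `n_boundary_dropped`.
#' @export
build_generator <- function(space, scheme = space$scheme,
                            params = space$params) {
  stopifnot(inherits(space, "cme_state_space"),
            inherits(scheme, "channel_scheme"),
            inherits(params, "subspace_params"))
  if (scheme$n_states != space$n_states)
    stop("scheme and state space disagree on the number of channel states")
  g <- generator_triplets(space, scheme, params)
  tr <- g$triplets
  N <- space$n_total
  d <- numeric(N)
  rs <- rowsum(tr[, 3], tr[, 1])
  d[as.integer(rownames(rs))] <- -rs
  Q <- Matrix::sparseMatrix(i = c(tr[, 1], seq_len(N)),
                            j = c(tr[, 2], seq_len(N)),
                            x = c(tr[, 3], d), dims = c(N, N))
  structure(list(Q = Q, space = space, n_boundary_dropped = g$dropped),
            class = "cme_generator")
}

#' @export
print.cme_generator <- function(x, ...) {
  cat(sprintf("CME generator: %d x %d, %d nonzeros (%d boundary transitions dropped)\n",
              nrow(x$Q), ncol(x$Q), Matrix::nnzero(x$Q), x$n_boundary_dropped))
  invisible(x)
}

# Strong connectivity of the transition graph (irreducibility of the chain).
check_irreducible <- function(Q) {
  A <- Q
  Matrix::diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(Matrix::drop0(A) != 0,
                                           mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  if (comp$no > 1L) {
    main <- which.max(comp$csize)
    bad <- which(comp$membership != main)
    stop(sprintf(
      "generator is reducible: %d state(s) outside the main communicating class (e.g. state index %s)",
      length(bad), paste(utils::head(bad, 5), collapse = ", ")))
  }
  invisible(TRUE)
}

# Solve pi Q = 0 by pinning state k (replace its balance equation with
# p_k = 1), solving the remaining banded system, and renormalizing.
pin_solve <- function(A, k) {
  N <- nrow(A)
  rhs <- -A[-k, k, drop = TRUE]
  x <- tryCatch(as.numeric(Matrix::solve(A[-k, -k], rhs)),
                error = function(e) NULL)
  if (is.null(x) || anyNA(x) || any(!is.finite(x))) return(NULL)
  p <- numeric(N)
  p[-k] <- x
  p[k] <- 1
  p[p < -1e-14 * max(p)] <- 0   # clip small negative round-off
  p[p < 0] <- 0
  p / sum(p)
}

# Inverse-iteration fallback: smallest-magnitude eigenpair of t(Q).
inverse_iteration <- function(A, shift = 1e-9, iters = 50, tol = 1e-12) {
  N <- nrow(A)
  B <- A - shift * Matrix::Diagonal(N)
  x <- rep(1 / N, N)
  for (i in seq_len(iters)) {
    y <- tryCatch(as.numeric(Matrix::solve(B, x)), error = function(e) NULL)
    if (is.null(y)) return(NULL)
    y <- y / sum(abs(y))
    if (max(abs(y - x)) < tol) { x <- y; break }
    x <- y
  }
  p <- abs(x)
  p / sum(p)
}

# Heuristic pin: lattice state nearest the fast-limit deterministic mode.
default_pin <- function(space, scheme, params) {
  M <- scheme$n_states
  w <- params$ions_per_uM
  kp <- scheme$k_plus
  if (is.null(kp) || kp == 0 || is.null(scheme$kappa) ||
      !is.finite(scheme$kappa)) {
    c_eq <- max(scheme$alpha) / params$beta + params$c_inf
    m_pin <- which.max(scheme$alpha) - 1L
  } else {
    kap <- scheme$kappa
    a_span <- scheme$alpha
    f <- function(c) {
      fb <- c^2 / (kap^2 + c^2)       # equilibrium bound fraction
      a <- a_span[1] * (1 - fb) + a_span[length(a_span)] * fb
      params$c_inf + a / params$beta - c
    }
    hi <- max(scheme$alpha) / params$beta + params$c_inf + 1e-9
    c_eq <- tryCatch(
      stats::uniroot(f, c(params$c_inf, max(hi, params$c_inf + 1e-9)),
                     tol = 1e-12)$root,
      error = function(e) max(scheme$alpha) / params$beta + params$c_inf)
    fb <- c_eq^2 / (kap^2 + c_eq^2)
    m_pin <- round(fb * (M - 1L))
  }
  n_pin <- min(space$n_max, max(0L, round(w * c_eq)))
  state_index(as.integer(n_pin), as.integer(m_pin), M)
}

#' Stationary distribution of a truncated CME generator
#'
#' Solves pi Q = 0 with sum(pi) = 1 by a sparse direct solve (one balance
#' equation replaced by a pinned-probability normalization; the pin is
#' relocated to the argmax of the solution and the solve repeated if the
#' residual exceeds `residual_tol`), with an inverse-iteration
#' (smallest-magnitude eigenpair) fallback.  The chain is checked for
#' irreducibility by strong connectivity before solving.
#'
#' @param generator A [build_generator()] object.
#' @param tail_tol Error if the tail mass (probability of the top three
#'   ion-count levels) exceeds this value; `NULL` disables the check.
#' @param residual_tol Acceptable stationarity residual `max|pi Q|`.
#' @param check Check irreducibility first (default `TRUE`).
#' @return An object of class `"stationary_dist"`: list with `p` (matrix,
#'   `(n_max + 1) x n_states`, rows = ion count), `tail_mass`, `residual`,
#'   `method`, plus the `space` it lives on.
#' @export
stationary_distribution <- function(generator, tail_tol = 1e-10,
                                    residual_tol = 1e-10, check = TRUE) {
  stopifnot(inherits(generator, "cme_generator"))
  space <- generator$space
  Q <- generator$Q
  if (check) check_irreducible(Q)
  A <- Matrix::t(Q)
  resid <- function(p) if (is.null(p)) Inf else max(abs(A %*% p))

  k <- default_pin(space, space$scheme, space$params)
  p <- pin_solve(A, k)
  r <- resid(p)
  method <- "sparse-direct"
  for (i in 1:3) {                       # re-pin at the mode if needed
    if (r < residual_tol) break
    k_new <- if (!is.null(p)) which.max(p) else ((k + 7L) %% nrow(A)) + 1L
    if (identical(k_new, k)) break
    k <- k_new
    p2 <- pin_solve(A, k)
    r2 <- resid(p2)
    if (r2 < r) { p <- p2; r <- r2 } else break
  }
  if (is.null(p) || r > residual_tol) {
    p2 <- inverse_iteration(A)
    r2 <- resid(p2)
    if (!is.null(p2) && r2 < r) { p <- p2; r <- r2; method <- "inverse-iteration" }
  }
  if (is.null(p)) stop("stationary solve failed (direct and eigen fallback)")

  pm <- matrix(p, nrow = space$n_max + 1L, ncol = space$n_states,
               byrow = TRUE)
  tail_mass <- sum(pm[max(1L, space$n_max - 1L):(space$n_max + 1L), ])
  if (!is.null(tail_tol) && tail_mass > tail_tol)
    stop(sprintf(
      "tail mass %.3g exceeds tolerance %.3g: increase n_max (reflecting truncation too tight)",
      tail_mass, tail_tol))
  structure(list(p = pm, tail_mass = tail_mass, residual = r,
                 method = method, space = space),
            class = "stationary_dist")
}

#' @export
print.stationary_dist <- function(x, ...) {
  cat(sprintf("Stationary distribution on %d x %d lattice (%s)\n",
              nrow(x$p), ncol(x$p), x$method))
  cat(sprintf("  residual max|pi Q| = %.3g, tail mass = %.3g\n",
              x$residual, x$tail_mass))
  invisible(x)
}

#' Tidy table of a stationary distribution
#'
#' @param x A `"stationary_dist"` object.
#' @param row.names,optional Ignored (base generic signature).
#' @param ... Ignored.
#' @return A data.frame with columns `n`, `channel_state` (0-based),
#'   `probability`, `concentration_uM`.
#' @export
as.data.frame.stationary_dist <- function(x, row.names = NULL,
                                          optional = FALSE, ...) {
  n_max <- nrow(x$p) - 1L
  M <- ncol(x$p)
  data.frame(
    n = rep(0:n_max, times = M),
    channel_state = rep(0:(M - 1L), each = n_max + 1L),
    probability = as.vector(x$p),
    concentration_uM = rep(0:n_max, times = M) / x$space$params$ions_per_uM)
}

#' Build and solve a CME in one call, with certified truncation
#'
#' Convenience wrapper used throughout the moment and deviation analyses:
#' picks `n_max` automatically (mean + 12 sd of the largest per-state
#' count, doubled until the tail certificate passes), builds the
#' generator, and returns the stationary distribution.
#'
#' @inheritParams build_state_space
#' @param residual_tol,check Passed to [stationary_distribution()].
#' @param n_max Integer truncation bound, or `"auto"`.
#' @return A `"stationary_dist"` object (its `space` records the final
#'   `n_max`).
#' @export
solve_cme <- function(scheme, params, n_max = "auto", tail_tol = 1e-10,
                      residual_tol = 1e-10, check = TRUE) {
  stopifnot(inherits(scheme, "channel_scheme"),
            inherits(params, "subspace_params"))
  auto <- identical(n_max, "auto")
  if (auto) {
    lam_high <- max(influx_count_rate(scheme$alpha, params)) / params$beta
    n_max <- max(20L, ceiling(lam_high + 12 * sqrt(lam_high)))
  }
  repeat {
    space <- structure(
      list(n_max = as.integer(n_max), n_states = scheme$n_states,
           n_total = (as.integer(n_max) + 1L) * scheme$n_states,
           states = NULL, scheme = scheme, params = params),
      class = "cme_state_space")
    if (space$n_total > 1e7)
      stop(sprintf("refusing a state space of %d states (> 1e7)",
                   space$n_total))
    gen <- build_generator(space)
    sd <- stationary_distribution(gen, tail_tol = if (auto) NULL else tail_tol,
                                  residual_tol = residual_tol, check = check)
    if (!auto || sd$tail_mass < tail_tol) return(sd)
    n_max <- n_max * 2L
  }
}

#' Transient solution of the master equation
#'
#' Integrates dp/dt = Q^T p with a stiff solver (`deSolve::lsoda`) from an
#' initial distribution on the same truncated lattice.
#'
#' @param generator A [build_generator()] object.
#' @param p0 Initial probability vector, length `n_total` (n-major order)
#'   or a `(n_max + 1) x n_states` matrix; must sum to 1.
#' @param t_grid Output times in ms (increasing, starting at 0).
#' @param atol,rtol Solver tolerances.
#' @return A list with `t` and `p`: a `length(t_grid) x n_total` matrix of
#'   distributions, checked to remain in \[0, 1\] and sum to 1 within 1e-8.
#' @export
transient_solve <- function(generator, p0, t_grid, atol = 1e-12,
                            rtol = 1e-10) {
  stopifnot(inherits(generator, "cme_generator"))
  N <- generator$space$n_total
  p0 <- as.vector(if (is.matrix(p0)) t(p0) else p0)
  if (length(p0) != N) stop("`p0` does not match the state space")
  if (abs(sum(p0) - 1) > 1e-10 || any(p0 < 0))
    stop("`p0` must be a probability distribution")
  tQ <- Matrix::t(generator$Q)
  rhs <- function(t, p, parms) list(as.numeric(tQ %*% p))
  sol <- deSolve::lsoda(y = p0, times = t_grid, func = rhs, parms = NULL,
                        atol = atol, rtol = rtol)
  if (attr(sol, "istate")[1] < 0)
    stop("transient integration failed; see deSolve diagnostics")
  P <- unname(sol[, -1, drop = FALSE])
  sums <- rowSums(P)
  if (any(abs(sums - 1) > 1e-8))
    stop("probability not conserved within 1e-8 along the trajectory")
  P[P < 0 & P > -1e-10] <- 0
  list(t = t_grid, p = P)
}
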