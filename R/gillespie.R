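# Exact-stochastic (Gillespie direct method) simulator, used as an
# independent verification oracle for every CME solve.  The trajectory
# core is compiled; the R layer handles configuration, seeding through
# R's RNG, batch-means error bars, and CME comparison.

#' Configuration for a stochastic simulation run
#'
#' @param scheme A [make_scheme()] channel scheme.
#' @param params A [subspace_params()] object.
#' @param t_end Simulated time, ms.
#' @param burn_in Initial transient discarded from all summaries, ms.
#' @param seed Integer RNG seed, recorded in the summary.
#' @param max_events Event-count guard; runs that hit it are flagged as
#'   truncated partial summaries.
#' @param n_hist Ion-count cap of the occupancy histogram (`"auto"`:
#'   mean + 12 sd of the largest per-state count).
#' @param n_batches Number of batch-means windows for standard errors.
#' @return An object of class `"ssa_config"`.
#' @export
ssa_config <- function(scheme, params, t_end, burn_in = 0, seed = 1L,
                       max_events = 1e8, n_hist = "auto", n_batches = 20L) {
  stopifnot(inherits(scheme, "channel_scheme"),
            inherits(params, "subspace_params"))
  if (t_end <= burn_in || burn_in < 0)
    stop("need `t_end` > `burn_in` >= 0")
  if (identical(n_hist, "auto")) {
    lam <- max(influx_count_rate(scheme$alpha, params)) / params$beta
    n_hist <- max(20L, ceiling(lam + 12 * sqrt(lam)))
  }
  structure(list(scheme = scheme, params = params, t_end = t_end,
                 burn_in = burn_in, seed = as.integer(seed),
                 max_events = max_events, n_hist = as.integer(n_hist),
                 n_batches = as.integer(n_batches)),
            class = "ssa_config")
}

#' Simulate the subspace with the Gillespie direct method
#'
#' Runs one exact trajectory of the (ion count, channel state) chain and
#' returns time-averaged summaries with batch-means standard errors.
#' Identical configuration and seed give an identical event sequence.
#'
#' @param config An [ssa_config()] object.
#' @param n0,m0 Initial ion count and channel state (defaults: the bulk-
#'   equilibrated count and state 1).
#' @param log_events Keep an event log (capped at `log_max` rows).
#' @param log_max Maximum number of logged events.
#' @return An object of class `"ssa_summary"`: time-averaged `E_C` (uM)
#'   and `E_count` with standard errors, `p_state` with standard errors,
#'   normalized occupancy histogram (`hist`), `p_open`, event counts,
#'   seed, and (optionally) the event log.
#' @export
ssa_simulate <- function(config, n0 = NULL, m0 = 1L, log_events = FALSE,
                         log_max = 100000L) {
  stopifnot(inherits(config, "ssa_config"))
  scheme <- config$scheme
  params <- config$params
  w <- params$ions_per_uM
  if (is.null(n0)) n0 <- max(0L, round(w * params$c_inf))
  if (m0 < 1L || m0 > scheme$n_states) stop("`m0` out of range")

  tr <- scheme$transitions
  k_eff <- ifelse(tr$ca_dependent, tr$mult * tr$rate / w^2,
                  tr$mult * tr$rate)
  set.seed(config$seed)
  raw <- ssa_run(alpha_bar = influx_count_rate(scheme$alpha, params),
                 beta = params$beta,
                 tr_from = as.integer(tr$from - 1L),
                 tr_to = as.integer(tr$to - 1L),
                 tr_dn = as.integer(tr$dn),
                 tr_k = as.numeric(k_eff),
                 tr_quad = tr$ca_dependent,
                 n0 = as.integer(n0), m0 = as.integer(m0 - 1L),
                 t_end = config$t_end, burn_in = config$burn_in,
                 n_cap = config$n_hist, n_batches = config$n_batches,
                 max_events = config$max_events,
                 log_max = if (log_events) as.integer(log_max) else 0L)

  span <- config$t_end - config$burn_in
  hist <- raw$hist / span
  B <- config$n_batches
  bw <- span / B
  batch_mean_n <- raw$batch_int_n / bw
  batch_p <- raw$batch_occ / bw
  E_count <- mean(batch_mean_n)
  se_count <- stats::sd(batch_mean_n) / sqrt(B)
  p_state <- colMeans(batch_p)
  se_state <- apply(batch_p, 2, stats::sd) / sqrt(B)

  structure(
    list(E_C = E_count / w, se_E_C = se_count / w,
         E_count = E_count, se_count = se_count,
         p_state = p_state, se_state = se_state,
         p_open = sum(p_state * scheme$open_fraction),
         hist = hist, clamped_fraction = raw$clamped_time / span,
         events = raw$events, react_count = raw$react_count,
         truncated = raw$truncated, seed = config$seed,
         t_end = config$t_end, burn_in = config$burn_in,
         n_batches = B, scheme = scheme, params = params,
         event_log = if (log_events) raw$log else NULL),
    class = "ssa_summary")
}

#' @export
print.ssa_summary <- function(x, ...) {
  cat(sprintf("SSA summary (seed %d, %.0f events%s)\n", x$seed, x$events,
              if (x$truncated) ", TRUNCATED at max_events" else ""))
  cat(sprintf("  E[C] = %.5g +/- %.2g uM; p_open = %.4g\n",
              x$E_C, x$se_E_C, x$p_open))
  cat(sprintf("  p_state: %s\n", paste(signif(x$p_state, 4), collapse = ", ")))
  invisible(x)
}

#' One-row record of an SSA summary
#'
#' @param x An `"ssa_summary"` object.
#' @param row.names,optional,... Ignored (base generic signature).
#' @return A one-row data.frame.
#' @export
as.data.frame.ssa_summary <- function(x, row.names = NULL,
                                      optional = FALSE, ...) {
  out <- data.frame(E_C_uM = x$E_C, se_E_C_uM = x$se_E_C,
                    E_count = x$E_count, se_count = x$se_count,
                    p_open = x$p_open, events = x$events, seed = x$seed)
  for (m in seq_along(x$p_state)) {
    out[[paste0("p_state_", m - 1L)]] <- x$p_state[m]
    out[[paste0("se_state_", m - 1L)]] <- x$se_state[m]
  }
  out
}

#' Compare an SSA summary against a CME stationary solution
#'
#' Computes z-scores for the expected count and each channel-state
#' marginal (SSA batch-means standard errors) and the total-variation
#' distance between the SSA occupancy histogram and the CME distribution
#' on the common lattice.
#'
#' @param summary An [ssa_simulate()] result.
#' @param sdist A `"stationary_dist"` for the same scheme and parameters.
#' @param z_threshold Pass/fail threshold on the absolute z-scores.
#' @return A list with `z_E_count`, `z_state`, `tv_distance`, `pass`.
#' @export
compare_to_cme <- function(summary, sdist, z_threshold = 4) {
  stopifnot(inherits(summary, "ssa_summary"),
            inherits(sdist, "stationary_dist"))
  if (ncol(summary$hist) != ncol(sdist$p))
    stop("SSA and CME state spaces have different channel-state counts")
  ms <- summarize_moments(sdist)
  z_E <- (summary$E_count - ms$E_count) / summary$se_count
  z_state <- ifelse(summary$se_state > 0,
                    (summary$p_state - ms$p_state) / summary$se_state, 0)
  n_common <- min(nrow(summary$hist), nrow(sdist$p))
  h1 <- summary$hist[seq_len(n_common), , drop = FALSE]
  h2 <- sdist$p[seq_len(n_common), , drop = FALSE]
  tv <- 0.5 * (sum(abs(h1 - h2)) +
               abs(sum(summary$hist) - sum(h1)) +
               abs(sum(sdist$p) - sum(h2)))
  zs <- c(z_E, z_state)
  list(z_E_count = z_E, z_state = z_state, tv_distance = tv,
       pass = all(abs(zs) < z_threshold))
}
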