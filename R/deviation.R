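# The headline analysis: small-system deviation Delta of the expected
# stationary concentration from its large-system limit, as a function of
# unitary volume, influx strength, binding kinetics and channel
# multiplicity.
#
# Delta = (E[C]_small - E[C]_large) / E[C]_large, with E[C]_small the CME
# mean at v = v0 and E[C]_large the same quantity at the reference volume
# ref_multiplier * v0 (default 10, the numerical stand-in for the
# infinite-volume limit).  In multi_channel mode the channel count scales
# with the volume: 1 channel at v0 is compared against ref_multiplier
# channels at ref_multiplier * v0.

build_deviation_scheme <- function(kind, mode, c_star_val, kappa, k_plus,
                                   beta, c_inf, b_t = 1L) {
  a <- alpha_from_c_star(c_star_val, beta, c_inf)
  if (kind == "unregulated")
    return(make_scheme("unregulated", alpha = a))
  if (mode == "single_channel") {
    if (kind == "activated")
      make_scheme("single_regulated", "activated", alpha1 = a,
                  kappa = kappa, k_plus = k_plus)
    else
      make_scheme("single_regulated", "inactivated", alpha0 = a,
                  kappa = kappa, k_plus = k_plus)
  } else {
    if (kind == "activated")
      make_scheme("multi_channel", "activated", alpha1 = a, kappa = kappa,
                  k_plus = k_plus, b_t = b_t)
    else
      make_scheme("multi_channel", "inactivated", alpha0 = a, kappa = kappa,
                  k_plus = k_plus, b_t = b_t)
  }
}

#' Small-system deviation of the expected concentration
#'
#' Solves the stationary CME at the unitary volume and at the large-system
#' reference volume and returns the fractional deviation of the expected
#' concentration.  In `single_channel` mode both solves use one channel
#' (influx scales with volume through the count conversion); in
#' `multi_channel` mode the reference system carries `ref_multiplier`
#' channels, so that channel number grows in proportion to volume.
#'
#' @param kind `"activated"`, `"inactivated"`, or `"unregulated"` (for
#'   which the deviation vanishes identically).
#' @param v0 Unitary subspace volume, liters.
#' @param c_star Influx parameter: target deterministic concentration, uM.
#' @param kappa Dissociation constant, uM.
#' @param k_plus Association rate constant, 1/(uM^2 ms).
#' @param mode `"single_channel"` or `"multi_channel"` volume scaling.
#' @param beta,c_inf Coupling rate (1/ms) and bulk concentration (uM).
#' @param ref_multiplier Reference volume as a multiple of `v0` (integer
#'   in multi-channel mode; default 10).
#' @param tail_tol Truncation certificate passed to [solve_cme()].
#' @return An object of class `"deviation_result"`: `E_C_small`,
#'   `E_C_large` (uM), `delta` (signed fraction), `delta_percent`, the
#'   tail masses of both solves, and a parameter echo.
#' @examples
#' \donttest{
#' small_system_deviation("activated", v0 = 1e-17, c_star = 7,
#'                        kappa = 2, k_plus = 0.005)
#' }
#' @export
small_system_deviation <- function(kind = c("activated", "inactivated",
                                            "unregulated"),
                                   v0, c_star, kappa = NULL, k_plus = NULL,
                                   mode = c("single_channel",
                                            "multi_channel"),
                                   beta = 0.01, c_inf = 0.1,
                                   ref_multiplier = 10L, tail_tol = 1e-10) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (v0 <= 0) stop("`v0` must be positive")
  if (mode == "multi_channel" && ref_multiplier != floor(ref_multiplier))
    stop("in multi-channel mode the reference multiplier must be an integer channel count")
  if (kind != "unregulated" && (is.null(kappa) || is.null(k_plus)))
    stop("regulated kinds need `kappa` and `k_plus`")

  sch_small <- build_deviation_scheme(kind, mode, c_star, kappa, k_plus,
                                      beta, c_inf, b_t = 1L)
  sch_large <- if (mode == "multi_channel" && kind != "unregulated")
    build_deviation_scheme(kind, mode, c_star, kappa, k_plus, beta, c_inf,
                           b_t = as.integer(ref_multiplier))
  else sch_small

  sd_small <- solve_cme(sch_small, subspace_params(v0, beta, c_inf),
                        tail_tol = tail_tol)
  sd_large <- solve_cme(sch_large,
                        subspace_params(ref_multiplier * v0, beta, c_inf),
                        tail_tol = tail_tol)
  ms_small <- summarize_moments(sd_small)
  ms_large <- summarize_moments(sd_large)
  delta <- (ms_small$E_C - ms_large$E_C) / ms_large$E_C
  structure(
    list(E_C_small = ms_small$E_C, E_C_large = ms_large$E_C,
         delta = delta, delta_percent = 100 * delta,
         p_open_small = ms_small$p_open, p_open_large = ms_large$p_open,
         tail_mass_small = sd_small$tail_mass,
         tail_mass_large = sd_large$tail_mass,
         parameters = list(kind = kind, mode = mode, v0 = v0,
                           c_star = c_star, kappa = kappa, k_plus = k_plus,
                           beta = beta, c_inf = c_inf,
                           ref_multiplier = ref_multiplier)),
    class = "deviation_result")
}

#' @export
print.deviation_result <- function(x, ...) {
  p <- x$parameters
  cat(sprintf("Small-system deviation (%s, %s)\n", p$kind, p$mode))
  cat(sprintf("  v0 = %g L, c_star = %g uM, reference at %gx\n",
              p$v0, p$c_star, p$ref_multiplier))
  cat(sprintf("  E[C] = %.5g uM (v0) vs %.5g uM (reference): Delta = %.2f%%\n",
              x$E_C_small, x$E_C_large, x$delta_percent))
  invisible(x)
}

#' Deviation surface over (unitary volume, influx strength)
#'
#' Computes the small-system deviation on a rectangular grid of unitary
#' volumes and influx parameters.  Cells whose CME solve fails are
#' recorded with `NA` and flagged rather than aborting the scan.
#'
#' @inheritParams small_system_deviation
#' @param v0_grid Unitary volumes, liters (default: five log-spaced
#'   points from the physiological unitary volume 1e-17 L up to 1e-15 L).
#' @param c_star_grid Influx parameters, uM (default: five points on
#'   \[1, 20\]).
#' @return An object of class `"deviation_surface"`: long-format
#'   data.frame `table` with columns `v0_liters`, `c_star_uM`,
#'   `delta_percent`, `e_c_small_uM`, `e_c_large_uM`, `tail_mass_small`,
#'   `tail_mass_large`, `failed`; plus summary fields
#'   `max_suppression_percent` (= max of -delta over the grid) and
#'   `argmax` (the cell attaining it).
#' @export
deviation_surface <- function(kind = c("activated", "inactivated"),
                              mode = c("multi_channel", "single_channel"),
                              v0_grid = 10^seq(-17, -15, length.out = 5),
                              c_star_grid = seq(1, 20, length.out = 5),
                              kappa, k_plus, beta = 0.01, c_inf = 0.1,
                              ref_multiplier = 10L, tail_tol = 1e-10) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (any(v0_grid <= 0) || any(c_star_grid <= 0))
    stop("grids must be positive")
  grid <- expand.grid(v0_liters = v0_grid, c_star_uM = c_star_grid,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    res <- tryCatch(
      small_system_deviation(kind, v0 = grid$v0_liters[i],
                             c_star = grid$c_star_uM[i], kappa = kappa,
                             k_plus = k_plus, mode = mode, beta = beta,
                             c_inf = c_inf, ref_multiplier = ref_multiplier,
                             tail_tol = tail_tol),
      error = function(e) e)
    if (inherits(res, "error"))
      data.frame(grid[i, ], delta_percent = NA_real_,
                 e_c_small_uM = NA_real_, e_c_large_uM = NA_real_,
                 tail_mass_small = NA_real_, tail_mass_large = NA_real_,
                 failed = TRUE)
    else
      data.frame(grid[i, ], delta_percent = res$delta_percent,
                 e_c_small_uM = res$E_C_small, e_c_large_uM = res$E_C_large,
                 tail_mass_small = res$tail_mass_small,
                 tail_mass_large = res$tail_mass_large, failed = FALSE)
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  ok <- !tab$failed
  imax <- if (any(ok)) which(ok)[which.min(tab$delta_percent[ok])] else NA
  structure(
    list(table = tab,
         max_suppression_percent = if (is.na(imax[1])) NA_real_
                                   else -tab$delta_percent[imax],
         argmax = if (is.na(imax[1])) NULL
                  else tab[imax, c("v0_liters", "c_star_uM")],
         kind = kind, mode = mode,
         parameters = list(kappa = kappa, k_plus = k_plus, beta = beta,
                           c_inf = c_inf, ref_multiplier = ref_multiplier)),
    class = "deviation_surface")
}

#' @export
print.deviation_surface <- function(x, ...) {
  cat(sprintf("Deviation surface (%s, %s): %d cells, %d failed\n",
              x$kind, x$mode, nrow(x$table), sum(x$table$failed)))
  if (!is.na(x$max_suppression_percent))
    cat(sprintf("  max suppression %.1f%% at v0 = %g L, c_star = %g uM\n",
                x$max_suppression_percent, x$argmax$v0_liters,
                x$argmax$c_star_uM))
  invisible(x)
}

#' Stationary summaries across volumes, with limit reference lines
#'
#' Solves the CME at integer multiples of the unitary volume for one or
#' more binding rate constants and tabulates `E[C]` and `p_open`,
#' attaching the fast/slow gating limits (single-channel mode) or the
#' mean-field equilibria (multi-channel mode) as reference values.
#'
#' @inheritParams small_system_deviation
#' @param multiples Positive integer volume multipliers.
#' @param k_plus_values Vector of association rate constants to sweep.
#' @return A data.frame with columns `multiple`, `v_liters`,
#'   `k_plus`, `E_C_uM`, `p_open`; the reference limits are attached as
#'   attribute `"limits"`.
#' @export
volume_series <- function(kind = c("activated", "inactivated"),
                          mode = c("single_channel", "multi_channel"),
                          v0, c_star, kappa, k_plus_values,
                          multiples = 1:8, beta = 0.01, c_inf = 0.1,
                          tail_tol = 1e-10) {
  kind <- match.arg(kind)
  mode <- match.arg(mode)
  if (any(multiples < 1 | multiples != floor(multiples)))
    stop("`multiples` must be positive integers")
  rows <- list()
  for (kp in k_plus_values) {
    for (mult in multiples) {
      b_t <- if (mode == "multi_channel") as.integer(mult) else 1L
      sch <- build_deviation_scheme(kind, mode, c_star, kappa, kp,
                                    beta, c_inf, b_t = b_t)
      sdist <- solve_cme(sch, subspace_params(mult * v0, beta, c_inf),
                         tail_tol = tail_tol)
      ms <- summarize_moments(sdist)
      rows[[length(rows) + 1L]] <-
        data.frame(multiple = mult, v_liters = mult * v0, k_plus = kp,
                   E_C_uM = ms$E_C, p_open = ms$p_open)
    }
  }
  out <- do.call(rbind, rows)
  sch1 <- build_deviation_scheme(kind, "single_channel", c_star, kappa,
                                 k_plus_values[1], beta, c_inf)
  attr(out, "limits") <- fast_slow_limits(sch1,
                                          subspace_params(v0, beta, c_inf))
  out
}
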