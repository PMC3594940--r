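# Physical parameters, unit conversions, and channel-regulation schemes.
#
# All internal rates are expressed in ions and milliseconds.  The "volume"
# that enters every propensity is w = ions_per_uM, the number of ions that
# one micromolar of concentration represents in a subspace of volume v
# (liters): w = v * N_A * 1e-6.  With that convention the microscopic
# two-ion binding propensity n(n-1) k+ / w^2 recovers the macroscopic
# mass-action rate k+ c^2 as the system grows.

#' Avogadro constant (exact SI value), per mole
#' @keywords internal
AVOGADRO <- 6.02214076e23

#' Physical environment of a calcium subspace
#'
#' Bundles the subspace volume, the passive coupling rate to the bulk
#' cytosol, the bulk calcium concentration, and the derived conversion
#' factor between concentration (uM) and ion count.
#'
#' @param v Subspace volume in liters (default `1e-17`, the unitary dyadic
#'   subspace volume).
#' @param beta Passive coupling (relaxation) rate to the bulk, in 1/ms
#'   (default `0.01`, i.e. a 100 ms equilibration time).
#' @param c_inf Bulk calcium concentration in uM (default `0.1`, the
#'   diastolic resting level).
#'
#' @return An object of class `"subspace_params"`: a list with fields `v`,
#'   `beta`, `c_inf` and `ions_per_uM` (= `v * 6.02214076e23 * 1e-6`).
#' @examples
#' p <- subspace_params(v = 1e-17)
#' count_from_concentration(0.1, p)   # ~0.6 resting ions
#' @export
subspace_params <- function(v = 1e-17, beta = 0.01, c_inf = 0.1) {
  stopifnot(is.numeric(v), length(v) == 1, is.finite(v),
            is.numeric(beta), length(beta) == 1, is.finite(beta),
            is.numeric(c_inf), length(c_inf) == 1, is.finite(c_inf))
  if (v <= 0) stop("subspace volume `v` must be positive (liters)")
  if (beta <= 0) stop("coupling rate `beta` must be positive (1/ms)")
  if (c_inf < 0) stop("bulk concentration `c_inf` must be >= 0 (uM)")
  structure(
    list(v = v, beta = beta, c_inf = c_inf,
         ions_per_uM = v * AVOGADRO * 1e-6),
    class = "subspace_params")
}

#' @export
print.subspace_params <- function(x, ...) {
  cat("Subspace parameters\n")
  cat(sprintf("  volume v       : %g L\n", x$v))
  cat(sprintf("  coupling beta  : %g /ms\n", x$beta))
  cat(sprintf("  bulk c_inf     : %g uM\n", x$c_inf))
  cat(sprintf("  ions per uM    : %g\n", x$ions_per_uM))
  invisible(x)
}

#' Convert between concentration and expected ion count
#'
#' `count_from_concentration()` maps a concentration in uM to the
#' (real-valued) number of ions it represents in the subspace volume;
#' `concentration_from_count()` is its inverse.
#'
#' @param c Concentration in uM (>= 0).
#' @param n Ion count (>= 0, need not be integer).
#' @param params A [subspace_params()] object.
#' @return A numeric vector of counts (resp. concentrations in uM).
#' @examples
#' p <- subspace_params(v = 1e-17)
#' count_from_concentration(5, p)  # ~30 ions
#' @export
count_from_concentration <- function(c, params) {
  stopifnot(inherits(params, "subspace_params"))
  if (any(c < 0)) stop("concentration must be >= 0")
  c * params$ions_per_uM
}

#' @rdname count_from_concentration
#' @export
concentration_from_count <- function(n, params) {
  stopifnot(inherits(params, "subspace_params"))
  if (any(n < 0)) stop("ion count must be >= 0")
  n / params$ions_per_uM
}

#' Total influx rate in ion units
#'
#' The upward transition rate of the ion-count birth-death chain for a
#' channel state with influx rate `alpha_m` (uM/ms): the channel flux plus
#' the passive flux from the bulk, converted to ions per ms.
#'
#' @param alpha_m Influx rate of the channel state, uM/ms (>= 0).
#' @param params A [subspace_params()] object.
#' @return Rate in ions/ms: `(alpha_m + beta * c_inf) * ions_per_uM`.
#' @export
influx_count_rate <- function(alpha_m, params) {
  stopifnot(inherits(params, "subspace_params"))
  if (any(alpha_m < 0)) stop("influx rate `alpha_m` must be >= 0")
  (alpha_m + params$beta * params$c_inf) * params$ions_per_uM
}

#' Microscopic two-calcium binding propensity
#'
#' Rate (1/ms) of the two-ion association step when `n` ions are present
#' and `free_units` binding-competent units (free channels) are available.
#' The combinatorial factor n(n-1) counts ordered pairs of ions, so that
#' the propensity approaches the mass-action rate `k_plus * c^2 *
#' free_units` in the macroscopic limit with c = n / w fixed.
#'
#' @param n Integer ion count (>= 0).
#' @param free_units Integer number of free binding units (>= 0).
#' @param k_plus Association rate constant, 1/(uM^2 ms).
#' @param params A [subspace_params()] object.
#' @return Propensity in 1/ms; zero whenever `n < 2`.
#' @export
binding_propensity <- function(n, free_units, k_plus, params) {
  stopifnot(inherits(params, "subspace_params"))
  if (any(n < 0) || any(n != floor(n))) stop("`n` must be a nonnegative integer")
  if (any(free_units < 0) || any(free_units != floor(free_units)))
    stop("`free_units` must be a nonnegative integer")
  if (k_plus < 0) stop("`k_plus` must be >= 0")
  n * (n - 1) * free_units * k_plus / params$ions_per_uM^2
}

#' Deterministic steady-state concentration and its inverse
#'
#' For a constant influx `alpha` the mean-field subspace concentration
#' relaxes to `c_star = alpha / beta + c_inf`.  `alpha_from_c_star()`
#' inverts the relation, which is how influx rates are specified throughout
#' the deviation sweeps ("influx parameter c_star").
#'
#' @param alpha Influx rate, uM/ms (>= 0).
#' @param beta Coupling rate, 1/ms (> 0).
#' @param c_inf Bulk concentration, uM (>= 0).
#' @param c_star Target steady-state concentration, uM (>= `c_inf`).
#' @return `c_star()`: concentration in uM. `alpha_from_c_star()`: influx
#'   in uM/ms.
#' @examples
#' c_star(0.049, 0.01, 0.1)  # 5 uM
#' @export
c_star <- function(alpha, beta, c_inf) {
  if (any(alpha < 0) || any(beta <= 0) || any(c_inf < 0))
    stop("rates must be nonnegative and `beta` positive")
  alpha / beta + c_inf
}

#' @rdname c_star
#' @export
alpha_from_c_star <- function(c_star, beta, c_inf) {
  if (any(beta <= 0) || any(c_inf < 0))
    stop("rates must be nonnegative and `beta` positive")
  if (any(c_star < c_inf))
    stop("`c_star` must be >= `c_inf` (influx cannot be negative)")
  beta * (c_star - c_inf)
}

# ---------------------------------------------------------------------------
# Channel schemes
# ---------------------------------------------------------------------------

new_channel_scheme <- function(kind, variant, alpha, transitions,
                               open_fraction, extra = list()) {
  n_states <- length(alpha)
  stopifnot(is.data.frame(transitions),
            all(c("from", "to", "rate", "mult", "dn", "ca_dependent") %in%
                names(transitions)))
  if (any(alpha < 0)) stop("per-state influx rates must be >= 0")
  if (nrow(transitions)) {
    with(transitions, {
      if (any(rate < 0)) stop("transition rates must be >= 0")
      if (any(mult < 1 | mult != floor(mult)))
        stop("transition multiplicities must be positive integers")
      if (any(from < 1 | from > n_states | to < 1 | to > n_states))
        stop("transition state indices out of range")
      if (any(from == to)) stop("self-transitions are not allowed")
      if (any(ca_dependent & dn != -2L))
        stop("calcium-dependent transitions must consume exactly 2 ions")
      if (any(!ca_dependent & !dn %in% c(0L, 2L)))
        stop("calcium-independent transitions release 0 or 2 ions")
    })
  }
  stopifnot(length(open_fraction) == n_states,
            all(open_fraction >= 0 & open_fraction <= 1))
  open_states <- which(open_fraction > 0)
  if (kind != "unregulated" && length(open_states) == 0)
    stop("regulated schemes must declare at least one open state")
  structure(
    c(list(kind = kind, variant = variant, n_states = n_states,
           alpha = alpha, transitions = transitions,
           open_fraction = open_fraction, open_states = open_states),
      extra),
    class = "channel_scheme")
}

transition_row <- function(from, to, rate, mult = 1L, dn = 0L,
                           ca_dependent = FALSE) {
  data.frame(from = as.integer(from), to = as.integer(to), rate = rate,
             mult = as.integer(mult), dn = as.integer(dn),
             ca_dependent = ca_dependent)
}

#' Construct a channel-regulation scheme
#'
#' A scheme is the channel-state machine that sits on top of the ion-count
#' birth-death chain: per-state influx rates `alpha_m` (uM/ms), calcium-
#' dependent transitions (two-ion binding at propensity
#' n(n-1) k+ mult / w^2), and calcium-independent transitions (two-ion
#' release at k-, or conformational steps that move no ions).
#'
#' Four kinds are supported:
#' \describe{
#'   \item{`unregulated`}{one state, constant influx `alpha`.}
#'   \item{`single_regulated`}{two states (calcium-free, calcium-bound) for
#'     a single channel with a two-calcium binding site.  The `activated`
#'     variant is closed when calcium-free (influx `alpha0`, default 0) and
#'     open when bound (influx `alpha1`); the `inactivated` variant is open
#'     when free (`alpha0`) and closed when bound (`alpha1`, default 0).}
#'   \item{`multi_channel`}{`b_t` identical two-state channels sharing the
#'     subspace; the aggregate state m = 0..b_t counts bound channels and
#'     the influx interpolates, `alpha_m = alpha0 (b_t - m)/b_t +
#'     alpha1 m / b_t`.}
#'   \item{`calmodulin`}{the four-state resident-regulator scheme
#'     S1 = lobe parked at a pre-association site, S2 = unbound,
#'     S3 = two calcium ions bound, S4 = calcium-bound and engaged with the
#'     effector site.  Only S4 alters channel activity: the `activated`
#'     variant conducts `alpha1` in S4 and `alpha0` elsewhere; the
#'     `inactivated` variant the other way around.}
#' }
#'
#' @param kind One of `"unregulated"`, `"single_regulated"`,
#'   `"multi_channel"`, `"calmodulin"`.
#' @param variant `"activated"` or `"inactivated"` (ignored for
#'   `unregulated`).
#' @param alpha Influx rate for the unregulated scheme, uM/ms.
#' @param alpha0,alpha1 Influx when calcium-free / calcium-bound (S4 for
#'   calmodulin), uM/ms.  The closed-state rate defaults to 0.
#' @param kappa Dissociation constant for the two-calcium site, uM
#'   (`kappa^2 = k_minus / k_plus`).  Give either `kappa` or `k_minus`.
#' @param k_plus Association rate constant, 1/(uM^2 ms).
#' @param k_minus Dissociation rate, 1/ms.  Derived from `kappa` if absent.
#' @param b_t Total channel count for `multi_channel` (positive integer).
#' @param gamma_plus,gamma_minus,delta_plus,delta_minus Calmodulin
#'   conformational rates, 1/ms: S1 -> S2 at `gamma_minus`, S2 -> S1 at
#'   `delta_minus`, S3 -> S4 at `gamma_plus`, S4 -> S3 at `delta_plus`.
#'
#' @return An object of class `"channel_scheme"`.
#' @examples
#' make_scheme("single_regulated", "activated",
#'             alpha1 = 0.049, kappa = 2, k_plus = 0.05)
#' @export
make_scheme <- function(kind = c("unregulated", "single_regulated",
                                 "multi_channel", "calmodulin"),
                        variant = c("activated", "inactivated"),
                        alpha = NULL, alpha0 = NULL, alpha1 = NULL,
                        kappa = NULL, k_plus = NULL, k_minus = NULL,
                        b_t = 1L,
                        gamma_plus = NULL, gamma_minus = NULL,
                        delta_plus = NULL, delta_minus = NULL) {
  kind <- match.arg(kind)

  if (kind == "unregulated") {
    if (is.null(alpha)) stop("`alpha` is required for an unregulated scheme")
    if (alpha < 0) stop("`alpha` must be >= 0")
    return(new_channel_scheme(
      kind, NA_character_, alpha = alpha,
      transitions = transition_row(1, 1, 0)[0, ],
      open_fraction = 1))
  }

  variant <- match.arg(variant)
  if (is.null(k_plus)) stop("`k_plus` is required for regulated schemes")
  if (k_plus < 0) stop("`k_plus` must be >= 0")
  if (is.null(k_minus)) {
    if (is.null(kappa)) stop("give either `kappa` or `k_minus`")
    if (kappa < 0) stop("`kappa` must be >= 0")
    k_minus <- kappa^2 * k_plus
  } else {
    if (k_minus < 0) stop("`k_minus` must be >= 0")
    kappa <- if (k_plus > 0) sqrt(k_minus / k_plus) else Inf
  }
  if (variant == "activated") {
    if (is.null(alpha1)) stop("activated schemes need `alpha1`")
    if (is.null(alpha0)) alpha0 <- 0
  } else {
    if (is.null(alpha0)) stop("inactivated schemes need `alpha0`")
    if (is.null(alpha1)) alpha1 <- 0
  }
  if (alpha0 < 0 || alpha1 < 0) stop("influx rates must be >= 0")

  if (kind == "single_regulated") {
    trans <- rbind(
      transition_row(1, 2, k_plus, dn = -2L, ca_dependent = TRUE),
      transition_row(2, 1, k_minus, dn = 2L))
    open_fraction <- if (variant == "activated") c(0, 1) else c(1, 0)
    return(new_channel_scheme(
      kind, variant, alpha = c(alpha0, alpha1), transitions = trans,
      open_fraction = open_fraction,
      extra = list(kappa = kappa, k_plus = k_plus, k_minus = k_minus)))
  }

  if (kind == "multi_channel") {
    if (length(b_t) != 1 || b_t < 1 || b_t != floor(b_t))
      stop("`b_t` must be a positive integer channel count")
    b_t <- as.integer(b_t)
    m <- 0:b_t                          # bound-channel count per state
    alpha_m <- alpha0 * (b_t - m) / b_t + alpha1 * m / b_t
    trans <- do.call(rbind, c(
      lapply(seq_len(b_t), function(s) {  # state s has m = s - 1 bound
        transition_row(s, s + 1L, k_plus, mult = b_t - (s - 1L),
                       dn = -2L, ca_dependent = TRUE)
      }),
      lapply(seq_len(b_t), function(s) {
        transition_row(s + 1L, s, k_minus, mult = s, dn = 2L)
      })))
    frac_bound <- m / b_t
    open_fraction <- if (variant == "activated") frac_bound else 1 - frac_bound
    return(new_channel_scheme(
      kind, variant, alpha = alpha_m, transitions = trans,
      open_fraction = open_fraction,
      extra = list(kappa = kappa, k_plus = k_plus, k_minus = k_minus,
                   b_t = b_t)))
  }

  # calmodulin: S1 <-> S2 <-> S3 <-> S4
  for (nm in c("gamma_plus", "gamma_minus", "delta_plus", "delta_minus")) {
    val <- get(nm)
    if (is.null(val)) stop(sprintf("calmodulin schemes need `%s`", nm))
    if (val < 0) stop(sprintf("`%s` must be >= 0", nm))
  }
  trans <- rbind(
    transition_row(1, 2, gamma_minus),
    transition_row(2, 1, delta_minus),
    transition_row(2, 3, k_plus, dn = -2L, ca_dependent = TRUE),
    transition_row(3, 2, k_minus, dn = 2L),
    transition_row(3, 4, gamma_plus),
    transition_row(4, 3, delta_plus))
  alpha_states <- c(alpha0, alpha0, alpha0, alpha1)  # S4 is the effector state
  open_fraction <- if (variant == "activated") c(0, 0, 0, 1) else c(1, 1, 1, 0)
  new_channel_scheme(
    kind, variant, alpha = alpha_states, transitions = trans,
    open_fraction = open_fraction,
    extra = list(kappa = kappa, k_plus = k_plus, k_minus = k_minus,
                 gamma_plus = gamma_plus, gamma_minus = gamma_minus,
                 delta_plus = delta_plus, delta_minus = delta_minus))
}

#' @export
print.channel_scheme <- function(x, ...) {
  cat(sprintf("Channel scheme: %s%s, %d state(s)\n", x$kind,
              if (!is.na(x$variant)) paste0(" (", x$variant, ")") else "",
              x$n_states))
  cat("  influx alpha_m (uM/ms):", signif(x$alpha, 4), "\n")
  if (!is.null(x$kappa))
    cat(sprintf("  kappa = %g uM, k+ = %g /uM^2/ms, k- = %g /ms\n",
                x$kappa, x$k_plus, x$k_minus))
  if (nrow(x$transitions)) {
    cat(sprintf("  %d channel-state transition(s); open state(s): %s\n",
                nrow(x$transitions), paste(x$open_states, collapse = ", ")))
  }
  invisible(x)
}
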