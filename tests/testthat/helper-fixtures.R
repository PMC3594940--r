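# Shared builders for the canonical study conditions.

unitary_params <- function(mult = 1) subspace_params(v = mult * 1e-17)

# reference single calcium-activated channel: kappa = 2 uM,
# k+ = 0.05 /uM^2/ms, c_star = 5 uM
activated_reference <- function(k_plus = 0.05, c_star_val = 5,
                                kappa = 2) {
  make_scheme("single_regulated", "activated",
              alpha1 = alpha_from_c_star(c_star_val, 0.01, 0.1),
              kappa = kappa, k_plus = k_plus)
}

inactivated_reference <- function(k_plus = 0.05, c_star_val = 5,
                                  kappa = 0.63) {
  make_scheme("single_regulated", "inactivated",
              alpha0 = alpha_from_c_star(c_star_val, 0.01, 0.1),
              kappa = kappa, k_plus = k_plus)
}

unregulated_reference <- function(c_star_val = 5) {
  make_scheme("unregulated",
              alpha = alpha_from_c_star(c_star_val, 0.01, 0.1))
}

# bisection oracle for a scalar root on a bracket
bisect_root <- function(f, lo, hi, tol = 1e-12) {
  flo <- f(lo)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(hi - lo) < tol) break
    if (sign(fm) == sign(flo)) { lo <- mid; flo <- fm } else hi <- mid
  }
  (lo + hi) / 2
}
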