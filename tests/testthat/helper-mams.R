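# Shared fixtures for the test suite. All randomness is seeded in the tests.

# the worked example setting: K = 4 arms, equal weights, rho = 0.4
tailor_design <- function(...) rb_design(...)

# boundaries object assembled by hand (for degenerate-boundary tests)
mk_bounds <- function(u_E, u_S, info_E, info_S = info_E) {
  structure(list(u_E = u_E, u_S = u_S, info_E = info_E, info_S = info_S),
            class = "rb_boundaries")
}

# scores object assembled by hand
mk_scores <- function(Z_E, Z_S, info_E, info_S = info_E) {
  structure(list(Z_E = Z_E, Z_S = Z_S, info_E = info_E, info_S = info_S),
            class = "rb_scores")
}

oc1 <- function(...) mamsrb:::oc_single(...)
ocJ <- function(...) mamsrb:::oc_multistage(...)

binom_bound <- function(p, reps, k = 3) p + k * sqrt(p * (1 - p) / reps)
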