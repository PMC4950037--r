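# Operating-characteristics engine: seeded sweeps reproducing the design's
# simulation studies at configurable replication, returning long-format data
# frames (one row per configuration and metric).

# per-configuration seeds derived from one master seed
derive_seeds <- function(master_seed, n) {
  set.seed(master_seed)
  sample.int(.Machine$integer.max - 1L, n)
}

binom_se <- function(p, reps) sqrt(p * (1 - p) / reps)

#' Design solutions across a grid of selection weights
#'
#' Re-solves the single-stage design (information search plus boundaries) for
#' each efficacy weight in `w_E_grid`, with `w_S = sqrt(1 - w_E^2)`. Required
#' information decreases as the weight on efficacy grows, and the efficacy
#' and safety boundaries coincide at equal weights.
#'
#' @param design Template [rb_design()]; its weights are overridden.
#' @param w_E_grid Efficacy weights in `[0, 1]`.
#' @return Data frame with columns `w_E`, `I_star`, `n_unrounded`, `u_E`,
#'   `u_S` (boundaries at `I_star`).
#' @export
sweep_weights <- function(design, w_E_grid = seq(0, 1, by = 0.1)) {
  stopifnot(all(w_E_grid >= 0 & w_E_grid <= 1))
  rows <- lapply(w_E_grid, function(w) {
    d <- design
    d$w_E <- w
    d$w_S <- sqrt(1 - w^2)
    sol <- solve_information(d)
    data.frame(w_E = w, I_star = sol$I_star, n_unrounded = sol$n_unrounded,
               u_E = sol$boundaries_at_I_star$u_E,
               u_S = sol$boundaries_at_I_star$u_S)
  })
  do.call(rbind, rows)
}

#' Empirical FWER and power over a grid of common effects
#'
#' Simulates the designed test under configurations where every arm shares
#' the same pair of effects `(gamma_E, gamma_S)` versus control, the setting
#' of the error-rate surface study: the FWER is maximised when one effect
#' sits at the null boundary and the other is large.
#'
#' @param design An [rb_design()].
#' @param boundaries Solved `rb_boundaries` for the design.
#' @param gamma_E_grid,gamma_S_grid Common effect grids.
#' @param reps Replicates per grid point.
#' @param seed Master seed; per-point substreams are derived from it.
#' @return Long data frame: one row per grid point with `p_reject`, `fwer`,
#'   `p_none`, standard error, replicates and substream seed.
#' @export
fwer_power_grid <- function(design, boundaries,
                            gamma_E_grid = c(0, 0.1, 0.25, 0.545),
                            gamma_S_grid = c(0, 0.25, 0.5, 1),
                            reps = 1e4, seed = 1) {
  grid <- expand.grid(gamma_E = gamma_E_grid, gamma_S = gamma_S_grid)
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    oc <- oc_single(design,
                    theta_E = rep(grid$gamma_E[i], design$K),
                    theta_S = rep(grid$gamma_S[i], design$K),
                    boundaries = boundaries, reps = reps, seed = seeds[i])
    data.frame(gamma_E = grid$gamma_E[i], gamma_S = grid$gamma_S[i],
               p_reject = oc[["p_reject"]], fwer = oc[["fwer"]],
               p_none = oc[["p_none"]],
               se = binom_se(oc[["p_reject"]], reps),
               reps = reps, seed = seeds[i])
  })
  do.call(rbind, rows)
}

# the 2^K per-arm patterns: each arm either (0, huge) or (huge, 0)
mixed_null_patterns <- function(K) {
  expand.grid(rep(list(c(FALSE, TRUE)), K), KEEP.OUT.ATTRS = FALSE)
}

#' Empirical FWER under mixed worst-case null configurations
#'
#' Enumerates all `2^K` per-arm patterns in which one endpoint's effect is
#' zero and the other is the large surrogate, the configurations probing the
#' strong-control conjecture: every pattern keeps each arm's null hypothesis
#' true, so any rejection is a familywise error.
#'
#' @inheritParams fwer_power_grid
#' @return Long data frame: one row per pattern (`pattern` encodes which
#'   arms have the large *efficacy* effect) with empirical `fwer`, `se`,
#'   `reps`, `seed`.
#' @export
mixed_null_fwer <- function(design, boundaries, reps = 1e4, seed = 1) {
  pats <- mixed_null_patterns(design$K)
  seeds <- derive_seeds(seed, nrow(pats))
  g <- design$gamma_surrogate
  rows <- lapply(seq_len(nrow(pats)), function(i) {
    eff_big <- unlist(pats[i, ])
    theta_E <- ifelse(eff_big, g, 0)
    theta_S <- ifelse(eff_big, 0, g)
    oc <- oc_single(design, theta_E, theta_S, boundaries,
                    reps = reps, seed = seeds[i])
    data.frame(pattern = paste(ifelse(eff_big, "E", "S"), collapse = ""),
               fwer = oc[["fwer"]], se = binom_se(oc[["fwer"]], reps),
               reps = reps, seed = seeds[i])
  })
  do.call(rbind, rows)
}

# the six correlation-robustness configurations: global null plus five
# worst-case patterns (all arms at one endpoint's limit, and mixed splits)
rho_sweep_configs <- function(design) {
  K <- design$K
  g <- design$gamma_surrogate
  cfg <- list(global_null = list(theta_E = rep(0, K), theta_S = rep(0, K)),
              all_safe    = list(theta_E = rep(0, K), theta_S = rep(g, K)),
              all_effective = list(theta_E = rep(g, K), theta_S = rep(0, K)))
  m_split <- pmin(K - 1, c(1, 2, 3))
  for (m in unique(m_split)) {
    cfg[[paste0("mixed_", m)]] <-
      list(theta_E = c(rep(g, m), rep(0, K - m)),
           theta_S = c(rep(0, m), rep(g, K - m)))
  }
  cfg
}

#' FWER robustness to misspecified correlation
#'
#' Boundaries are solved at the design's correlation, then trials are
#' simulated at each `true_rho`, over six effect configurations: the global
#' null and five worst-case patterns built from the large surrogate effect.
#' The procedure is conservative when the true correlation is below the
#' design value; the maximum inflation occurs under perfect correlation.
#'
#' @inheritParams fwer_power_grid
#' @param true_rho_grid Correlations used to generate the data.
#' @return Long data frame: one row per (configuration, true rho).
#' @export
rho_misspecification <- function(design, boundaries,
                                 true_rho_grid = c(-0.5, 0, 0.4, 0.7, 1),
                                 reps = 1e4, seed = 1) {
  cfg <- rho_sweep_configs(design)
  grid <- expand.grid(config = names(cfg), true_rho = true_rho_grid,
                      stringsAsFactors = FALSE)
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    cf <- cfg[[grid$config[i]]]
    oc <- oc_single(design, cf$theta_E, cf$theta_S, boundaries,
                    reps = reps, seed = seeds[i],
                    true_rho = grid$true_rho[i])
    data.frame(config = grid$config[i], true_rho = grid$true_rho[i],
               fwer = oc[["fwer"]], se = binom_se(oc[["fwer"]], reps),
               reps = reps, seed = seeds[i])
  })
  do.call(rbind, rows)
}

#' Power against safety effect and number of effective arms
#'
#' Empirical disjunctive power when `j_eff` arms carry the desirable
#' efficacy effect `delta`, the rest the minimum clinically important effect
#' `delta0`, and all arms share the safety effect `gamma_S`. Power rises
#' with the safety effect (the gate and safety margin bind less) and with
#' the number of effective arms.
#'
#' @inheritParams fwer_power_grid
#' @param gamma_S_grid Common safety effects.
#' @param j_eff_grid Numbers of arms at `delta` (subset of `1:K`).
#' @return Long data frame: one row per (`gamma_S`, `j_eff`).
#' @export
power_vs_safety <- function(design, boundaries,
                            gamma_S_grid = c(0, 0.25, 0.5, 1),
                            j_eff_grid = seq_len(design$K),
                            reps = 1e4, seed = 1) {
  grid <- expand.grid(gamma_S = gamma_S_grid, j_eff = j_eff_grid)
  seeds <- derive_seeds(seed, nrow(grid))
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    j <- grid$j_eff[i]
    theta_E <- c(rep(design$delta, j), rep(design$delta0, design$K - j))
    oc <- oc_single(design, theta_E, rep(grid$gamma_S[i], design$K),
                    boundaries, reps = reps, seed = seeds[i])
    data.frame(gamma_S = grid$gamma_S[i], j_eff = j,
               power = oc[["p_reject"]],
               se = binom_se(oc[["p_reject"]], reps),
               reps = reps, seed = seeds[i])
  })
  do.call(rbind, rows)
}
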