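# Limiting post-selection distributions.
#
# Calibration works in the two least-favourable limits of the null space:
#   (E-limit) theta_E = 0, gamma_S -> Inf : every arm is eligible almost
#     surely and rejection reduces to the efficacy margin of the selected arm;
#   (S-limit) theta_S = 0, gamma_E -> Inf : rejection reduces to the safety
#     margin of the selected arm, conditioned on at least one eligible arm.
#
# Writing standardised statistics as X_Tk = (A_k - A_0)/sqrt(2) + drift with
# (A_k, B_k) iid bivariate standard normal (corr rho) per arm, the selection
# objective ranks arms by C_k + d_k where C_k = w_E A_k + w_S B_k and
# d_k = sqrt(2) w_E sqrt(I_E) theta_Ek (common shifts cancel). Conditioning
# on the selected arm's C and the shared control variable collapses each
# limiting probability to a low-dimensional Gauss-Legendre quadrature; the
# same conditioning differentiated in the threshold yields the stage-1
# post-selection densities used by the multi-stage recursion.

# --- E-limit: tail and density of the selected arm's efficacy statistic ----

# Per-arm decomposition of P(Z_{E,i*} >= u, i* = k) in the E-limit, at
# efficacy drifts theta_E (length K). Returns the K-vector of joint
# probabilities; their sum is the limiting rejection probability / power.
eff_tail_by_arm <- function(u, design, info_E, theta_E, ngl = .NGL) {
  K <- design$K
  p <- sel_params(design)
  a <- u / sqrt(info_E)
  d <- sqrt(2) * design$w_E * sqrt(info_E) * theta_E
  mAfac <- p$covAC / p$s2
  vA <- 1 - p$covAC^2 / p$s2
  g <- gl_rule(ngl, -8 * p$s, 8 * p$s)
  wc <- g$w * stats::dnorm(g$x, 0, p$s)
  out <- numeric(K)
  for (k in seq_len(K)) {
    selk <- rep(1, ngl)
    for (j in seq_len(K)[-k])
      selk <- selk * stats::pnorm((g$x + d[k] - d[j]) / p$s)
    # A_k - A_0 >= sqrt(2) (a - sqrt(I_E) theta_Ek), A_k | C_k ~ N(mA, vA)
    t_k <- sqrt(2) * (a - sqrt(info_E) * theta_E[k])
    out[k] <- sum(wc * selk *
                    stats::pnorm((mAfac * g$x - t_k) / sqrt(1 + vA)))
  }
  out
}

# Density (standardised scale) of X_{E,i*} jointly with {i* = k}; vectorised
# over x. Obtained by differentiating the tail above in the threshold.
eff_density_by_arm <- function(x, design, info_E, theta_E, ngl = .NGL) {
  K <- design$K
  p <- sel_params(design)
  d <- sqrt(2) * design$w_E * sqrt(info_E) * theta_E
  mAfac <- p$covAC / p$s2
  vA <- 1 - p$covAC^2 / p$s2
  sd1 <- sqrt(1 + vA)
  g <- gl_rule(ngl, -8 * p$s, 8 * p$s)
  wc <- g$w * stats::dnorm(g$x, 0, p$s)
  dens <- matrix(0, length(x), K)
  for (k in seq_len(K)) {
    selk <- rep(1, ngl)
    for (j in seq_len(K)[-k])
      selk <- selk * stats::pnorm((g$x + d[k] - d[j]) / p$s)
    t_k <- sqrt(2) * (x - sqrt(info_E) * theta_E[k])   # length(x)
    arg <- (outer(t_k, mAfac * g$x, function(t, m) m - t)) / sd1
    dens[, k] <- (sqrt(2) / sd1) * as.vector(stats::dnorm(arg) %*% (wc * selk))
  }
  dens
}

# --- S-limit: joint tail/density of selected safety statistic and N_S >= 1 --

# Shared geometry of the S-limit quadrature. The competing-arm factor
# q(c1, b0) = 1 - P(C_j > c1, B_j > b0 + sqrt(2) ctil) does not depend on
# the threshold u, so it is precomputed once and reused across the many
# evaluations a root search makes.
safety_quad_setup <- function(design, info_S, ngl = .NGL) {
  p <- sel_params(design)
  ctil <- design$c / sqrt(info_S)
  mBfac <- p$covBC / p$s2
  vB <- 1 - p$covBC^2 / p$s2
  rBC <- p$covBC / p$s
  g0 <- gl_rule(ngl, -8, 8)               # shared control variable B_0
  gc <- gl_rule(ngl, -8 * p$s, 8 * p$s)   # selected arm's C
  t0 <- g0$x + sqrt(2) * ctil
  # base[i, ] = outer weight x control weight x q^(K-1) for c1 = gc$x[i]
  base <- matrix(0, ngl, ngl)
  for (i in seq_len(ngl)) {
    q <- 1 - pbvnorm_upper(t0, gc$x[i] / p$s, rBC)
    base[i, ] <- gc$w[i] * stats::dnorm(gc$x[i], 0, p$s) *
      g0$w * stats::dnorm(g0$x) * q^(design$K - 1)
  }
  list(K = design$K, ctil = ctil, mBfac = mBfac, vB = vB,
       b0 = g0$x, c1 = gc$x, base = base, ngl = ngl)
}

# P(Z_{S,i*} >= u, N_S >= 1) in the S-limit (theta_S = 0, gamma_E -> Inf).
safety_joint_tail <- function(u, design, info_S, setup = NULL) {
  if (is.null(setup)) setup <- safety_quad_setup(design, info_S)
  M <- max(setup$ctil, u / sqrt(info_S))
  # inner[i, j] = P(B_1 >= b0_j + sqrt(2) M | C_1 = c1_i)
  arg <- outer(-setup$mBfac * setup$c1, setup$b0 + sqrt(2) * M, "+")
  inner <- stats::pnorm(arg / sqrt(setup$vB), lower.tail = FALSE)
  setup$K * sum(setup$base * inner)
}

# Density (standardised scale) of X_{S,i*} jointly with {N_S >= 1} in the
# S-limit; zero below the standardised gate. Vectorised over x.
safety_joint_density <- function(x, design, info_S, setup = NULL) {
  if (is.null(setup)) setup <- safety_quad_setup(design, info_S)
  dens <- numeric(length(x))
  live <- x > setup$ctil
  if (!any(live)) return(dens)
  shift <- outer(-setup$mBfac * setup$c1, setup$b0, "+")  # ngl x ngl
  for (ix in which(live)) {
    phi <- stats::dnorm((sqrt(2) * x[ix] + shift) / sqrt(setup$vB))
    dens[ix] <- setup$K * sqrt(2) / sqrt(setup$vB) * sum(setup$base * phi)
  }
  dens
}

#' Probability that at least one arm clears the safety gate
#'
#' `P(N_S >= 1; theta_S = 0)`, the probability under null safety effects that
#' at least one arm's safety score statistic exceeds the gate `c`. The safety
#' statistics share the control arm and are therefore equicorrelated with
#' correlation 1/2; the probability is computed by integrating over the
#' control effect, never by assuming independence. With `c = 0` the arms and
#' control are exchangeable and the value is exactly `K / (K + 1)`.
#'
#' @param design An [rb_design()].
#' @param info_S Safety information per comparison at the analysis where the
#'   gate is applied. Irrelevant when `c = 0` or `c = -Inf`.
#' @return A probability.
#' @examples
#' prob_any_safe(rb_design(K = 4), info_S = 50)  # 4/5
#' @export
prob_any_safe <- function(design, info_S = 1) {
  stopifnot(inherits(design, "rb_design"))
  if (design$c == -Inf) return(1)
  ctil <- design$c / sqrt(info_S)
  g <- gl_rule(.NGL, -8, 8)
  # all ineligible: every B_k <= B_0 + sqrt(2) ctil
  1 - sum(g$w * stats::dnorm(g$x) *
            stats::pnorm(g$x + sqrt(2) * ctil)^design$K)
}

# --- Monte-Carlo oracle on standardised selection variables ----------------

# Draw the standardised per-arm variables (A, B) once; reused across
# candidate boundaries (common random numbers makes MC tails monotone in u).
draw_std_arms <- function(K, rho, reps, seed) {
  if (!is.null(seed)) set.seed(seed)
  A <- matrix(stats::rnorm(reps * (K + 1)), reps, K + 1)
  B <- rho * A + sqrt(1 - rho^2) * matrix(stats::rnorm(reps * (K + 1)),
                                          reps, K + 1)
  list(A = A, B = B)
}

# E-limit MC tail: P(X_{E,i*} >= u/sqrt(I_E)) with efficacy drifts theta_E.
mc_eff_tail <- function(u, design, info_E, theta_E, std) {
  K <- design$K
  a <- u / sqrt(info_E)
  d <- sqrt(2) * design$w_E * sqrt(info_E) * theta_E
  D <- design$w_E * std$A[, -1, drop = FALSE] +
    design$w_S * std$B[, -1, drop = FALSE]
  D <- sweep(D, 2, d, "+")
  istar <- max.col(D, ties.method = "first")
  XE <- (std$A[cbind(seq_len(nrow(D)), istar + 1)] - std$A[, 1]) / sqrt(2) +
    sqrt(info_E) * theta_E[istar]
  mean(XE >= a)
}

# S-limit MC joint tail: c(P(X_{S,i*} >= u/sqrt(I_S), N_S >= 1), P(N_S >= 1)).
mc_safety_tail <- function(u, design, info_S, std) {
  K <- design$K
  ctil <- design$c / sqrt(info_S)
  b <- u / sqrt(info_S)
  XS <- (std$B[, -1, drop = FALSE] - std$B[, 1]) / sqrt(2)
  C <- design$w_E * std$A[, -1, drop = FALSE] +
    design$w_S * std$B[, -1, drop = FALSE]
  elig <- XS > ctil
  C[!elig] <- -Inf
  any_elig <- rowSums(elig) > 0
  istar <- max.col(C, ties.method = "first")
  XSsel <- XS[cbind(seq_len(nrow(XS)), istar)]
  c(joint = mean(any_elig & XSsel >= b), p_ns = mean(any_elig))
}
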