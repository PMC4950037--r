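# Multi-stage extension: alpha-spending boundary schedules for the selected
# arm's efficacy and safety statistics, the maximum-information search, and
# the multi-stage trial executor.
#
# Selection happens at analysis 1 only. Thereafter the selected arm's score
# statistics have independent Gaussian increments distributed exactly as in
# a univariate group-sequential test, so stage-1 exit probabilities use the
# limiting post-selection distributions and later stages use the standard
# recursion over a sub-density grid.

# number of grid nodes carried between stages of the recursion
.GST_GRID <- 241L

# Solve one endpoint's (l_j, u_j) schedule under its limiting configuration.
#   info_seq   increasing information levels for the monitored endpoint
#   t_frac     information fractions used by the spending functions
#   level      total one-sided error to spend (alpha, or alpha / P(N_S >= 1))
#   tail1      function(u) -> P(Z_1 >= u) at stage 1 (selection included)
#   dens1      function(z) -> stage-1 density of Z_1
#   support_lo hard lower support bound of Z_1 (the safety gate), or -Inf
gst_solve_schedule <- function(design, info_seq, t_frac, level,
                               tail1, dens1, support_lo = -Inf) {
  J <- length(info_seq)
  stopifnot(length(t_frac) == J, all(diff(info_seq) > 0) || J == 1,
            t_frac[J] == 1)
  fU <- spending_function(design$spend_upper)
  fL <- spending_function(design$spend_lower)
  cumU <- fU$spend(t_frac, level)
  cumL <- fL$spend(t_frac, 1 - level)
  piU <- diff(c(0, cumU))
  piL <- diff(c(0, cumL))
  if (any(piU < -1e-12) || any(piL < -1e-12))
    stop("spending function produced a negative stagewise spend", call. = FALSE)
  l <- u <- numeric(J)
  sd1 <- sqrt(info_seq[1])
  hi_cap <- 1e3 * sqrt(info_seq[J])

  # stage 1 boundaries from the exact post-selection tail
  u[1] <- root_expand(function(x) tail1(x) - piU[1],
                      lo = max(support_lo, -6 * sd1), hi = 6 * sd1,
                      max_hi = hi_cap)
  if (J == 1) {
    l[1] <- u[1]
  } else {
    # P(Z_1 <= x) = 1 - tail1(x); written as a decreasing objective in x
    l[1] <- root_expand(function(x) tail1(x) - (1 - piL[1]),
                        lo = max(support_lo, -6 * sd1), hi = 6 * sd1,
                        max_hi = hi_cap)
    if (l[1] >= u[1])
      stop("stage-1 spends leave no continuation region", call. = FALSE)
    # interior sub-density between the stage-1 boundaries
    g <- gl_rule(.GST_GRID, max(l[1], support_lo), u[1])
    mass_w <- g$w * dens1(g$x)
    z <- g$x
    for (j in 2:J) {
      v <- info_seq[j] - info_seq[j - 1]
      upc <- function(x) sum(mass_w * stats::pnorm((x - z) / sqrt(v),
                                                   lower.tail = FALSE))
      loc <- function(x) sum(mass_w * stats::pnorm((x - z) / sqrt(v)))
      u[j] <- root_expand(function(x) upc(x) - piU[j],
                          lo = min(z) - 6 * sqrt(v), hi = max(z) + 6 * sqrt(v),
                          max_hi = hi_cap)
      if (j < J) {
        l[j] <- root_expand(function(x) piL[j] - loc(x),
                            lo = min(z) - 6 * sqrt(v), hi = max(z) + 6 * sqrt(v),
                            max_hi = hi_cap)
        if (l[j] >= u[j])
          stop("spends leave no continuation region at stage ", j,
               call. = FALSE)
        gn <- gl_rule(.GST_GRID, l[j], u[j])
        dens_new <- vapply(gn$x, function(y)
          sum(mass_w * stats::dnorm(y, z, sqrt(v))), numeric(1))
        z <- gn$x
        mass_w <- gn$w * dens_new
      } else {
        # proper termination: remaining mass splits so l_J = u_J
        l[j] <- u[j]
      }
    }
  }
  data.frame(stage = seq_len(J), t = t_frac, info = info_seq,
             lower = l, upper = u, spend_upper = piU, spend_lower = piL)
}

# root_expand assumes f decreasing; for the lower boundary searches above the
# objectives are arranged to be decreasing in x as well.

# Efficacy schedule at information sequence info_E_seq (score scale), under
# the E-limit with efficacy effects theta_E = 0.
solve_eff_schedule <- function(design, info_E_seq, t_frac) {
  theta0 <- rep(0, design$K)
  tail1 <- function(u) sum(eff_tail_by_arm(u, design, info_E_seq[1], theta0))
  dens1 <- function(z) rowSums(eff_density_by_arm(z / sqrt(info_E_seq[1]),
                                                  design, info_E_seq[1],
                                                  theta0)) / sqrt(info_E_seq[1])
  gst_solve_schedule(design, info_E_seq, t_frac, design$alpha, tail1, dens1)
}

# Safety schedule: spends level alpha / P(N_S >= 1) as a function of the
# efficacy information fractions; statistics live on the safety information
# scale with hard support above the gate c.
solve_safety_schedule <- function(design, info_S_seq, t_frac) {
  p_ns <- prob_any_safe(design, info_S_seq[1])
  level <- design$alpha / p_ns
  setup <- safety_quad_setup(design, info_S_seq[1])
  tail1 <- function(u) safety_joint_tail(u, design, info_S_seq[1], setup) / p_ns
  dens1 <- function(z) safety_joint_density(z / sqrt(info_S_seq[1]), design,
                                            info_S_seq[1], setup) /
    (p_ns * sqrt(info_S_seq[1]))
  gst_solve_schedule(design, info_S_seq, t_frac, level, tail1, dens1,
                     support_lo = design$c)
}

#' Solve one endpoint's stagewise stopping boundaries
#'
#' Alpha-spending boundary schedule for monitoring the selected arm's score
#' statistic over `J` analyses, computed under the endpoint's limiting
#' configuration: the efficacy schedule spends a total of `alpha` (given at
#' least one eligible arm, all safety effects arbitrarily large), the safety
#' schedule spends `alpha / P(N_S >= 1; theta_S = 0)` conditionally on
#' eligibility. Stage-1 exit probabilities use the exact post-selection
#' distribution; increments at later stages are independent Gaussians, as in
#' a univariate group-sequential test. Futility is binding; the construction
#' makes the final upper and lower bounds coincide so the test terminates
#' properly at analysis `J`.
#'
#' @param design An [rb_design()].
#' @param info_seq Increasing information levels for the monitored endpoint
#'   at analyses `1..J`.
#' @param endpoint `"efficacy"` or `"safety"`.
#' @param t_frac Information fractions driving the spending functions;
#'   defaults to `info_seq / max(info_seq)` for efficacy, and should be the
#'   *efficacy* fractions for the safety schedule (the default does this
#'   automatically since the two information scales are proportional).
#' @return A data frame with one row per stage: `stage`, `t`, `info`,
#'   `lower`, `upper`, and the stagewise spends.
#' @export
solve_stagewise_boundaries <- function(design, info_seq,
                                       endpoint = c("efficacy", "safety"),
                                       t_frac = info_seq / max(info_seq)) {
  stopifnot(inherits(design, "rb_design"))
  endpoint <- match.arg(endpoint)
  if (endpoint == "efficacy")
    solve_eff_schedule(design, info_seq, t_frac)
  else
    solve_safety_schedule(design, info_seq, t_frac)
}

# Limiting disjunctive power of a multi-stage design: probability of
# stopping with rejection at some analysis under efficacy effects theta_E in
# the E-limit (safety bounds cleared almost surely). Mixture over the
# selected arm, each component propagated with its own drift.
multistage_limiting_power <- function(design, eff_schedule, theta_E) {
  J <- nrow(eff_schedule)
  I <- eff_schedule$info
  l <- eff_schedule$lower; u <- eff_schedule$upper
  total <- 0
  for (k in seq_len(design$K)) {
    # stage 1: P(select k, Z_1 >= u_1)
    tail_k <- function(x) eff_tail_by_arm(x, design, I[1], theta_E)[k]
    total <- total + tail_k(u[1])
    if (J > 1) {
      g <- gl_rule(.GST_GRID, l[1], u[1])
      dens_k <- eff_density_by_arm(g$x / sqrt(I[1]), design, I[1],
                                   theta_E)[, k] / sqrt(I[1])
      z <- g$x
      mass_w <- g$w * dens_k
      for (j in 2:J) {
        v <- I[j] - I[j - 1]
        mu <- v * theta_E[k]
        total <- total + sum(mass_w * stats::pnorm((u[j] - z - mu) / sqrt(v),
                                                   lower.tail = FALSE))
        if (j < J) {
          gn <- gl_rule(.GST_GRID, l[j], u[j])
          dens_new <- vapply(gn$x, function(y)
            sum(mass_w * stats::dnorm(y, z + mu, sqrt(v))), numeric(1))
          z <- gn$x
          mass_w <- gn$w * dens_new
        }
      }
    }
  }
  total
}

#' Solve a multi-stage design: maximum information and boundary schedules
#'
#' Searches for the maximum efficacy information level `I_EJ` at which the
#' multi-stage test attains the target disjunctive power under the sizing
#' configuration `theta_E = (delta0, ..., delta0, delta)` with all arms
#' arbitrarily safe, re-solving both endpoints' spending schedules at every
#' candidate. Safety information runs at `I_Sj = sigma_E^2 I_Ej / sigma_S^2`,
#' so both statistics are driven by the same patients. The per-arm
#' recruitment ceiling is `n* = ceiling(2 sigma_E^2 I_EJ)`.
#'
#' @param design An [rb_design()] with `J >= 1`.
#' @param fractions Anticipated information fractions `t_1 < ... < t_J = 1`;
#'   defaults to equal spacing `(1:J)/J`.
#' @param theta_E Sizing configuration; defaults as in [solve_information()].
#' @param power_tol Tolerance of the information search on the power scale.
#' @return An `"rb_schedule"`: data frame `stages` (per-stage `t`, `info_E`,
#'   `info_S`, `l_E`, `u_E`, `l_S`, `u_S`), plus `I_EJ`, `n_star`,
#'   `attained_power`, and the `design`.
#' @examples
#' \donttest{
#' solve_max_information(rb_design(J = 2))
#' }
#' @export
solve_max_information <- function(design, fractions = seq_len(design$J) / design$J,
                                  theta_E = c(rep(design$delta0, design$K - 1),
                                              design$delta),
                                  power_tol = 1e-5) {
  stopifnot(inherits(design, "rb_design"), length(fractions) == design$J,
            all(diff(c(0, fractions)) > 0), fractions[design$J] == 1)
  target <- 1 - design$beta
  ratio <- design$sigma_E^2 / design$sigma_S^2
  pw <- function(I_EJ) {
    sch <- solve_eff_schedule(design, I_EJ * fractions, fractions)
    multistage_limiting_power(design, sch, theta_E) - target
  }
  I0 <- ((stats::qnorm(1 - design$alpha) + stats::qnorm(target)) /
           max(design$delta, 1e-8))^2
  lo <- I0 / 2; hi <- 4 * I0
  while (pw(hi) < 0 && hi < 1e4 * I0) hi <- hi * 2
  while (pw(lo) > 0 && lo > 1e-4 * I0) lo <- lo / 2
  I_EJ <- stats::uniroot(pw, c(lo, hi), tol = power_tol)$root
  info_E <- I_EJ * fractions
  info_S <- ratio * info_E
  eff <- solve_eff_schedule(design, info_E, fractions)
  saf <- solve_safety_schedule(design, info_S, fractions)
  stages <- data.frame(stage = seq_len(design$J), t = fractions,
                       info_E = info_E, info_S = info_S,
                       l_E = eff$lower, u_E = eff$upper,
                       l_S = saf$lower, u_S = saf$upper)
  structure(list(stages = stages, I_EJ = I_EJ,
                 n_star = ceiling(2 * design$sigma_E^2 * I_EJ),
                 attained_power = multistage_limiting_power(design, eff,
                                                            theta_E) ,
                 design = design),
            class = "rb_schedule")
}

#' @export
print.rb_schedule <- function(x, ...) {
  cat(sprintf("Multi-stage risk-benefit MAMS design (J = %d)\n",
              nrow(x$stages)))
  cat(sprintf("  maximum information I_EJ = %.4f, recruitment ceiling n* = %d per arm\n",
              x$I_EJ, x$n_star))
  cat(sprintf("  attained limiting power %.4f\n", x$attained_power))
  print(x$stages, digits = 5)
  invisible(x)
}

#' Run one multi-stage trial
#'
#' Executes the multi-stage decision rule on simulated patient-level data:
#' selection at analysis 1 (stop for futility if no arm clears the gate),
#' then the selected arm is monitored against the schedule — stop and reject
#' when both statistics clear their upper bounds at the same analysis, stop
#' and accept as soon as either crosses its lower bound (binding futility),
#' continue otherwise; the final bounds coincide so a decision is guaranteed.
#'
#' Cumulative per-arm sample sizes are `n_j = ceiling(2 sigma_E^2 I_Ej)` and
#' score statistics are computed at the information actually attained.
#'
#' @param design An [rb_design()].
#' @param theta_E,theta_S True effect vectors.
#' @param schedule An `rb_schedule` from [solve_max_information()].
#' @param seed Integer seed.
#' @return An `"rb_decision"` with the stage at which the trial stopped.
#' @export
run_multistage_trial <- function(design, theta_E, theta_S, schedule, seed = NULL) {
  stopifnot(inherits(schedule, "rb_schedule"))
  if (!is.null(seed)) set.seed(seed)
  st <- schedule$stages
  J <- nrow(st)
  n_cum <- ceiling(2 * design$sigma_E^2 * st$info_E)
  resp <- simulate_responses(design, theta_E, theta_S, n_cum[1])
  sc <- score_statistics(resp, design)
  sel <- select_treatment(sc, design)
  if (is.na(sel$selected))
    return(structure(list(outcome = "accept_H0_futility", selected = NA_integer_,
                          stage_stopped = 1L, scores = sc, selection = sel),
                     class = "rb_decision"))
  k <- sel$selected
  for (j in seq_len(J)) {
    if (j > 1) {
      add <- simulate_responses(design, theta_E, theta_S,
                                n_cum[j] - n_cum[j - 1])
      resp$efficacy <- rbind(resp$efficacy, add$efficacy)
      resp$safety <- rbind(resp$safety, add$safety)
      sc <- score_statistics(resp, design)
    }
    if (sc$Z_E[k] >= st$u_E[j] && sc$Z_S[k] >= st$u_S[j])
      return(structure(list(outcome = "reject_H0", selected = k,
                            stage_stopped = j, scores = sc, selection = sel),
                       class = "rb_decision"))
    if (sc$Z_E[k] <= st$l_E[j] || sc$Z_S[k] <= st$l_S[j])
      return(structure(list(outcome = "accept_H0_final", selected = k,
                            stage_stopped = j, scores = sc, selection = sel),
                       class = "rb_decision"))
  }
  # unreachable when u_J = l_J; guard against numerical slack
  structure(list(outcome = "accept_H0_final", selected = k,
                 stage_stopped = J, scores = sc, selection = sel),
            class = "rb_decision")
}

# Vectorised multi-stage simulator on the score scale. Returns empirical
# rates (p_reject, fwer, p_none, expected information for the efficacy
# endpoint, stagewise stopping distribution).
oc_multistage <- function(design, theta_E, theta_S, schedule,
                          reps = 1e4, seed = NULL, true_rho = design$rho) {
  st <- schedule$stages
  J <- nrow(st)
  K <- design$K
  if (!is.null(seed)) set.seed(seed)
  # stage 1: full selection machinery
  std <- draw_std_arms(K, true_rho, reps, NULL)
  I_E1 <- st$info_E[1]; I_S1 <- st$info_S[1]
  ZE <- sqrt(I_E1) * sweep((std$A[, -1, drop = FALSE] - std$A[, 1]) / sqrt(2),
                           2, sqrt(I_E1) * theta_E, "+")
  ZS <- sqrt(I_S1) * sweep((std$B[, -1, drop = FALSE] - std$B[, 1]) / sqrt(2),
                           2, sqrt(I_S1) * theta_S, "+")
  O <- ZE / sqrt(I_E1) * design$w_E + ZS / sqrt(I_S1) * design$w_S
  elig <- ZS > design$c
  O[!elig] <- -Inf
  any_elig <- rowSums(elig) > 0
  istar <- max.col(O, ties.method = "first")
  idx <- cbind(seq_len(reps), istar)
  zE <- ZE[idx]; zS <- ZS[idx]
  thE <- theta_E[istar]; thS <- theta_S[istar]
  alive <- any_elig
  reject <- rep(FALSE, reps)
  stop_stage <- rep(1L, reps)
  info_used <- rep(st$info_E[1], reps)
  rej_by_stage <- acc_by_stage <- numeric(J)
  for (j in seq_len(J)) {
    if (j > 1) {
      vE <- st$info_E[j] - st$info_E[j - 1]
      vS <- st$info_S[j] - st$info_S[j - 1]
      n_alive <- sum(alive)
      if (n_alive == 0) break
      # increments share the within-subject correlation through common draws
      zA <- stats::rnorm(n_alive); zB <- stats::rnorm(n_alive)
      zb <- true_rho * zA + sqrt(1 - true_rho^2) * zB
      zE[alive] <- zE[alive] + vE * thE[alive] + sqrt(vE) * zA
      zS[alive] <- zS[alive] + vS * thS[alive] + sqrt(vS) * zb
      info_used[alive] <- st$info_E[j]
      stop_stage[alive] <- j
    }
    rej_j <- alive & zE >= st$u_E[j] & zS >= st$u_S[j]
    acc_j <- alive & !rej_j & (zE <= st$l_E[j] | zS <= st$l_S[j])
    if (j == J) acc_j <- alive & !rej_j   # forced decision at the last look
    rej_by_stage[j] <- mean(rej_j)
    acc_by_stage[j] <- mean(acc_j)
    reject <- reject | rej_j
    alive <- alive & !(rej_j | acc_j)
  }
  null_arm <- theta_E <= 0 | theta_S <= 0
  fw_error <- reject & null_arm[istar]
  stage_tab <- tabulate(stop_stage, nbins = J) / reps
  names(stage_tab) <- paste0("stop_stage_", seq_len(J))
  names(rej_by_stage) <- paste0("reject_stage_", seq_len(J))
  names(acc_by_stage) <- paste0("accept_stage_", seq_len(J))
  c(p_reject = mean(reject), fwer = mean(fw_error), p_none = mean(!any_elig),
    expected_info_E = mean(info_used), stage_tab, rej_by_stage, acc_by_stage)
}
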