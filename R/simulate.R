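# Trial simulator: response generation, score statistics, selection, and the
# vectorised score-scale Monte-Carlo engine behind the operating
# characteristics and oracle checks.

#' Simulate patient-level bivariate responses
#'
#' Draws `n_per_arm` bivariate normal (efficacy, safety) responses for the
#' control arm (arm 0, means fixed at zero) and each of the `K` experimental
#' arms with mean advantages `theta_E`, `theta_S` over control, common known
#' covariance `matrix(c(sigma_E^2, rho sigma_E sigma_S, ., sigma_S^2), 2)`.
#'
#' @param design An [rb_design()].
#' @param theta_E,theta_S Length-`K` effect vectors (differences vs control).
#'   Infinite values are not allowed; use `design$gamma_surrogate`.
#' @param n_per_arm Responses per arm (>= 1).
#' @param seed Integer seed.
#' @return An `"rb_responses"` list with matrices `efficacy` and `safety`
#'   (`n_per_arm` rows, `K + 1` columns; column 1 is control) and the `design`.
#' @export
simulate_responses <- function(design, theta_E, theta_S, n_per_arm, seed = NULL) {
  stopifnot(inherits(design, "rb_design"),
            length(theta_E) == design$K, length(theta_S) == design$K,
            all(is.finite(theta_E)), all(is.finite(theta_S)),
            n_per_arm >= 1)
  if (!is.null(seed)) set.seed(seed)
  K <- design$K
  ne <- n_per_arm * (K + 1)
  zE <- matrix(stats::rnorm(ne), n_per_arm, K + 1)
  zS <- design$rho * zE +
    sqrt(1 - design$rho^2) * matrix(stats::rnorm(ne), n_per_arm, K + 1)
  eff <- sweep(design$sigma_E * zE, 2, c(0, theta_E), "+")
  saf <- sweep(design$sigma_S * zS, 2, c(0, theta_S), "+")
  structure(list(efficacy = eff, safety = saf, design = design),
            class = "rb_responses")
}

#' Score statistics from accumulated responses
#'
#' For each experimental arm `k`, `Z_Tk = I_T (muhat_Tk - muhat_T0)` with
#' `I_T = n / (2 sigma_T^2)`; the covariance structure across arms (shared
#' control) and endpoints (within-subject correlation) arises from the data,
#' not from explicit computation.
#'
#' @param responses An `rb_responses` object, or a list with `efficacy` and
#'   `safety` matrices (`K + 1` columns, control first).
#' @param design Design; defaults to the one attached to `responses`.
#' @return An `"rb_scores"` list: vectors `Z_E`, `Z_S` (length `K`) and the
#'   information levels `info_E`, `info_S`.
#' @export
score_statistics <- function(responses, design = responses$design) {
  stopifnot(inherits(design, "rb_design"),
            is.matrix(responses$efficacy), is.matrix(responses$safety),
            ncol(responses$efficacy) == design$K + 1)
  n <- nrow(responses$efficacy)
  if (n < 1) stop("no responses on at least one arm", call. = FALSE)
  info_E <- info_from_n(n, design$sigma_E)
  info_S <- info_from_n(n, design$sigma_S)
  mE <- colMeans(responses$efficacy)
  mS <- colMeans(responses$safety)
  structure(list(Z_E = info_E * (mE[-1] - mE[1]),
                 Z_S = info_S * (mS[-1] - mS[1]),
                 info_E = info_E, info_S = info_S),
            class = "rb_scores")
}

#' Apply the risk-benefit selection rule
#'
#' Arms with `Z_Sk > c` form the eligible set; among them the arm maximising
#' the objective `O_k = w_E Z_Ek / sqrt(I_E) + w_S Z_Sk / sqrt(I_S)` is
#' selected. Ties (probability zero under the continuous model) are broken
#' towards the lowest arm index so runs are reproducible. An empty eligible
#' set is a valid outcome: the trial stops for futility.
#'
#' @param scores An `rb_scores` object.
#' @param design An [rb_design()].
#' @return An `"rb_selection"` list: `eligible` (integer indices),
#'   `n_eligible`, `objective` (length `K`; values for ineligible arms are
#'   reported but flagged by the `eligible` set), and `selected` (arm index,
#'   or `NA` meaning "none").
#' @export
select_treatment <- function(scores, design) {
  stopifnot(inherits(scores, "rb_scores"), inherits(design, "rb_design"),
            length(scores$Z_E) == design$K)
  O <- design$w_E * scores$Z_E / sqrt(scores$info_E) +
    design$w_S * scores$Z_S / sqrt(scores$info_S)
  eligible <- which(scores$Z_S > design$c)
  selected <- if (length(eligible) == 0) NA_integer_ else
    eligible[which.max(O[eligible])]
  structure(list(eligible = eligible, n_eligible = length(eligible),
                 objective = O, selected = selected),
            class = "rb_selection")
}

#' @export
print.rb_selection <- function(x, ...) {
  cat(sprintf("eligible arms: %s (N_S = %d); selected: %s\n",
              if (x$n_eligible) paste(x$eligible, collapse = ", ") else "none",
              x$n_eligible,
              if (is.na(x$selected)) "none" else x$selected))
  invisible(x)
}

#' Run one single-stage trial
#'
#' Generates responses, selects a treatment, and applies the single-stage
#' decision rule: stop for futility if no arm clears the safety gate;
#' otherwise reject the selected arm's null hypothesis if and only if
#' `Z_E,i* >= u_E` and `Z_S,i* >= u_S`.
#'
#' @param design An [rb_design()].
#' @param theta_E,theta_S True effect vectors.
#' @param boundaries An `rb_boundaries` (or list with `u_E`, `u_S`).
#' @param n_per_arm Responses per arm.
#' @param seed Integer seed.
#' @return An `"rb_decision"` list: `outcome` (one of `"reject_H0"`,
#'   `"accept_H0_futility"`, `"accept_H0_final"`), `selected` (arm index or
#'   `NA`), `stage_stopped`, and the `scores`.
#' @export
run_single_stage_trial <- function(design, theta_E, theta_S, boundaries,
                                   n_per_arm, seed = NULL) {
  resp <- simulate_responses(design, theta_E, theta_S, n_per_arm, seed)
  sc <- score_statistics(resp, design)
  sel <- select_treatment(sc, design)
  if (is.na(sel$selected)) {
    outcome <- "accept_H0_futility"
  } else if (sc$Z_E[sel$selected] >= boundaries$u_E &&
             sc$Z_S[sel$selected] >= boundaries$u_S) {
    outcome <- "reject_H0"
  } else {
    outcome <- "accept_H0_final"
  }
  structure(list(outcome = outcome, selected = sel$selected,
                 stage_stopped = 1L, scores = sc, selection = sel),
            class = "rb_decision")
}

#' @export
print.rb_decision <- function(x, ...) {
  cat(sprintf("trial decision: %s (selected arm: %s, stage %d)\n", x$outcome,
              if (is.na(x$selected)) "none" else x$selected, x$stage_stopped))
  invisible(x)
}

# ---- vectorised score-scale engine ----------------------------------------

# Simulate `reps` single-stage trials directly on the score-statistic scale
# (exact under the normal model). Returns named vector of empirical rates:
# p_reject (any rejection), fwer (rejection of a true null), p_none (futility
# gate), and per-arm selection frequencies sel_1..sel_K. `true_rho` lets the
# data-generating correlation differ from the design's.
oc_single <- function(design, theta_E, theta_S, boundaries,
                      reps = 1e4, seed = NULL, true_rho = design$rho) {
  stopifnot(length(theta_E) == design$K, length(theta_S) == design$K)
  K <- design$K
  info_E <- boundaries$info_E
  info_S <- boundaries$info_S
  gen <- design
  gen$rho <- true_rho
  std <- draw_std_arms(K, true_rho, reps, seed)
  XE <- sweep((std$A[, -1, drop = FALSE] - std$A[, 1]) / sqrt(2), 2,
              sqrt(info_E) * theta_E, "+")
  XS <- sweep((std$B[, -1, drop = FALSE] - std$B[, 1]) / sqrt(2), 2,
              sqrt(info_S) * theta_S, "+")
  O <- design$w_E * XE + design$w_S * XS     # objective on standardised scale
  elig <- sqrt(info_S) * XS > design$c
  O[!elig] <- -Inf
  any_elig <- rowSums(elig) > 0
  istar <- max.col(O, ties.method = "first")
  idx <- cbind(seq_len(reps), istar)
  reject <- any_elig &
    sqrt(info_E) * XE[idx] >= boundaries$u_E &
    sqrt(info_S) * XS[idx] >= boundaries$u_S
  null_arm <- theta_E <= 0 | theta_S <= 0    # arms whose H0 is true
  fw_error <- reject & null_arm[istar]
  sel <- tabulate(istar[any_elig], nbins = K) / reps
  names(sel) <- paste0("sel_", seq_len(K))
  c(p_reject = mean(reject), fwer = mean(fw_error),
    p_none = mean(!any_elig), sel)
}
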