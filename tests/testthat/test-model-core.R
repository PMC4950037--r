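test_that("response generator matches the bivariate normal model", {
  n <- 1e5
  # independence when rho = 0
  r0 <- simulate_responses(rb_design(K = 1, rho = 0), theta_E = 0, theta_S = 0,
                           n_per_arm = n, seed = 101)
  expect_lt(abs(cor(r0$efficacy[, 2], r0$safety[, 2])), 3 / sqrt(n))
  # null configuration: per-arm means near zero (3.5 sigma to allow for the
  # four simultaneous per-column checks)
  expect_true(all(abs(colMeans(cbind(r0$efficacy, r0$safety))) < 3.5 / sqrt(n)))
  # generating correlation recovered (large-sample check)
  r4 <- simulate_responses(rb_design(K = 1, rho = 0.4), theta_E = 0.3,
                           theta_S = -0.2, n_per_arm = n, seed = 102)
  expect_lt(abs(cor(r4$efficacy[, 2], r4$safety[, 2]) - 0.4),
            3 * (1 - 0.4^2) / sqrt(n))
  expect_equal(mean(r4$efficacy[, 2]), 0.3, tolerance = 4 / sqrt(n))
  # infinite effects must go through the surrogate, not Inf
  expect_error(simulate_responses(rb_design(K = 1), Inf, 0, 10))
})

test_that("score statistics: identity, hand computation, and errors", {
  des <- rb_design(K = 2, sigma_E = 1, sigma_S = 2)
  # equal sample means on every arm -> all score statistics zero
  resp <- simulate_responses(des, c(0, 0), c(0, 0), n_per_arm = 50, seed = 1)
  centred <- lapply(resp[c("efficacy", "safety")],
                    function(m) sweep(m, 2, colMeans(m)))
  sc0 <- score_statistics(c(centred, list(design = des)), des)
  expect_equal(unname(sc0$Z_E), c(0, 0))
  expect_equal(unname(sc0$Z_S), c(0, 0))
  # n = 50, sigma_E = 1: I_E = 25; a mean advantage of 0.5 gives Z = 12.5
  shifted <- centred
  shifted$efficacy[, 2] <- shifted$efficacy[, 2] + 0.5
  sc <- score_statistics(c(shifted, list(design = des)), des)
  expect_equal(unname(sc$Z_E[1]), 25 * 0.5)
  expect_equal(sc$info_E, 50 / 2)
  expect_equal(sc$info_S, 50 / (2 * 4))
  # no responses is an error
  empty <- list(efficacy = matrix(0, 0, 3), safety = matrix(0, 0, 3))
  expect_error(score_statistics(empty, des), "no responses")
})

test_that("score statistic moments match the model covariance", {
  des <- rb_design(K = 2, rho = 0.4)
  n <- 20; trials <- 2000
  I <- n / 2
  set.seed(103)
  ZE <- ZS <- matrix(0, trials, 2)
  for (t in seq_len(trials)) {
    sc <- score_statistics(simulate_responses(des, c(0.2, 0), c(0, 0.1), n),
                           des)
    ZE[t, ] <- sc$Z_E; ZS[t, ] <- sc$Z_S
  }
  se_mean <- sqrt(I / trials)
  se_var <- I * sqrt(2 / trials)
  expect_lt(max(abs(colMeans(ZE) - I * c(0.2, 0))), 3 * se_mean)
  expect_lt(max(abs(apply(ZE, 2, var) - I)), 3 * se_var)
  # shared control induces covariance I/2 across arms
  expect_lt(abs(cov(ZE[, 1], ZE[, 2]) - I / 2), 3 * se_var)
  # within-arm cross-endpoint covariance rho * sqrt(I_E I_S)
  expect_lt(abs(cov(ZE[, 1], ZS[, 1]) - 0.4 * I), 3 * se_var)
})

test_that("selection rule: gate, objective maximisation, tie-breaking", {
  des2 <- rb_design(K = 2, c = 0)
  # worked example: equal weights, I = 25
  sc <- mk_scores(Z_E = c(10, 2), Z_S = c(5, 12), info_E = 25)
  sel <- select_treatment(sc, des2)
  expect_equal(sel$eligible, c(1L, 2L))
  expect_equal(sel$objective, sqrt(0.5) * c(15, 14) / 5, tolerance = 1e-12)
  expect_identical(sel$selected, 1L)
  # futility gate: nothing eligible
  none <- select_treatment(mk_scores(c(10, 2), c(-1, 0), 25), des2)
  expect_identical(none$n_eligible, 0L)
  expect_identical(none$selected, NA_integer_)
  # exact tie -> lowest index
  tie <- select_treatment(mk_scores(c(5, 5), c(5, 5), 25), des2)
  expect_identical(tie$selected, 1L)
  # permutation equivariance
  des3 <- rb_design(K = 3)
  z_e <- c(3, 9, 6); z_s <- c(2, 1, 3.5)
  perm <- c(3L, 1L, 2L)
  s1 <- select_treatment(mk_scores(z_e, z_s, 25), des3)
  s2 <- select_treatment(mk_scores(z_e[perm], z_s[perm], 25), des3)
  expect_identical(perm[s2$selected], s1$selected)
  expect_equal(s2$objective, s1$objective[perm])
})

test_that("raising an eligible arm's efficacy never hands selection to a third arm", {
  des <- rb_design(K = 4)
  set.seed(104)
  for (i in 1:200) {
    z_e <- rnorm(4, sd = 3); z_s <- rnorm(4, sd = 3)
    sc <- mk_scores(z_e, z_s, 25)
    before <- select_treatment(sc, des)$selected
    k <- sample(4, 1)
    if (!(k %in% which(z_s > 0))) next
    z_e2 <- z_e; z_e2[k] <- z_e2[k] + rexp(1, 0.2)
    after <- select_treatment(mk_scores(z_e2, z_s, 25), des)$selected
    expect_true(after %in% c(before, k))
  }
})

test_that("endpoint swap leaves the selected objective unchanged under symmetry", {
  des <- rb_design(K = 3, c = -Inf, w_E = sqrt(0.5), sigma_E = 1, sigma_S = 1)
  set.seed(105)
  z_e <- rnorm(3, sd = 4); z_s <- rnorm(3, sd = 4)
  a <- select_treatment(mk_scores(z_e, z_s, 30), des)
  b <- select_treatment(mk_scores(z_s, z_e, 30), des)
  expect_equal(a$objective[a$selected], b$objective[b$selected])
})

test_that("selection is uniform under the exchangeable null", {
  des <- rb_design(K = 4, c = -Inf)
  oc <- oc1(des, theta_E = rep(0, 4), theta_S = rep(0, 4),
            boundaries = mk_bounds(Inf, Inf, 25), reps = 4e4, seed = 106)
  sel <- oc[paste0("sel_", 1:4)]
  expect_true(all(abs(sel - 0.25) < 3 * sqrt(0.25 * 0.75 / 4e4)))
  expect_equal(sum(sel), 1)  # an arm is always selected without the gate
})

test_that("single-stage decision rule honours degenerate boundaries", {
  des <- rb_design(K = 2, c = -Inf)
  always <- run_single_stage_trial(des, c(0, 0), c(0, 0),
                                   mk_bounds(-Inf, -Inf, 10), 20, seed = 107)
  expect_identical(always$outcome, "reject_H0")
  never <- run_single_stage_trial(des, c(0, 0), c(0, 0),
                                  mk_bounds(Inf, -Inf, 10), 20, seed = 107)
  expect_identical(never$outcome, "accept_H0_final")
  # gate everything out -> futility at stage 1
  gated <- run_single_stage_trial(rb_design(K = 2, c = 1e9), c(0, 0), c(0, 0),
                                  mk_bounds(-Inf, -Inf, 10), 20, seed = 107)
  expect_identical(gated$outcome, "accept_H0_futility")
  expect_identical(gated$selected, NA_integer_)
})

test_that("probability of any safe arm: exchangeable values and MC agreement", {
  expect_equal(prob_any_safe(rb_design(K = 4, c = 0)), 0.8, tolerance = 1e-8)
  expect_equal(prob_any_safe(rb_design(K = 1, c = 0)), 0.5, tolerance = 1e-8)
  expect_equal(prob_any_safe(rb_design(K = 3, c = -Inf)), 1)
  # non-zero gate against the simulation oracle
  des <- rb_design(K = 3, c = 2)
  p_int <- prob_any_safe(des, info_S = 16)
  std <- mamsrb:::draw_std_arms(3, des$rho, 1e5, seed = 108)
  p_mc <- mamsrb:::mc_safety_tail(-Inf, des, info_S = 16, std)[["p_ns"]]
  expect_lt(abs(p_int - p_mc), 3 * sqrt(p_mc * (1 - p_mc) / 1e5))
})
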