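test_that("a one-look schedule reduces to the single-stage design", {
  des <- tailor_design()
  sol <- solve_information(des)
  sch <- solve_max_information(rb_design(J = 1))
  expect_equal(sch$I_EJ, sol$I_star, tolerance = 1e-3)
  expect_equal(sch$stages$u_E, sol$boundaries_at_I_star$u_E, tolerance = 1e-3)
  expect_equal(sch$stages$u_S, sol$boundaries_at_I_star$u_S, tolerance = 1e-3)
  expect_equal(sch$stages$l_E, sch$stages$u_E)  # terminates at the only look
})

test_that("without selection the schedule matches a univariate group-sequential test", {
  # K = 1, no gate, two equally spaced looks, linear spending
  des <- rb_design(K = 1, c = -Inf, J = 2,
                   spend_upper = "pow:1", spend_lower = "pow:1")
  I <- c(25, 50)
  sch <- solve_stagewise_boundaries(des, I, endpoint = "efficacy")
  # stage 1 spends alpha/2 with no selection: u_1 = sqrt(I_1) z_{1 - alpha/2}
  expect_equal(sch$upper[1], sqrt(25) * qnorm(1 - 0.025), tolerance = 1e-4)
  # simulation oracle for the full schedule: stagewise crossing probabilities
  set.seed(118)
  reps <- 2e5
  z1 <- sqrt(I[1]) * rnorm(reps)
  z2 <- z1 + sqrt(I[2] - I[1]) * rnorm(reps)
  cross_u1 <- z1 >= sch$upper[1]
  cross_l1 <- z1 <= sch$lower[1]
  cont <- !cross_u1 & !cross_l1
  se3 <- function(p) 3 * sqrt(p * (1 - p) / reps)
  expect_lt(abs(mean(cross_u1) - 0.025), se3(0.025))
  expect_lt(abs(mean(cross_l1) - 0.475), se3(0.475))
  expect_lt(abs(mean(cont & z2 >= sch$upper[2]) - 0.025), se3(0.025))
  expect_lt(abs(mean(cont & z2 <= sch$lower[2]) - 0.475), se3(0.475))
})

test_that("stagewise error spend is conserved under the limiting configurations", {
  des <- rb_design(J = 3)
  sch <- solve_max_information(des)
  g <- des$gamma_surrogate
  fU <- spending_function(des$spend_upper)
  piU <- diff(c(0, fU$spend(sch$stages$t, des$alpha)))
  # efficacy limit: all arms safe, null efficacy
  oc_e <- ocJ(des, rep(0, 4), rep(g, 4), sch, reps = 1e5, seed = 119)
  rej <- oc_e[paste0("reject_stage_", 1:3)]
  for (j in 1:3)
    expect_lt(abs(rej[j] - piU[j]), 3 * sqrt(piU[j] * (1 - piU[j]) / 1e5))
  expect_lt(oc_e[["fwer"]], binom_bound(0.05, 1e5))
  # safety limit: huge efficacy, null safety; total rejection also alpha
  oc_s <- ocJ(des, rep(g, 4), rep(0, 4), sch, reps = 1e5, seed = 120)
  expect_lt(abs(oc_s[["p_reject"]] - 0.05), 3 * sqrt(0.05 * 0.95 / 1e5))
  expect_lt(oc_s[["fwer"]], binom_bound(0.05, 1e5))
})

test_that("interim looks with binding futility cost maximum information", {
  sol1 <- solve_information(tailor_design())
  sch2 <- solve_max_information(rb_design(J = 2))
  expect_gt(sch2$I_EJ, sol1$I_star)
  # ...but early stopping saves information in expectation under the null
  oc0 <- ocJ(rb_design(J = 2), rep(0, 4), rep(1e6, 4), sch2,
             reps = 2e4, seed = 121)
  expect_lt(oc0[["expected_info_E"]], sch2$I_EJ)
  # attained limiting power meets the target
  expect_equal(sch2$attained_power, 0.9, tolerance = 1e-3)
  oc_pow <- ocJ(rb_design(J = 2), c(0.178, 0.178, 0.178, 0.545), rep(1e6, 4),
                sch2, reps = 1e5, seed = 122)
  expect_lt(abs(oc_pow[["p_reject"]] - 0.9), 3 * sqrt(0.9 * 0.1 / 1e5))
})

test_that("increments of the selected arm's statistic are independent of its stage-1 value", {
  # patient-level check: select at n = 20 per arm, extend the same trial to
  # n = 40; the increment Z_2 - Z_1 must be uncorrelated with the
  # (selection-skewed) stage-1 value and carry variance I_2 - I_1
  des <- rb_design(K = 4, c = -Inf)
  trials <- 2000
  set.seed(123)
  z1 <- z2 <- numeric(trials)
  for (t in seq_len(trials)) {
    resp <- simulate_responses(des, rep(0, 4), rep(0, 4), 40)
    stage1 <- list(efficacy = resp$efficacy[1:20, ], safety = resp$safety[1:20, ])
    sc1 <- score_statistics(stage1, des)
    k <- select_treatment(sc1, des)$selected
    z1[t] <- sc1$Z_E[k]
    z2[t] <- score_statistics(resp, des)$Z_E[k]
  }
  I1 <- 10; I2 <- 20
  inc <- z2 - z1
  expect_gt(mean(z1), 0)  # selection skews stage 1 upwards
  expect_lt(abs(cov(z1, inc)), 3 * sqrt(I1 * (I2 - I1) / trials))
  expect_lt(abs(var(inc) - (I2 - I1)), 3 * (I2 - I1) * sqrt(2 / trials))
})

test_that("trials terminate properly and futility gates bind", {
  des <- rb_design(J = 3)
  sch <- solve_max_information(des)
  # final-look boundaries coincide for both endpoints
  expect_equal(sch$stages$l_E[3], sch$stages$u_E[3])
  expect_equal(sch$stages$l_S[3], sch$stages$u_S[3])
  # every simulated path reaches a decision
  oc <- ocJ(des, rep(0.3, 4), rep(0.2, 4), sch, reps = 2e4, seed = 124)
  expect_equal(sum(oc[paste0("stop_stage_", 1:3)]), 1)
  expect_equal(oc[["p_reject"]] + sum(oc[paste0("accept_stage_", 1:3)]) +
                 oc[["p_none"]], 1, tolerance = 1e-12)
  # grossly unsafe arms never pass the stage-1 gate
  oc_bad <- ocJ(des, rep(1, 4), rep(-des$gamma_surrogate, 4), sch,
                reps = 5e3, seed = 125)
  expect_equal(oc_bad[["p_none"]], 1)
  # the patient-level executor agrees with the rule and terminates in time
  for (s in 1:10) {
    dec <- run_multistage_trial(des, rep(0.2, 4), rep(0.3, 4), sch, seed = s)
    expect_true(dec$outcome %in% c("reject_H0", "accept_H0_final",
                                   "accept_H0_futility"))
    expect_lte(dec$stage_stopped, 3)
    if (dec$outcome == "reject_H0") expect_false(is.na(dec$selected))
  }
})

test_that("multi-stage worst-case FWER stays within the nominal level", {
  des <- rb_design(J = 3)
  sch <- solve_max_information(des)
  g <- des$gamma_surrogate
  bound <- binom_bound(0.05, 1e5)
  # mixed per-arm worst-case patterns (strong-control conjecture)
  oc_m1 <- ocJ(des, c(g, 0, 0, 0), c(0, g, g, g), sch, reps = 1e5, seed = 126)
  oc_m2 <- ocJ(des, c(g, g, 0, 0), c(0, 0, g, g), sch, reps = 1e5, seed = 127)
  expect_lt(oc_m1[["fwer"]], bound)
  expect_lt(oc_m2[["fwer"]], bound)
})
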