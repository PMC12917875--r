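params0 <- c(alpha1 = 0, alpha2 = 1, beta1 = 0, beta2 = 1, eta = 1)

test_that("joint toxicity probability follows the odds-multiplier model", {
  # psi_A = psi_B = 1/2, no-interaction p = 3/4, odds 3; multiplier
  # exp(log 2) = 2 gives odds 6, p = 6/7
  expect_equal(joint_tox_prob(params0, 0, 0), 6 / 7, tolerance = 1e-12)
  # eta = 0 factorises exactly
  set.seed(3)
  for (rep in 1:20) {
    pr <- c(alpha1 = rnorm(1), alpha2 = rexp(1), beta1 = rnorm(1),
            beta2 = rexp(1), eta = 0)
    da <- runif(1, 0, 1); db <- runif(1, 0, 1)
    psiA <- plogis(pr["alpha1"] + pr["alpha2"] * da)
    psiB <- plogis(pr["beta1"] + pr["beta2"] * db)
    expect_equal(unname(joint_tox_prob(pr, da, db)),
                 unname(1 - (1 - psiA) * (1 - psiB)), tolerance = 1e-10)
  }
  # vanishing single-agent toxicity drives the joint probability to zero
  pr0 <- c(alpha1 = -40, alpha2 = 1, beta1 = -40, beta2 = 1, eta = 0.5)
  expect_lt(joint_tox_prob(pr0, 0.4, 0.4), 1e-10)
})

test_that("joint toxicity is monotone in both standardized doses", {
  set.seed(8)
  for (rep in 1:20) {
    pr <- c(alpha1 = rnorm(1), alpha2 = rexp(1), beta1 = rnorm(1),
            beta2 = rexp(1), eta = rexp(1))
    d <- sort(runif(5, 0, 2))
    expect_true(all(diff(joint_tox_prob(pr, d, 0.3)) >= 0))
    expect_true(all(diff(joint_tox_prob(pr, 0.3, d)) >= 0))
  }
})

test_that("with eta = 0 and one agent negligible the model is single-agent logistic", {
  pr <- c(alpha1 = -1, alpha2 = 2, beta1 = -50, beta2 = 1, eta = 0)
  d <- seq(0.1, 0.9, by = 0.2)
  expect_equal(unname(joint_tox_prob(pr, d, 0.25)),
               unname(plogis(-1 + 2 * d)), tolerance = 1e-10)
})

test_that("the sampler recovers toxicity surfaces generated inside the model family", {
  truth_par <- c(alpha1 = -1, alpha2 = 1.2, beta1 = -1.2, beta2 = 1, eta = 0.5)
  pri <- blrm_priors()
  da <- matrix(pri$std_doses_a, 3, 3)
  db <- matrix(pri$std_doses_b, 3, 3, byrow = TRUE)
  truth <- joint_tox_prob(truth_par, da, db)
  set.seed(123)
  st <- list(n = matrix(480L, 3, 3),
             y = matrix(rbinom(9, 480L, truth), 3, 3))
  fit <- blrm_fit(st, pri, n_samples = 2000, burnin = 1000)
  expect_lt(max(abs(fit$pi_mean - truth)), 0.05)
  expect_lt(max(abs(fit$pi_plugin - truth)), 0.05)
})

test_that("prior-predictive centre of the no-data fit matches direct Monte Carlo", {
  pri <- blrm_priors()
  st <- list(n = matrix(0L, 3, 3), y = matrix(0L, 3, 3))
  set.seed(42)
  fit <- suppressWarnings(blrm_fit(st, pri, n_samples = 2000, burnin = 500))
  draws <- replicate(4000, {
    pr <- c(alpha1 = rnorm(1, -2, sqrt(10)), alpha2 = exp(rnorm(1, 0.5, 0.5)),
            beta1 = rnorm(1, -2, sqrt(10)), beta2 = exp(rnorm(1, 0.5, 0.5)),
            eta = rnorm(1, 0, 0.5))
    joint_tox_prob(pr, pri$std_doses_a[1], pri$std_doses_b[1])
  })
  expect_lt(abs(fit$pi_mean[1, 1] - mean(draws)), 0.1)
})

test_that("model misfit to a sharp toxicity cliff shows the known bias pattern", {
  # 0/12 at the lowest combination, 9/12 and 8/12 at its neighbours: the
  # rigid parametric surface overestimates the first and underestimates the
  # other two
  st <- list(n = matrix(c(12L, 12L, 0L, 12L, 0L, 0L, 0L, 0L, 0L), 3, 3, byrow = TRUE),
             y = matrix(c(0L, 9L, 0L, 8L, 0L, 0L, 0L, 0L, 0L), 3, 3, byrow = TRUE))
  set.seed(7)
  fit <- suppressWarnings(blrm_fit(st, blrm_priors()))
  expect_gt(fit$pi_plugin[1, 1], 0.10)      # far above the observed 0%
  expect_lt(fit$pi_plugin[1, 2], 9 / 12)    # below the observed 75%
  expect_lt(fit$pi_plugin[2, 1], 8 / 12)    # below the observed 67%
  # monotone surface despite non-monotone data
  expect_true(all(diff(fit$pi_plugin) >= -1e-9))
})

test_that("EWOC admissibility and escalation follow the patient-gain rule", {
  pri <- blrm_priors()
  post <- structure(list(
    pi_exceed = matrix(c(0.1, 0.40, 0.8, 0.40, 0.8, 0.9, 0.8, 0.9, 1), 3, 3,
                       byrow = TRUE),
    pi_plugin = matrix(c(0.10, 0.25, 0.45, 0.25, 0.45, 0.6, 0.45, 0.6, 0.7),
                       3, 3, byrow = TRUE),
    pi_mean = matrix(c(0.10, 0.25, 0.45, 0.25, 0.45, 0.6, 0.45, 0.6, 0.7),
                     3, 3, byrow = TRUE)), class = "blrm_posterior")
  adm <- ewoc_admissible(post, pri)
  expect_true(adm[1, 2])   # boundary: non-strict <=
  expect_false(adm[1, 3])
  st <- new_trial_state(c(3, 3))
  st$n[1, 1] <- 3L
  st$history <- data.frame(cohort = 1, pos_a = 1, pos_b = 1, n = 3, y = 0)
  cfg <- design_config()
  nxt <- blrm_next_dose(post, st, cfg, pri)
  # 0.25 is closest to 0.30 from below; the (2,1)/(1,2) tie breaks by
  # column-major index order, deterministically
  expect_equal(nxt, c(2, 1))
  # nothing admissible -> NULL (trial terminates)
  post$pi_exceed[] <- 1
  expect_null(blrm_next_dose(post, st, cfg, pri))
})

test_that("final BLRM selection requires six patients and prefers below-target means", {
  post <- structure(list(
    pi_plugin = matrix(c(0.24, 0.29, 0.5, 0.4, 0.5, 0.6, 0.5, 0.6, 0.7), 3, 3,
                       byrow = TRUE),
    pi_mean = matrix(0.5, 3, 3),
    pi_exceed = matrix(0, 3, 3)), class = "blrm_posterior")
  st <- new_trial_state(c(3, 3))
  cfg <- design_config()
  st$n[1, 1] <- 21L
  expect_equal(blrm_select_final(post, st, cfg), c(1, 1))
  st$n[1, 2] <- 6L
  expect_equal(blrm_select_final(post, st, cfg), c(1, 2))
  st$n[] <- 0L
  expect_null(blrm_select_final(post, st, cfg))
})
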