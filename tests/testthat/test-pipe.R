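test_that("neighbouring constraint tracks treated combinations and bars diagonal escalation", {
  st <- new_trial_state(c(3, 3))
  adm <- neighbor_admissible(st, "any-previous")
  expect_equal(which(adm), 1L)  # only d11 before any treatment
  st$n[1, 1] <- 3L
  st$history <- data.frame(cohort = 1, pos_a = 1, pos_b = 1, n = 3, y = 0)
  adm <- neighbor_admissible(st, "any-previous")
  expect_true(adm[1, 1] && adm[2, 1] && adm[1, 2])
  expect_false(adm[2, 2])  # diagonal escalation from (1,1)
  expect_false(adm[3, 1])
  st$n[2, 1] <- 3L
  adm <- neighbor_admissible(st, "any-previous")
  expect_true(adm[2, 2])   # sideways from (2,1) is allowed
  expect_true(adm[3, 1])
  expect_false(adm[3, 2])  # diagonal from (2,1)
  # "current" uses only the last treated combination
  st$history <- rbind(st$history,
                      data.frame(cohort = 2, pos_a = 2, pos_b = 1, n = 3, y = 0))
  admc <- neighbor_admissible(st, "current")
  expect_false(admc[3, 2])  # diagonal escalation from the current (2,1)
  expect_false(admc[1, 3])  # two levels away
  expect_true(admc[3, 1])
})

test_that("overdose rule bars toxic combinations and empty sets signal termination", {
  st <- make_state(matrix(c(9L, 6L, 0L, 6L, 0L, 0L, 0L, 0L, 0L), 3, 3, byrow = TRUE),
                   matrix(c(0L, 4L, 0L, 4L, 0L, 0L, 0L, 0L, 0L), 3, 3, byrow = TRUE))
  st$history <- data.frame(cohort = 1, pos_a = 1, pos_b = 1, n = 3, y = 0)
  est <- mtc_estimate(st, 0.3)
  q <- overdose_measure(est)
  cfg <- design_config()
  adm <- pipe_admissible(st, est, q, cfg)
  # the decisively toxic neighbours (4/6) must be barred
  expect_false(adm[1, 2])
  expect_false(adm[2, 1])
  expect_true(adm[1, 1])
  # all-toxic lowest combination: q11 >= epsilon signals a safety stop
  st2 <- make_state(matrix(c(6L, rep(0L, 8)), 3, 3),
                    matrix(c(5L, rep(0L, 8)), 3, 3))
  q2 <- overdose_measure(mtc_estimate(st2, 0.3))
  expect_gte(q2[1, 1], cfg$epsilon_pipe)
})

test_that("weighted randomisation uses inverse sample sizes", {
  st <- new_trial_state(c(3, 3))
  st$n[1, 1] <- 3L
  adm <- matrix(FALSE, 3, 3); adm[1, 1] <- TRUE; adm[1, 2] <- TRUE
  w_unseen <- 1 / st$prior_ss
  w_seen <- 1 / (3 + st$prior_ss)
  p_unseen <- w_unseen / (w_unseen + w_seen)
  set.seed(99)
  picks <- replicate(4000, pipe_next_dose(adm, st)[2])
  phat <- mean(picks == 2)
  se <- sqrt(p_unseen * (1 - p_unseen) / 4000)
  expect_lt(abs(phat - p_unseen), 3 * se)
  # single candidate needs no randomness
  adm2 <- matrix(FALSE, 3, 3); adm2[2, 1] <- TRUE
  expect_equal(pipe_next_dose(adm2, st), c(2, 1))
})

test_that("final selection picks the closest posterior mean below the contour", {
  st <- make_state(matrix(c(12L, 6L, 0L, 6L, 0L, 0L, 0L, 0L, 0L), 3, 3, byrow = TRUE),
                   matrix(c(1L, 1L, 0L, 4L, 0L, 0L, 0L, 0L, 0L), 3, 3, byrow = TRUE))
  est <- mtc_estimate(st, 0.3)
  cfg <- design_config()
  sel <- pipe_select_final(st, est, cfg)
  # (1,2) with 1/6 has posterior mean nearer 0.30 than (1,1) with 1/12
  pm <- beta_posterior_mean(st)
  expect_equal(sel, c(1, 2))
  expect_lt(abs(pm[1, 2] - 0.3), abs(pm[1, 1] - 0.3))
  # nothing with six patients -> no selection
  st2 <- make_state(matrix(c(3L, rep(0L, 8)), 3, 3), matrix(0L, 3, 3))
  expect_null(pipe_select_final(st2, mtc_estimate(st2, 0.3), cfg))
  # combinations above the contour are never selected even with many patients
  st3 <- make_state(matrix(c(12L, 12L, rep(0L, 7)), 3, 3),
                    matrix(c(1L, 6L, rep(0L, 7)), 3, 3))
  est3 <- mtc_estimate(st3, 0.3)
  expect_equal(est3$contour[2, 1], 1L)  # 6/12 DLTs puts (2,1) above
  sel3 <- pipe_select_final(st3, est3, cfg)
  expect_false(identical(sel3, c(2, 1)))
})

test_that("allocation paths respect the neighbouring constraint and safety rule", {
  cfg <- design_config(lambda = 0.6)
  for (s in 1:10) {
    r <- run_trial(load_scenario("A1"), "pipe", "mtc", cfg, seed = s)
    h <- r$state$history
    # every cohort (after the first) within one level of some earlier cohort,
    # never a simultaneous escalation of both agents
    for (k in 2:nrow(h)) {
      da <- h$pos_a[k] - h$pos_a[1:(k - 1)]
      db <- h$pos_b[k] - h$pos_b[1:(k - 1)]
      near <- abs(da) <= 1 & abs(db) <= 1 & !(da > 0 & db > 0)
      expect_true(any(near))
    }
  }
})

test_that("toxic truths yield stochastically more DLTs than benign truths", {
  cfg <- design_config(lambda = 1)
  hot <- load_scenario("A1")
  cold <- scenario(matrix(0.05, 3, 3), "benign")
  d_hot <- sapply(1:60, function(s) sum(run_trial(hot, "pipe", "mtc", cfg, seed = s)$state$y))
  d_cold <- sapply(1:60, function(s) sum(run_trial(cold, "pipe", "mtc", cfg, seed = s)$state$y))
  expect_gt(mean(d_hot), mean(d_cold) + 2)
})
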