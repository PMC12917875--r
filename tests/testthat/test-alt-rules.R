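test_that("interval probabilities come from the beta posterior with monotone clamping", {
  # uniform Beta(1,1) everywhere: P(R1)=0.16, P(R3)=0.67 exactly
  st <- new_trial_state(c(3, 3))
  st$prior_a <- matrix(1, 3, 3); st$prior_b <- matrix(1, 3, 3)
  ip <- interval_probs(st)
  expect_equal(ip$p_under, matrix(0.16, 3, 3))
  expect_equal(ip$p_over, matrix(1 - 0.33, 3, 3))
  # clamping: a raw violation is replaced by the neighbour's value
  m <- matrix(c(0.2, 0.5, 0.1, 0.3), 2, 2, byrow = TRUE)
  cl <- mtcinsert:::enforce_monotone(m, decreasing = TRUE)
  expect_lte(cl[1, 2], 0.2)
  expect_true(all(diff(cl) <= 1e-12), all(diff(t(cl)) <= 1e-12))
  # no-op on already-monotone input
  mono <- matrix(c(0.9, 0.8, 0.8, 0.7), 2, 2)
  expect_equal(mtcinsert:::enforce_monotone(mono, decreasing = TRUE), mono)
  inc <- matrix(c(0.1, 0.2, 0.2, 0.4), 2, 2)
  expect_equal(mtcinsert:::enforce_monotone(inc, decreasing = FALSE), inc)
})

test_that("clamping is idempotent on random matrices", {
  set.seed(21)
  for (rep in 1:20) {
    m <- matrix(runif(9), 3, 3)
    once <- mtcinsert:::enforce_monotone(m, decreasing = TRUE)
    expect_equal(mtcinsert:::enforce_monotone(once, decreasing = TRUE), once)
    up <- mtcinsert:::enforce_monotone(m, decreasing = FALSE)
    expect_equal(mtcinsert:::enforce_monotone(up, decreasing = FALSE), up)
  }
})

fake_probs <- function(u, o) {
  structure(list(p_under = u, p_over = o), class = "interval_probs")
}

test_that("rule-1 trigger demands every combination look unacceptable", {
  u <- matrix(0.1, 2, 2); o <- matrix(0.1, 2, 2)
  expect_false(alt1_trigger(fake_probs(u, o), 0.7))
  u <- matrix(c(0.9, 0.9, 0.1, 0.1), 2, 2)
  o <- matrix(c(0.1, 0.1, 0.9, 0.9), 2, 2)
  expect_true(alt1_trigger(fake_probs(u, o), 0.7))
  # cutoff 1 disables the rule (strict >)
  expect_false(alt1_trigger(fake_probs(matrix(1, 2, 2), matrix(1, 2, 2)), 1))
  # the literal conjunction is unsatisfiable for cutoffs >= 0.5 on real
  # posteriors (probabilities of disjoint regions cannot both exceed 0.5)
  expect_false(alt1_trigger(fake_probs(u, o), 0.7, strict = TRUE))
})

test_that("rule-2 trigger needs an under/over step and no explorable combination", {
  st <- new_trial_state(c(2, 2))
  u <- matrix(c(0.8, 0.1, 0.1, 0.1), 2, 2)      # (1,1) underdosed
  o <- matrix(c(0.1, 0.8, 0.8, 0.9), 2, 2)      # neighbours overdosed
  expect_true(alt2_trigger(fake_probs(u, o), st, 0.6))
  # an observed DLT rate inside [1/6, 1/3] vetoes the trigger
  st$n[1, 1] <- 6L; st$y[1, 1] <- 1L
  expect_false(alt2_trigger(fake_probs(u, o), st, 0.6))
  st$y[1, 1] <- 0L  # 0/6 is outside the band again
  expect_true(alt2_trigger(fake_probs(u, o), st, 0.6))
  # all-flat posteriors never trigger at cutoff 0.6
  st2 <- new_trial_state(c(3, 3))
  st2$prior_a <- matrix(1, 3, 3); st2$prior_b <- matrix(1, 3, 3)
  expect_false(alt2_trigger(interval_probs(st2), st2, 0.6))
})

test_that("insertion locations scan under/over steps and match a brute-force scan", {
  u <- matrix(c(0.8, 0.8, 0.1, 0.1, 0.1, 0.1), 3, 2, byrow = TRUE)
  o <- matrix(c(0.1, 0.1, 0.8, 0.8, 0.9, 0.9), 3, 2, byrow = TRUE)
  plan <- alt_insertion_locations(fake_probs(u, o), 0.6)
  expect_equal(plan$a_gaps, 1L)
  expect_length(plan$b_gaps, 0)
  set.seed(5)
  for (rep in 1:20) {
    u <- matrix(runif(9), 3, 3); o <- matrix(runif(9), 3, 3)
    plan <- alt_insertion_locations(fake_probs(u, o), 0.5)
    a_ref <- integer(0); b_ref <- integer(0)
    for (i in 1:2) for (j in 1:3) if (u[i, j] > 0.5 && o[i + 1, j] > 0.5) a_ref <- c(a_ref, i)
    for (i in 1:3) for (j in 1:2) if (u[i, j] > 0.5 && o[i, j + 1] > 0.5) b_ref <- c(b_ref, j)
    expect_equal(plan$a_gaps, sort(unique(a_ref)))
    expect_equal(plan$b_gaps, sort(unique(b_ref)))
  }
  # symmetric input gives a transpose-symmetric plan
  u <- matrix(c(0.9, 0.1, 0.1, 0.1), 2, 2); o <- matrix(c(0.1, 0.9, 0.9, 0.9), 2, 2)
  p1 <- alt_insertion_locations(fake_probs(u, o), 0.6)
  p2 <- alt_insertion_locations(fake_probs(t(u), t(o)), 0.6)
  expect_equal(p1$a_gaps, p2$b_gaps)
  expect_equal(p1$b_gaps, p2$a_gaps)
})

test_that("alternative rules drive whole trials and can insert", {
  cfg <- design_config()
  ins1 <- mean(sapply(1:40, function(s) {
    run_trial(load_scenario("A1"), "pipe", "alt1", cfg, seed = s)$inserted
  }))
  ins2 <- mean(sapply(1:40, function(s) {
    run_trial(load_scenario("A1"), "pipe", "alt2", cfg, seed = s)$inserted
  }))
  expect_gt(ins1 + ins2, 0)  # the interval rules do fire under a hostile truth
  r <- run_trial(load_scenario("A1"), "pipe", "alt2", cfg, seed = 11)
  expect_true(r$termination_reason %in% c("completed", "toxicity_stop", "no_admissible"))
})
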