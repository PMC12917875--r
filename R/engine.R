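# Trial orchestration: single seeded trials, replicated studies and the
# case-study replay.

`%||%` <- function(a, b) if (is.null(a)) b else a

rule_cutoffs <- function(insertion_rule, config) {
  c1 <- config$cutoff_under %||% switch(insertion_rule, alt1 = 0.7, alt2 = 0.6, NA)
  c2 <- config$cutoff_over %||% c1
  c(c1, c2)
}

#' Simulate (or replay) a single dual-agent dose-finding trial
#'
#' Runs the full cohort loop: treat the current combination, update the
#' per-combination counts and beta posteriors, apply the insertion check
#' (when the window is open) before any escalation decision, then escalate
#' per the host design, stopping when the sample size is exhausted or the
#' design terminates. The cohort treated directly after an insertion must
#' receive a combination containing a new dose level; by default
#' (\code{persist_restrict}) later cohorts keep preferring new-level
#' combinations whenever the host design's rules admit one.
#'
#' @param scen A \code{scenario} giving the true toxicities (may be
#'   \code{NULL} when \code{responses} supplies the outcomes).
#' @param design Host escalation design, \code{"pipe"} or \code{"blrm"}.
#' @param insertion_rule \code{"mtc"} (contour rule), \code{"alt1"},
#'   \code{"alt2"} (interval rules) or \code{"off"}.
#' @param config A \code{design_config}.
#' @param seed Integer seed; the trial is fully reproducible given
#'   (scenario, design, rule, config, seed).
#' @param priors \code{blrm_priors} for the logistic-model design (its
#'   standardized doses must match the starting grid).
#' @param responses Optional list-matrix of fixed per-combination response
#'   streams (as from \code{\link{case_study_responses}}); replaces the
#'   binomial outcome draws.
#' @param trace Keep a per-cohort log of allocations, contour probabilities
#'   and insertion decisions.
#' @return A list of class \code{trial_result}.
#' @export
run_trial <- function(scen = NULL, design = c("pipe", "blrm"),
                      insertion_rule = c("mtc", "alt1", "alt2", "off"),
                      config = design_config(), seed = NULL,
                      priors = NULL, responses = NULL, trace = FALSE) {
  design <- match.arg(design)
  insertion_rule <- match.arg(insertion_rule)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(scen) && is.null(responses)) {
    stop("either a scenario or fixed response streams must be supplied")
  }

  shape <- if (!is.null(scen)) dim(scen$truth) else dim(responses)
  prior <- pipe_prior(shape)
  state <- new_trial_state(shape, prior$median, prior$ss, config$prior_param)
  if (design == "blrm") priors <- priors %||% blrm_priors()
  std_a <- if (design == "blrm") priors$std_doses_a else NULL
  std_b <- if (design == "blrm") priors$std_doses_b else NULL
  truth <- if (!is.null(scen)) scen else NULL
  base_counts <- if (!is.null(responses)) {
    list(n = attr(responses, "n_obs"), y = attr(responses, "y_obs"))
  } else NULL
  resp_used <- if (!is.null(responses)) matrix(0L, shape[1], shape[2]) else NULL
  cutoffs <- rule_cutoffs(insertion_rule, config)

  current <- c(1L, 1L)  # starting combination is always the lowest
  total <- 0L; cohort <- 0L
  restrict <- NULL
  term <- "completed"
  log <- list()

  repeat {
    cohort <- cohort + 1L
    k <- min(config$cohort_size, config$max_n - total)
    i <- current[1]; j <- current[2]
    out <- if (!is.null(responses)) {
      used <- resp_used[i, j]
      if (used + k > length(responses[[i, j]])) {
        stop("response stream exhausted at combination (", i, ",", j, ")")
      }
      resp_used[i, j] <- used + k
      responses[[i, j]][(used + 1L):(used + k)]
    } else {
      stats::rbinom(k, 1L, truth$truth[i, j])
    }
    state$n[i, j] <- state$n[i, j] + k
    state$y[i, j] <- state$y[i, j] + sum(out)
    total <- total + k
    state$history <- rbind(state$history, data.frame(
      cohort = cohort, pos_a = state$levels_a[i], pos_b = state$levels_b[j],
      n = k, y = sum(out)))

    # --- insertion check, prior to any escalation decision ---
    ins_event <- NULL
    if (insertion_rule != "off" &&
        window_open(total, config, state$insertion_done)) {
      plan <- NULL
      if (insertion_rule == "mtc") {
        est <- mtc_estimate(state, config$theta)
        if (trace) {
          ins_event <- list(prob = est$probability, triggered = FALSE)
        }
        if (insertion_triggered(est, config$lambda)) {
          plan <- insertion_candidates(est$contour, state)
        }
      } else {
        ip <- interval_probs(state)
        trig <- if (insertion_rule == "alt1") {
          alt1_trigger(ip, cutoffs[1], cutoffs[2])
        } else {
          alt2_trigger(ip, state, cutoffs[1], cutoffs[2])
        }
        if (trig) {
          plan <- filter_plan(
            alt_insertion_locations(ip, cutoffs[1], cutoffs[2]), state)
        }
      }
      if (!is.null(plan) && plan_size(plan) > 0L) {
        state <- expand_state(state, plan)
        state$insertion_cohort <- cohort
        if (!is.null(truth)) truth <- expand_truth(truth, plan)
        if (!is.null(responses)) {
          exp_r <- expand_responses(responses, resp_used, base_counts, plan,
                                    config$max_n)
          responses <- exp_r$responses; resp_used <- exp_r$used
          base_counts <- exp_r$base_counts
        }
        if (design == "blrm") {
          std_a <- expand_std_doses(std_a, plan$a_gaps)
          std_b <- expand_std_doses(std_b, plan$b_gaps)
          priors$std_doses_a <- std_a; priors$std_doses_b <- std_b
        }
        restrict <- new_combination_mask(state)
        if (trace) {
          ins_event <- c(ins_event %||% list(),
                         list(triggered = TRUE, plan = plan, total = total))
        }
      }
    }

    if (trace) {
      log[[cohort]] <- list(cohort = cohort, combo = c(i, j),
                            pos = c(state$history$pos_a[cohort],
                                    state$history$pos_b[cohort]),
                            dlt = sum(out), total = total,
                            insertion = ins_event)
    }

    if (total >= config$max_n) break

    # --- escalation per the host design ---
    if (design == "pipe") {
      est <- mtc_estimate(state, config$theta)
      q <- overdose_measure(est)
      if (q[1, 1] >= config$epsilon_pipe) { term <- "toxicity_stop"; break }
      adm <- pipe_admissible(state, est, q, config)
      if (!is.null(restrict)) {
        r <- adm & restrict
        if (any(r)) adm <- r
        if (!isTRUE(config$persist_restrict)) restrict <- NULL
      }
      if (!any(adm)) { term <- "no_admissible"; break }
      current <- pipe_next_dose(adm, state)
    } else {
      post <- blrm_fit(state, priors, config$blrm_samples, config$blrm_burnin,
                       config$blrm_interaction)
      nxt <- blrm_next_dose(post, state, config, priors,
                            extra_mask = restrict)
      if (is.null(nxt) && !is.null(restrict)) {
        nxt <- blrm_next_dose(post, state, config, priors)
      }
      restrict <- NULL
      if (is.null(nxt)) { term <- "toxicity_stop"; break }
      current <- nxt
    }
  }

  # --- final selection ---
  sel <- NULL
  if (term == "completed") {
    if (design == "pipe") {
      sel <- pipe_select_final(state, mtc_estimate(state, config$theta),
                               config)
    } else {
      post <- blrm_fit(state, priors, config$blrm_samples, config$blrm_burnin,
                       config$blrm_interaction)
      sel <- blrm_select_final(post, state, config)
    }
  }

  sel_pos <- if (!is.null(sel)) {
    c(state$levels_a[sel[1]], state$levels_b[sel[2]])
  } else NULL
  sel_tox <- if (!is.null(sel) && !is.null(truth)) {
    truth$truth[sel[1], sel[2]]
  } else NA_real_
  classification <- if (is.null(sel)) "none" else if (is.na(sel_tox)) {
    NA_character_
  } else classify_combo(sel_tox)

  if (!is.null(truth)) {
    tox_class <- classify_combo(truth$truth)
    n_acceptable <- sum(state$n[is_acceptable_class(tox_class)])
    n_toxic <- sum(state$n[tox_class == "toxic"])
  } else {
    n_acceptable <- NA_real_; n_toxic <- NA_real_
  }

  structure(list(
    selection = sel, selection_pos = sel_pos, selection_true_tox = sel_tox,
    selection_inserted = if (!is.null(sel)) {
      state$inserted_a[sel[1]] || state$inserted_b[sel[2]]
    } else NA,
    classification = classification,
    inserted = state$insertion_done,
    insertion_cohort = state$insertion_cohort,
    termination_reason = term, total_n = total,
    n_acceptable = n_acceptable, n_toxic = n_toxic,
    state = state, truth = truth, seed = seed,
    trace = if (trace) log else NULL
  ), class = "trial_result")
}

#' @export
print.trial_result <- function(x, ...) {
  cat("Trial result (", x$termination_reason, ", n = ", x$total_n, ")\n",
      sep = "")
  if (is.null(x$selection)) {
    cat("No combination selected\n")
  } else {
    cat("Selected combination at levels (", x$selection_pos[1], ", ",
        x$selection_pos[2], ")",
        if (isTRUE(x$selection_inserted)) " [inserted]", "\n", sep = "")
    if (!is.na(x$selection_true_tox)) {
      cat(sprintf("True toxicity %.3f (%s)\n", x$selection_true_tox,
                  x$classification))
    }
  }
  if (x$inserted) cat("Insertion at cohort", x$insertion_cohort, "\n")
  print(x$state)
  invisible(x)
}

expand_std_doses <- function(std, gaps) {
  if (!length(gaps)) return(std)
  expand_levels(std, rep(FALSE, length(std)), gaps)$levels
}

# Extend fixed response streams to an expanded grid. New combinations draw
# per-patient DLT probabilities from Beta(1 + ybar, 1 + nbar - ybar), where
# nbar/ybar are midpoint interpolations of the flanking combinations'
# observed totals in the source study.
expand_responses <- function(responses, used, base_counts, plan, max_n) {
  nb <- interp_expand(base_counts$n + 0, plan$a_gaps, plan$b_gaps)
  yb <- interp_expand(base_counts$y + 0, plan$a_gaps, plan$b_gaps)
  Inew <- nrow(nb$mat); Jnew <- ncol(nb$mat)
  old_i <- which(!nb$new_rows); old_j <- which(!nb$new_cols)
  out <- matrix(vector("list", Inew * Jnew), Inew, Jnew)
  out[old_i, old_j] <- responses
  new_used <- matrix(0L, Inew, Jnew)
  new_used[old_i, old_j] <- used
  for (i in seq_len(Inew)) for (j in seq_len(Jnew)) {
    if (!is.null(out[[i, j]])) next
    stream <- integer(max_n)
    for (t in seq_len(max_n)) {
      p <- stats::rbeta(1, 1 + yb$mat[i, j], 1 + nb$mat[i, j] - yb$mat[i, j])
      stream[t] <- stats::rbinom(1, 1, p)
    }
    out[[i, j]] <- stream
  }
  list(responses = out, used = new_used,
       base_counts = list(n = nb$mat, y = yb$mat))
}

#' Replicated simulation study for one scenario and threshold
#'
#' Runs \code{n_reps} independent trials (seeds \code{base_seed + 1 ...
#' base_seed + n_reps}; the same rep shares its outcome stream across
#' thresholds and rules, a common-random-numbers comparison) and aggregates
#' the operating characteristics.
#'
#' @param scen A \code{scenario} or the name of a built-in one.
#' @param lambda MTC threshold (stored into \code{config}).
#' @inheritParams run_trial
#' @param n_reps Number of replicated trials.
#' @param base_seed Base seed for the replication stream.
#' @return An \code{oc_summary}.
#' @export
run_study <- function(scen, lambda = NULL, design = c("pipe", "blrm"),
                      insertion_rule = c("mtc", "alt1", "alt2", "off"),
                      n_reps = 1000, base_seed = 1,
                      config = design_config(), priors = NULL) {
  design <- match.arg(design)
  insertion_rule <- match.arg(insertion_rule)
  if (is.character(scen)) scen <- load_scenario(scen)
  if (!is.null(lambda)) config$lambda <- lambda
  results <- vector("list", n_reps)
  for (r in seq_len(n_reps)) {
    results[[r]] <- run_trial(scen, design, insertion_rule, config,
                              seed = base_seed + r, priors = priors)
  }
  summarize_trials(results, scen, config$theta)
}

#' Replay both-design case study with fixed response streams
#'
#' Regenerates the fixed per-combination response streams under the given
#' seed (identical streams for either design at the same seed) and reruns the
#' chosen design on the reduced case-study grid, tracing every cohort and any
#' insertion.
#'
#' @param design \code{"pipe"} or \code{"blrm"}.
#' @param lambda MTC threshold (the contour insertion rule is used).
#' @param seed Seed for the response streams and the trial.
#' @param config A \code{design_config}.
#' @return A \code{trial_result} with a per-cohort \code{trace}.
#' @export
replay_case_study <- function(design = c("pipe", "blrm"), lambda = 0.6,
                              seed = 1, config = design_config()) {
  design <- match.arg(design)
  config$lambda <- lambda
  set.seed(seed)
  responses <- case_study_responses(config$max_n)
  run_trial(scen = NULL, design = design, insertion_rule = "mtc",
            config = config, seed = NULL, responses = responses,
            trace = TRUE)
}
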