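# Trial state and design configuration containers shared by both host designs.

#' Design configuration for a dual-agent dose-finding trial
#'
#' Collects the tunable parameters of the host escalation designs and the
#' insertion procedure. Defaults reproduce the reference simulation setting:
#' target toxicity 0.30, cohorts of three, maximum 48 patients, insertion
#' window 18--42 treated patients, a single insertion timepoint, PIPE overdose
#' threshold 0.5 and EWOC bound P(pi > 0.33) <= 0.40.
#'
#' @param theta Target toxicity probability in (0, 1).
#' @param lambda MTC threshold in [0, 1]; the modal contour probability must
#'   strictly exceed it to trigger an insertion. 1 turns insertions off;
#'   values below 0.5 are allowed but not recommended (two contours can then
#'   be near-equally probable because some combination is close to target).
#' @param cohort_size Patients per cohort.
#' @param max_n Maximum total sample size.
#' @param insertion_window Two totals (inclusive) of treated patients between
#'   which an insertion may occur.
#' @param epsilon_pipe PIPE overdose threshold: combinations with contour-
#'   averaged overdose probability \code{q >= epsilon_pipe} are inadmissible,
#'   and the trial stops if the lowest combination fails.
#' @param min_patients_select Minimum patients on a combination for it to be
#'   selectable at trial end.
#' @param ewoc_zeta,ewoc_epsilon EWOC rule for the logistic-model design: a
#'   combination is admissible only if P(pi > ewoc_zeta) <= ewoc_epsilon.
#' @param cutoff_under,cutoff_over Interval-rule cutoffs C1/C2 for the
#'   alternative insertion rules; \code{NULL} means use the calibrated default
#'   of the selected rule (0.7 for rule 1, 0.6 for rule 2).
#' @param adjacency How PIPE targets the contour: \code{"adjacent"} (cells
#'   touching the contour from either side), \code{"closest-below"} (cells
#'   touching it from below only) or \code{"none"} (no contour filter; the
#'   inverse-sample-size weighting alone steers allocation).
#' @param constraint Neighbouring constraint: \code{"current"} (the next
#'   combination must be within one level of the one just treated) or
#'   \code{"any-previous"} (within one level of any previously treated
#'   combination); diagonal escalation is excluded either way.
#' @param allow_multiple_insertions If \code{TRUE}, insertions may occur at
#'   more than one timepoint (still only at midpoints of original levels).
#' @param blrm_estimator Toxicity estimate used for logistic-model escalation:
#'   \code{"plugin"} (posterior parameter means substituted into the model) or
#'   \code{"average"} (posterior mean of the per-draw probabilities).
#' @param blrm_interaction Interaction term: \code{"printed"} uses the odds
#'   multiplier exp(eta * log(1 + exp(dA) exp(dB))); \code{"classical"} uses
#'   exp(eta * dA * dB).
#' @param adjacency_phase When the contour-adjacency filter applies:
#'   \code{"post-insertion"} (default; before an insertion the design
#'   explores the whole safe neighbourhood, after one it targets the contour)
#'   or \code{"always"}.
#' @param persist_restrict If \code{TRUE} (default), every post-insertion
#'   cohort prefers combinations involving a new dose level whenever the host
#'   design's own rules admit one; if \code{FALSE}, only the cohort directly
#'   after the insertion is so restricted.
#' @param select_mode Final-selection eligibility: \code{"frontier"}
#'   (default; combinations closest to below the final contour),
#'   \code{"below"} (any combination below it) or \code{"any"}.
#' @param prior_param Beta hyperparameter derivation from the prior centres,
#'   \code{"median"} (default) or \code{"mean"}; see
#'   \code{\link{beta_from_median}}.
#' @param blrm_samples,blrm_burnin Retained MCMC draws and burn-in iterations.
#' @return A list of class \code{design_config}.
#' @export
design_config <- function(theta = 0.30, lambda = 0.6, cohort_size = 3,
                          max_n = 48, insertion_window = c(18, 42),
                          epsilon_pipe = 0.5, min_patients_select = 6,
                          ewoc_zeta = 0.33, ewoc_epsilon = 0.40,
                          cutoff_under = NULL, cutoff_over = NULL,
                          adjacency = c("adjacent", "closest-below", "none"),
                          adjacency_phase = c("post-insertion", "always"),
                          constraint = c("any-previous", "current"),
                          persist_restrict = TRUE,
                          select_mode = c("frontier", "below", "any"),
                          prior_param = c("median", "mean"),
                          allow_multiple_insertions = FALSE,
                          blrm_estimator = c("plugin", "average"),
                          blrm_interaction = c("printed", "classical"),
                          blrm_samples = 2000, blrm_burnin = 1000) {
  stopifnot(theta > 0, theta < 1, lambda >= 0, lambda <= 1,
            cohort_size >= 1, max_n >= cohort_size,
            length(insertion_window) == 2L,
            insertion_window[1] <= insertion_window[2],
            epsilon_pipe > 0, ewoc_zeta > 0, ewoc_zeta <= 1,
            ewoc_epsilon > 0, min_patients_select >= 0)
  structure(list(
    theta = theta, lambda = lambda, cohort_size = cohort_size, max_n = max_n,
    insertion_window = insertion_window, epsilon_pipe = epsilon_pipe,
    min_patients_select = min_patients_select,
    ewoc_zeta = ewoc_zeta, ewoc_epsilon = ewoc_epsilon,
    cutoff_under = cutoff_under, cutoff_over = cutoff_over,
    adjacency = match.arg(adjacency),
    adjacency_phase = match.arg(adjacency_phase),
    constraint = match.arg(constraint),
    persist_restrict = isTRUE(persist_restrict),
    select_mode = match.arg(select_mode),
    prior_param = match.arg(prior_param),
    allow_multiple_insertions = allow_multiple_insertions,
    blrm_estimator = match.arg(blrm_estimator),
    blrm_interaction = match.arg(blrm_interaction),
    blrm_samples = blrm_samples, blrm_burnin = blrm_burnin
  ), class = "design_config")
}

#' Beta hyperparameters matching a given prior centre and sample size
#'
#' Given a prior centre m and a total prior sample size s, returns the
#' Beta(a, b) hyperparameters with a + b = s whose MEDIAN equals m (solved by
#' root finding on the beta CDF; results are cached). With very small s such
#' a prior is bimodal: its mass splits between 0 and 1 so that
#' P(pi <= m) = 0.5, and its mean lies close to 0.5 rather than at m. The
#' simpler mean-matching parameterisation a = m s, b = (1 - m) s is available
#' via \code{param = "mean"}.
#'
#' @param m Prior centre(s) in (0, 1) (vectorised).
#' @param ss Total prior sample size a + b.
#' @param param \code{"median"} (default) or \code{"mean"}.
#' @return List with matrices/vectors \code{a} and \code{b} shaped like
#'   \code{m}.
#' @export
beta_from_median <- function(m, ss, param = c("median", "mean")) {
  param <- match.arg(param)
  if (any(m <= 0) || any(m >= 1) || ss <= 0) {
    stop("prior centres must lie in (0, 1) and the sample size be positive")
  }
  if (param == "mean") {
    return(list(a = m * ss, b = (1 - m) * ss))
  }
  a <- vapply(as.vector(m), function(mi) {
    key <- sprintf("%.12g|%.12g", mi, ss)
    hit <- .beta_med_cache[[key]]
    if (!is.null(hit)) return(hit)
    f <- function(a) stats::pbeta(mi, a, ss - a) - 0.5
    root <- stats::uniroot(f, c(ss * 1e-9, ss * (1 - 1e-9)), tol = 1e-12)$root
    .beta_med_cache[[key]] <- root
    root
  }, numeric(1))
  if (is.matrix(m)) a <- matrix(a, nrow(m), ncol(m))
  list(a = a, b = ss - a)
}

.beta_med_cache <- new.env(parent = emptyenv())

#' Create a fresh trial state
#'
#' The state tracks, per combination, the patients treated and toxicities
#' observed, together with the beta prior framework (per-combination prior
#' centres, a shared prior sample size, and the implied Beta hyperparameters;
#' see \code{\link{beta_from_median}}), the dose-level geometry (original
#' level positions are integers, inserted levels sit at midpoints) and the
#' insertion status.
#'
#' @param shape Grid dimensions c(I, J), or omitted when \code{prior_centre}
#'   is given.
#' @param prior_centre Matrix of prior toxicity centres (medians by default);
#'   defaults to the fixture pattern of \code{\link{pipe_prior}}.
#' @param prior_ss Shared prior sample size; defaults to 1/(I*J).
#' @param prior_param Hyperparameter derivation, \code{"median"} or
#'   \code{"mean"}; see \code{\link{beta_from_median}}.
#' @return A list of class \code{trial_state}.
#' @export
new_trial_state <- function(shape = c(3, 3), prior_centre = NULL,
                            prior_ss = NULL,
                            prior_param = c("median", "mean")) {
  prior_param <- match.arg(prior_param)
  if (!is.null(prior_centre)) shape <- dim(prior_centre)
  I <- shape[1]; J <- shape[2]
  if (is.null(prior_centre)) prior_centre <- pipe_prior(shape)$median
  if (is.null(prior_ss)) prior_ss <- 1 / (I * J)
  stopifnot(all(prior_centre > 0), all(prior_centre < 1), prior_ss > 0)
  ab <- beta_from_median(prior_centre, prior_ss, prior_param)
  structure(list(
    levels_a = as.numeric(seq_len(I)), levels_b = as.numeric(seq_len(J)),
    inserted_a = rep(FALSE, I), inserted_b = rep(FALSE, J),
    original_shape = c(I, J),
    n = matrix(0L, I, J), y = matrix(0L, I, J),
    prior_centre = prior_centre, prior_ss = prior_ss,
    prior_param = prior_param, prior_a = ab$a, prior_b = ab$b,
    history = data.frame(cohort = integer(0), pos_a = numeric(0),
                         pos_b = numeric(0), n = integer(0), y = integer(0)),
    insertion_done = FALSE, insertion_cohort = NA_integer_
  ), class = "trial_state")
}

#' @export
print.trial_state <- function(x, ...) {
  I <- length(x$levels_a); J <- length(x$levels_b)
  cat("Trial state on a", I, "x", J, "grid (",
      sum(x$n), "patients,", sum(x$y), "DLTs )\n")
  disp <- matrix(paste0(x$y, "/", x$n), I, J)
  rownames(disp) <- ifelse(x$inserted_a, paste0("[", x$levels_a, "]"), x$levels_a)
  colnames(disp) <- ifelse(x$inserted_b, paste0("[", x$levels_b, "]"), x$levels_b)
  print(disp, quote = FALSE)
  if (x$insertion_done) {
    cat("Insertion occurred at cohort", x$insertion_cohort, "\n")
  }
  invisible(x)
}

# Posterior beta shape parameters under the conjugate update.
posterior_alpha <- function(state) state$prior_a + state$y
posterior_beta <- function(state) state$prior_b + state$n - state$y

#' Posterior mean toxicity per combination under the beta framework
#' @param state A \code{trial_state}.
#' @return Matrix of posterior means (a + y) / (a + b + n).
#' @export
beta_posterior_mean <- function(state) {
  a <- posterior_alpha(state); b <- posterior_beta(state)
  a / (a + b)
}

#' Below-target posterior probabilities for every combination
#' @param state A \code{trial_state}.
#' @param theta Target toxicity.
#' @return Matrix of P(pi_ij <= theta | data).
#' @export
state_below_target <- function(state, theta = 0.30) {
  stats::pbeta(theta, posterior_alpha(state), posterior_beta(state))
}

#' Contour posterior for the current trial state
#'
#' Convenience wrapper combining \code{\link{state_below_target}} and
#' \code{\link{contour_distribution}}.
#'
#' @param state A \code{trial_state}.
#' @param theta Target toxicity.
#' @return An \code{mtc_estimate}.
#' @export
mtc_estimate <- function(state, theta = 0.30) {
  contour_distribution(state_below_target(state, theta))
}
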