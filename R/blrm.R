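# Two-dimensional five-parameter Bayesian logistic regression host design:
# joint toxicity model with an interaction odds multiplier, adaptive
# random-walk Metropolis sampling, EWOC admissibility and patient-gain
# escalation.

#' Prior specification for the dual-agent logistic model
#'
#' The model has parameters (alpha1, alpha2, beta1, beta2, eta): single-agent
#' logistic intercepts/slopes for each agent plus an interaction parameter.
#' Priors are normal on (alpha1, log alpha2), (beta1, log beta2) and eta.
#' Defaults are the calibrated operational priors of the reference simulation
#' setting: intercepts N(-2, 10), log-slopes N(0.5, 0.25), eta N(0, 0.25)
#' (variances), standardized doses (0.10, 0.25, 0.40) for both agents, and
#' EWOC rule P(pi > 0.33) <= 0.40.
#'
#' @param mu_a1,var_a1 Mean and variance of alpha1 (Agent A intercept).
#' @param mu_la2,var_la2 Mean and variance of log(alpha2) (Agent A log-slope).
#' @param mu_b1,var_b1,mu_lb2,var_lb2 Same for Agent B.
#' @param mu_eta,var_eta Mean and variance of the interaction parameter.
#' @param std_doses_a,std_doses_b Strictly increasing standardized doses.
#' @param ewoc_zeta,ewoc_epsilon EWOC overdose bound and probability cutoff.
#' @return A list of class \code{blrm_priors}.
#' @export
blrm_priors <- function(mu_a1 = -2, var_a1 = 10, mu_la2 = 0.5, var_la2 = 0.25,
                        mu_b1 = -2, var_b1 = 10, mu_lb2 = 0.5, var_lb2 = 0.25,
                        mu_eta = 0, var_eta = 0.25,
                        std_doses_a = c(0.10, 0.25, 0.40),
                        std_doses_b = c(0.10, 0.25, 0.40),
                        ewoc_zeta = 0.33, ewoc_epsilon = 0.40) {
  stopifnot(var_a1 > 0, var_la2 > 0, var_b1 > 0, var_lb2 > 0, var_eta > 0,
            all(diff(std_doses_a) > 0), all(diff(std_doses_b) > 0))
  structure(list(
    mu = c(a1 = mu_a1, la2 = mu_la2, b1 = mu_b1, lb2 = mu_lb2, eta = mu_eta),
    sd = sqrt(c(a1 = var_a1, la2 = var_la2, b1 = var_b1, lb2 = var_lb2,
                eta = var_eta)),
    std_doses_a = std_doses_a, std_doses_b = std_doses_b,
    ewoc_zeta = ewoc_zeta, ewoc_epsilon = ewoc_epsilon
  ), class = "blrm_priors")
}

#' Joint toxicity probability of a dose combination
#'
#' Single-agent toxicities are logistic in the standardized doses,
#' psi_A = logistic(alpha1 + alpha2 dA) and psi_B likewise. Without
#' interaction the no-toxicity probabilities multiply,
#' p = 1 - (1 - psi_A)(1 - psi_B); the interaction enters as an odds
#' multiplier, odds = odds_noint * exp(eta * log(1 + exp(dA) exp(dB)))
#' (or the classical exp(eta * dA * dB) when requested).
#'
#' @param params Named vector or list with elements \code{alpha1},
#'   \code{alpha2}, \code{beta1}, \code{beta2}, \code{eta} (slopes positive).
#' @param d_a,d_b Standardized doses (vectorised, recycled together).
#' @param interaction \code{"printed"} (default odds multiplier) or
#'   \code{"classical"}.
#' @return Toxicity probabilities in (0, 1).
#' @examples
#' p <- joint_tox_prob(c(alpha1 = 0, alpha2 = 1, beta1 = 0, beta2 = 1,
#'                       eta = 1), 0, 0)  # 6/7
#' @export
joint_tox_prob <- function(params, d_a, d_b,
                           interaction = c("printed", "classical")) {
  interaction <- match.arg(interaction)
  params <- as.list(params)
  a1 <- params$alpha1; a2 <- params$alpha2
  b1 <- params$beta1; b2 <- params$beta2; eta <- params$eta
  if (a2 <= 0 || b2 <= 0) stop("slope parameters must be positive")
  # log(1 - psi) computed stably on the log scale
  l1mA <- stats::plogis(a1 + a2 * d_a, lower.tail = FALSE, log.p = TRUE)
  l1mB <- stats::plogis(b1 + b2 * d_b, lower.tail = FALSE, log.p = TRUE)
  s <- l1mA + l1mB                      # log(1 - p_noint)
  logp <- log(-expm1(s))                # log(p_noint)
  logodds <- logp - s
  inter <- if (interaction == "printed") {
    eta * log1p(exp(d_a + d_b))
  } else {
    eta * d_a * d_b
  }
  stats::plogis(logodds + inter)
}

# Log posterior density (up to a constant) for phi = (a1, la2, b1, lb2, eta).
blrm_log_post <- function(phi, n, y, da_grid, db_grid, priors, interaction) {
  params <- list(alpha1 = phi[1], alpha2 = exp(phi[2]),
                 beta1 = phi[3], beta2 = exp(phi[4]), eta = phi[5])
  lp <- sum(stats::dnorm(phi, priors$mu, priors$sd, log = TRUE))
  obs <- n > 0
  if (any(obs)) {
    pi <- joint_tox_prob(params, da_grid[obs], db_grid[obs], interaction)
    pi <- pmin(pmax(pi, 1e-12), 1 - 1e-12)
    lp <- lp + sum(y[obs] * log(pi) + (n[obs] - y[obs]) * log1p(-pi))
  }
  lp
}

#' Fit the dual-agent logistic model by adaptive random-walk Metropolis
#'
#' Componentwise random-walk Metropolis on (alpha1, log alpha2, beta1,
#' log beta2, eta) with step sizes adapted towards a 44\% acceptance rate
#' during burn-in, plus an adaptive joint random-walk move along the
#' empirical posterior covariance to mix the correlated intercept/slope
#' pairs. Returns posterior draws together with three per-combination
#' summaries: the posterior-averaged toxicity \code{pi_mean}, the plug-in
#' estimate \code{pi_plugin} (posterior parameter means substituted into the
#' model, the escalation default), and \code{pi_exceed} = P(pi > zeta).
#'
#' @param state A \code{trial_state}, or a list with matrices \code{n},
#'   \code{y}.
#' @param priors A \code{blrm_priors}; its standardized doses must match the
#'   grid shape.
#' @param n_samples Retained draws (>= 500).
#' @param burnin Burn-in iterations.
#' @param interaction Interaction form, see \code{\link{joint_tox_prob}}.
#' @return A list of class \code{blrm_posterior}.
#' @export
blrm_fit <- function(state, priors = blrm_priors(), n_samples = 2000,
                     burnin = 1000, interaction = c("printed", "classical")) {
  interaction <- match.arg(interaction)
  if (n_samples < 500) stop("n_samples must be at least 500")
  n <- state$n; y <- state$y
  I <- nrow(n); J <- ncol(n)
  stopifnot(length(priors$std_doses_a) == I, length(priors$std_doses_b) == J)
  da_grid <- matrix(priors$std_doses_a, I, J)
  db_grid <- matrix(priors$std_doses_b, I, J, byrow = TRUE)

  phi <- priors$mu
  lp <- blrm_log_post(phi, n, y, da_grid, db_grid, priors, interaction)
  step <- pmin(priors$sd, 1)
  total <- burnin + n_samples
  draws <- matrix(NA_real_, n_samples, 5,
                  dimnames = list(NULL, c("alpha1", "alpha2", "beta1",
                                          "beta2", "eta")))
  phi_hist <- matrix(NA_real_, total, 5)
  chol_joint <- NULL
  acc <- numeric(5); acc_win <- numeric(5); win <- 0L
  for (t in seq_len(total)) {
    for (k in 1:5) {
      prop <- phi
      prop[k] <- phi[k] + stats::rnorm(1, 0, step[k])
      lp_prop <- blrm_log_post(prop, n, y, da_grid, db_grid, priors,
                               interaction)
      if (log(stats::runif(1)) < lp_prop - lp) {
        phi <- prop; lp <- lp_prop
        acc[k] <- acc[k] + 1; acc_win[k] <- acc_win[k] + 1
      }
    }
    if (!is.null(chol_joint)) {
      # joint move along the burn-in covariance: mixes correlated parameters
      prop <- phi + drop(stats::rnorm(5) %*% chol_joint)
      lp_prop <- blrm_log_post(prop, n, y, da_grid, db_grid, priors,
                               interaction)
      if (log(stats::runif(1)) < lp_prop - lp) {
        phi <- prop; lp <- lp_prop
      }
    }
    win <- win + 1L
    if (t <= burnin && win == 50L) {  # adapt during burn-in only
      rate <- acc_win / 50
      step <- step * exp(pmin(pmax(rate - 0.44, -0.5), 0.5))
      acc_win[] <- 0; win <- 0L
    }
    phi_hist[t, ] <- phi
    if (t %% 250L == 0L && t >= burnin %/% 2) {
      # adaptive joint proposal (Haario-style, growing window)
      keep <- phi_hist[max(1, t %/% 2):t, , drop = FALSE]
      sig <- stats::cov(keep) * (2.38^2 / 5) + diag(1e-10, 5)
      chol_joint <- tryCatch(chol(sig), error = function(e) chol_joint)
    }
    if (t > burnin) {
      draws[t - burnin, ] <- c(phi[1], exp(phi[2]), phi[3], exp(phi[4]),
                               phi[5])
    }
  }

  # per-draw toxicity surfaces
  pi_sum <- matrix(0, I, J); exceed <- matrix(0, I, J)
  for (s in seq_len(n_samples)) {
    pis <- joint_tox_prob(draws[s, ], da_grid, db_grid, interaction)
    pi_sum <- pi_sum + pis
    exceed <- exceed + (pis > priors$ewoc_zeta)
  }
  pi_mean <- pi_sum / n_samples
  pi_exceed <- exceed / n_samples
  pi_plugin <- joint_tox_prob(colMeans(draws), da_grid, db_grid, interaction)

  rhat <- split_rhat(draws)
  if (any(rhat > 1.1, na.rm = TRUE)) {
    warning("possible MCMC non-convergence: split R-hat up to ",
            sprintf("%.2f", max(rhat, na.rm = TRUE)))
  }
  structure(list(samples = draws, pi_mean = pi_mean, pi_plugin = pi_plugin,
                 pi_exceed = pi_exceed, accept_rate = acc / total,
                 rhat = rhat),
            class = "blrm_posterior")
}

# Split-chain R-hat from a single chain's halves.
split_rhat <- function(draws) {
  m <- nrow(draws) %/% 2L
  apply(draws, 2L, function(x) {
    h1 <- x[seq_len(m)]; h2 <- x[m + seq_len(m)]
    W <- (stats::var(h1) + stats::var(h2)) / 2
    B <- m * (mean(h1) - mean(h2))^2 / 2  # 2-chain between variance
    if (W <= 0) return(NA_real_)
    sqrt(((m - 1) / m * W + B / m) / W)
  })
}

#' @export
print.blrm_posterior <- function(x, ...) {
  cat("Dual-agent logistic model posterior (", nrow(x$samples),
      "draws )\nPosterior mean toxicity (%):\n")
  print(round(100 * x$pi_mean, 1))
  invisible(x)
}

#' EWOC admissibility of each combination
#'
#' A combination is admissible when the posterior probability that its
#' toxicity exceeds \code{zeta} is at most \code{epsilon} (non-strict).
#'
#' @param posterior A \code{blrm_posterior}.
#' @param priors The \code{blrm_priors} holding \code{ewoc_epsilon}.
#' @return Logical matrix.
#' @export
ewoc_admissible <- function(posterior, priors = blrm_priors()) {
  posterior$pi_exceed <= priors$ewoc_epsilon
}

blrm_estimate <- function(posterior, config) {
  if (config$blrm_estimator == "plugin") posterior$pi_plugin else
    posterior$pi_mean
}

#' Patient-gain escalation for the logistic-model design
#'
#' Among combinations passing EWOC and the neighbouring constraint (and any
#' extra mask), picks the one with estimated toxicity closest to the target
#' from below; if every admissible estimate exceeds the target, falls back to
#' the admissible combination with the smallest estimate. Ties break by
#' column-major index order. Returns \code{NULL} when no combination is
#' admissible (the trial then terminates).
#'
#' @param posterior A \code{blrm_posterior}.
#' @param state A \code{trial_state}.
#' @param config A \code{design_config}.
#' @param priors The \code{blrm_priors} (for the EWOC cutoff).
#' @param extra_mask Optional additional logical constraint (e.g. the
#'   new-combination restriction after an insertion).
#' @return Integer vector c(i, j), or \code{NULL}.
#' @export
blrm_next_dose <- function(posterior, state, config = design_config(),
                           priors = blrm_priors(), extra_mask = NULL) {
  mask <- ewoc_admissible(posterior, priors) &
    neighbor_admissible(state, config$constraint)
  if (!is.null(extra_mask)) mask <- mask & extra_mask
  if (!any(mask)) return(NULL)
  est <- blrm_estimate(posterior, config)
  below <- mask & (est <= config$theta)
  pick <- if (any(below)) {
    cand <- which(below)
    cand[which.max(est[cand])]        # closest to theta from below
  } else {
    cand <- which(mask)
    cand[which.min(est[cand])]
  }
  c(row(est)[pick], col(est)[pick])
}

#' Final selection for the logistic-model design
#'
#' The patient-gain criterion restricted to combinations treated with at
#' least \code{min_patients_select} patients; \code{NULL} when none qualify.
#'
#' @inheritParams blrm_next_dose
#' @return Integer vector c(i, j), or \code{NULL}.
#' @export
blrm_select_final <- function(posterior, state, config = design_config()) {
  mask <- state$n >= config$min_patients_select
  if (!any(mask)) return(NULL)
  est <- blrm_estimate(posterior, config)
  below <- mask & (est <= config$theta)
  pick <- if (any(below)) {
    cand <- which(below)
    cand[which.max(est[cand])]
  } else {
    cand <- which(mask)
    cand[which.min(est[cand])]
  }
  c(row(est)[pick], col(est)[pick])
}
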