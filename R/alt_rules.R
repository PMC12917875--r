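# Alternative insertion rules: interval-probability triggers with
# monotonicity enforcement, extending a single-agent adaptive dose
# modification idea to the combination grid.

#' Posterior interval probabilities with monotonicity enforcement
#'
#' For each combination, computes the posterior probability of lying in the
#' underdosing region R1 = [0, 0.16) and the overdosing region
#' R3 = (0.33, 1] under the beta framework. Because the independent beta
#' posteriors need not respect dose monotonicity, the raw values are swept in
#' increasing (i, j) order: each P(R1) is clamped to the minimum over its
#' lower neighbours (nonincreasing in dose) and each P(R3) to the maximum
#' (nondecreasing in dose).
#'
#' @param state A \code{trial_state}.
#' @param lower,upper Region boundaries (defaults 0.16 and 0.33).
#' @return A list of class \code{interval_probs} with matrices
#'   \code{p_under}, \code{p_over} and the raw (unclamped) versions.
#' @export
interval_probs <- function(state, lower = 0.16, upper = 0.33) {
  a <- posterior_alpha(state); b <- posterior_beta(state)
  p_under <- stats::pbeta(lower, a, b)
  p_over <- stats::pbeta(upper, a, b, lower.tail = FALSE)
  structure(list(
    p_under = enforce_monotone(p_under, decreasing = TRUE),
    p_over = enforce_monotone(p_over, decreasing = FALSE),
    raw_under = p_under, raw_over = p_over,
    regions = c(lower = lower, upper = upper)
  ), class = "interval_probs")
}

# Sweep in increasing (i, j) order, assigning each cell its neighbour's value
# when the monotonicity requirement is violated.
enforce_monotone <- function(m, decreasing) {
  I <- nrow(m); J <- ncol(m)
  for (i in seq_len(I)) for (j in seq_len(J)) {
    nb <- c(if (i > 1) m[i - 1, j], if (j > 1) m[i, j - 1])
    if (length(nb)) {
      m[i, j] <- if (decreasing) min(m[i, j], min(nb)) else
        max(m[i, j], max(nb))
    }
  }
  m
}

#' Insertion trigger of interval rule 1
#'
#' Triggers when every combination is confidently outside the acceptable
#' region: each has P(underdosing) > C1 or P(overdosing) > C2. A literal
#' conjunction (each combination satisfying both conditions at once) is
#' available via \code{strict = TRUE}, but is unsatisfiable for cutoffs of
#' 0.5 or more since the two probabilities cannot sum beyond 1.
#'
#' @param probs An \code{interval_probs}.
#' @param c1,c2 Cutoffs in [0, 1]; calibrated default 0.7 with C1 = C2.
#' @param strict Use the literal per-combination conjunction.
#' @return Logical scalar.
#' @export
alt1_trigger <- function(probs, c1 = 0.7, c2 = c1, strict = FALSE) {
  u <- probs$p_under > c1; o <- probs$p_over > c2
  if (strict) all(u & o) else all(u | o)
}

#' Insertion trigger of interval rule 2
#'
#' Triggers when some combination looks confidently underdosed while a
#' neighbouring escalation in either agent looks confidently overdosed, and
#' no tested combination has an observed toxicity rate inside [1/6, 1/3]
#' (i.e. nothing already on the grid is worth exploring first).
#'
#' @param probs An \code{interval_probs}.
#' @param state The \code{trial_state} (for observed DLT rates).
#' @param c1,c2 Cutoffs; calibrated default 0.6 with C1 = C2.
#' @return Logical scalar.
#' @export
alt2_trigger <- function(probs, state, c1 = 0.6, c2 = c1) {
  tested <- state$n > 0
  if (any(tested)) {
    rate <- state$y[tested] / state$n[tested]
    if (any(rate >= 1 / 6 & rate <= 1 / 3)) return(FALSE)
  }
  plan <- alt_insertion_locations(probs, c1, c2)
  plan_size(plan) > 0L
}

#' Insertion locations for the interval rules
#'
#' A new Agent A level goes between levels i and i+1 when, for some j,
#' P(pi_{ij} in R1) > C1 and P(pi_{i+1,j} in R3) > C2; analogously for
#' Agent B over columns.
#'
#' @param probs An \code{interval_probs}.
#' @param c1,c2 Cutoffs.
#' @return An \code{insertion_plan}.
#' @export
alt_insertion_locations <- function(probs, c1, c2 = c1) {
  u <- probs$p_under; o <- probs$p_over
  I <- nrow(u); J <- ncol(u)
  a_gaps <- which(vapply(seq_len(max(I - 1L, 0L)), function(i) {
    any(u[i, ] > c1 & o[i + 1L, ] > c2)
  }, logical(1)))
  b_gaps <- which(vapply(seq_len(max(J - 1L, 0L)), function(j) {
    any(u[, j] > c1 & o[, j + 1L] > c2)
  }, logical(1)))
  structure(list(a_gaps = as.integer(a_gaps), b_gaps = as.integer(b_gaps)),
            class = "insertion_plan")
}
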