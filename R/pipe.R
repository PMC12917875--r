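# PIPE host design: contour-guided escalation with inverse-sample-size
# weighted randomisation, the contour-averaged overdose rule, and single-
# combination final selection.

# Cells touching the estimated contour. "closest-below": cells below the
# contour (entry 0) whose upper or right neighbour is above it or off the
# grid; "adjacent" additionally includes cells above the contour (entry 1)
# whose lower or left neighbour is below it or off the grid.
contour_adjacent <- function(contour, mode = c("adjacent", "closest-below")) {
  mode <- match.arg(mode)
  I <- nrow(contour); J <- ncol(contour)
  up1 <- rbind(contour[-1, , drop = FALSE], matrix(1L, 1, J))      # [i+1, j], 1 off-grid
  right1 <- cbind(contour[, -1, drop = FALSE], matrix(1L, I, 1))   # [i, j+1]
  below <- contour == 0L & (up1 == 1L | right1 == 1L)
  if (mode == "closest-below") return(below)
  down0 <- rbind(matrix(0L, 1, J), contour[-I, , drop = FALSE])    # [i-1, j], 0 off-grid
  left0 <- cbind(matrix(0L, I, 1), contour[, -J, drop = FALSE])    # [i, j-1]
  above <- contour == 1L & (down0 == 0L | left0 == 0L)
  below | above
}

#' Combinations reachable under the neighbouring constraint
#'
#' A combination is reachable when it is at most one dose level of either
#' agent away from a reference combination, excluding diagonal escalation (a
#' simultaneous one-level increase of both agents). Under
#' \code{constraint = "current"} the reference is the combination treated
#' last; under \code{"any-previous"} it is every previously treated
#' combination. Before any patient is treated only the lowest combination is
#' reachable.
#'
#' @param state A \code{trial_state}.
#' @param constraint \code{"current"} or \code{"any-previous"}.
#' @return Logical matrix over the current grid.
#' @export
neighbor_admissible <- function(state, constraint = c("current", "any-previous")) {
  constraint <- match.arg(constraint)
  I <- length(state$levels_a); J <- length(state$levels_b)
  adm <- matrix(FALSE, I, J)
  treated <- which(state$n > 0, arr.ind = TRUE)
  if (nrow(treated) == 0L) {
    adm[1, 1] <- TRUE
    return(adm)
  }
  if (constraint == "current") {
    h <- state$history[nrow(state$history), ]
    treated <- cbind(match(h$pos_a, state$levels_a),
                     match(h$pos_b, state$levels_b))
  }
  for (k in seq_len(nrow(treated))) {
    i <- treated[k, 1]; j <- treated[k, 2]
    for (di in -1:1) for (dj in -1:1) {
      if (di == 1 && dj == 1) next  # no diagonal escalation
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= I && jj >= 1 && jj <= J) adm[ii, jj] <- TRUE
    }
  }
  adm
}

#' Admissible combinations for the next PIPE cohort
#'
#' Intersects the neighbouring constraint with the overdose rule
#' (\code{q < epsilon_pipe}); when the result meets the set of combinations
#' adjacent to the estimated contour, the candidate set is narrowed to that
#' intersection, otherwise escalation proceeds through the safe neighbourhood
#' towards the contour.
#'
#' @param state A \code{trial_state}.
#' @param estimate The current \code{mtc_estimate}.
#' @param q Overdose matrix from \code{\link{overdose_measure}} (recomputed
#'   from \code{estimate} when omitted).
#' @param config A \code{design_config}.
#' @return Logical matrix of admissible combinations (possibly all-FALSE).
#' @export
pipe_admissible <- function(state, estimate, q = NULL,
                            config = design_config()) {
  if (is.null(q)) q <- overdose_measure(estimate)
  base <- neighbor_admissible(state, config$constraint) &
    (q < config$epsilon_pipe)
  if (config$adjacency == "none") return(base)
  if (identical(config$adjacency_phase, "post-insertion") &&
      !state$insertion_done) {
    return(base)
  }
  adj <- contour_adjacent(estimate$contour, config$adjacency)
  if (any(base & adj)) base & adj else base
}

#' Weighted-randomisation choice of the next PIPE combination
#'
#' Samples one admissible combination with probability proportional to the
#' inverse of its sample size. The shared prior sample size is added to the
#' denominator so that untreated combinations have finite (large) weight.
#'
#' @param admissible Logical matrix of admissible combinations.
#' @param state A \code{trial_state}.
#' @return Integer vector c(i, j).
#' @export
pipe_next_dose <- function(admissible, state) {
  idx <- which(admissible)
  if (!length(idx)) stop("no admissible combination to randomise over")
  w <- 1 / (state$n[idx] + state$prior_ss)
  pick <- if (length(idx) == 1L) idx else {
    idx[sample.int(length(idx), 1L, prob = w)]
  }
  c(row(state$n)[pick], col(state$n)[pick])
}

#' Final PIPE selection
#'
#' Among combinations below the final contour estimate (combinations above it
#' are never recommended) and treated with at least
#' \code{min_patients_select} patients, selects the one whose beta posterior
#' mean toxicity is closest to the target; ties are broken uniformly at
#' random. Returns \code{NULL} when no combination qualifies.
#'
#' @param state A \code{trial_state} at trial end.
#' @param estimate The final \code{mtc_estimate}.
#' @param config A \code{design_config}.
#' @return Integer vector c(i, j), or \code{NULL}.
#' @export
pipe_select_final <- function(state, estimate, config = design_config()) {
  elig <- state$n >= config$min_patients_select
  elig <- switch(config$select_mode,
    frontier = elig & contour_adjacent(estimate$contour, "closest-below"),
    below = elig & estimate$contour == 0L,
    any = elig,
    stop("unknown select_mode"))
  if (!any(elig)) return(NULL)
  pm <- beta_posterior_mean(state)
  dist <- abs(pm - config$theta)
  dist[!elig] <- Inf
  best <- which(dist == min(dist))
  pick <- if (length(best) == 1L) best else best[sample.int(length(best), 1L)]
  c(row(state$n)[pick], col(state$n)[pick])
}
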